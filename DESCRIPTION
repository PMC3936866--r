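Package: pvsignal
Title: Cross-Source Pharmacovigilance Signal Detection with the BCPNN
    Information Component
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A semi-automated pharmacovigilance pipeline that extracts
    drug-adverse-event pairs from three source types (spontaneous-report
    tables in the FAERS quarterly format, biomedical abstracts, and
    health-forum comment threads) and screens them for disproportionality
    signals.  Provides dictionary-based named-entity recognition with
    Porter stemming and abstract-to-title acronym propagation, a tf-idf
    co-occurrence association score, report deduplication and term
    normalization for spontaneous reports, the Bayesian Confidence
    Propagation Neural Network (BCPNN) information component with
    closed-form variance, cross-source comparison tables, and a seeded
    synthetic-data generator with injected signals for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
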