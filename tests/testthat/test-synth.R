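small_cfg <- function(n = 200, seed = 5, ...) synth_config(n_docs = n,
                                                           seed = seed, ...)

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  p1 <- tempfile(); p2 <- tempfile()
  generate_corpus(cfg, "medline", p1)
  generate_corpus(cfg, "medline", p2)
  expect_identical(readLines(p1), readLines(p2))
  d1 <- tempfile(); d2 <- tempfile()
  generate_faers(cfg, d1)
  generate_faers(cfg, d2)
  for (f in c("DRUG.txt", "REAC.txt", "DEMO.txt"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## a different seed changes the content
  p3 <- tempfile()
  generate_corpus(small_cfg(seed = 6), "medline", p3)
  expect_false(identical(readLines(p1), readLines(p3)))
  ## zero documents: valid empty outputs
  expect_equal(nrow(read_abstract_corpus(
    generate_corpus(small_cfg(n = 0), "medline", tempfile())$path)), 0L)
})

test_that("tagging the generated corpora recovers the generator bookkeeping", {
  cfg <- small_cfg()
  dicts <- synth_dictionaries(cfg)
  med <- generate_corpus(cfg, "medline", tempfile())
  docs <- read_abstract_corpus(med$path)
  ann <- tag_corpus(docs, dicts$drugs, dicts$events)
  got <- unique(ann[, .(doc_id, concept_id)])
  data.table::setorder(got, doc_id, concept_id)
  exp <- unique(med$truth)
  data.table::setorder(exp, doc_id, concept_id)
  expect_identical(got, exp)
  blog <- generate_corpus(cfg, "blog", tempfile())
  bdocs <- read_forum_corpus(blog$path)
  bann <- tag_corpus(bdocs, dicts$drugs, dicts$events)
  gotb <- unique(bann[, .(doc_id, concept_id)])
  data.table::setorder(gotb, doc_id, concept_id)
  expb <- unique(blog$truth)
  data.table::setorder(expb, doc_id, concept_id)
  expect_identical(gotb, expb)
})

test_that("faers generation exercises dedup without changing content", {
  cfg <- small_cfg(duplicate_rate = 0.25)
  cfg0 <- small_cfg(duplicate_rate = 0)
  d <- generate_faers(cfg, tempfile())
  d0 <- generate_faers(cfg0, tempfile())
  ## duplicates inflate the raw row counts...
  expect_gt(length(readLines(d$drug_path)), length(readLines(d0$drug_path)))
  ## ...but deduplicated instances are identical for the same seed core
  rec <- read_faers_quarter(d$drug_path, d$reac_path, d$demo_path)
  rec0 <- read_faers_quarter(d0$drug_path, d0$reac_path, d0$demo_path)
  expect_identical(dedupe_reports(rec), dedupe_reports(rec0))
  ## follow-up instances share the case id with fu_code followup
  inst <- dedupe_reports(rec)
  fu <- inst[fu_code == "followup"]
  expect_gt(nrow(fu), 0)
  expect_true(all(fu$case_id %in% inst[fu_code == "initial", case_id]))
})

test_that("faers instances match the generator's report bookkeeping", {
  cfg <- small_cfg()
  d <- generate_faers(cfg, tempfile())
  dicts <- synth_dictionaries(cfg)
  rec <- read_faers_quarter(d$drug_path, d$reac_path, d$demo_path)
  inst <- normalize_records(dedupe_reports(rec), dicts$drugs, dicts$events)
  got <- unique(rbind(
    inst[, .(isr, case_id, fu_code, concept_id = drug_concept)],
    inst[, .(isr, case_id, fu_code, concept_id = event_concept)]))
  data.table::setorder(got, isr, case_id, fu_code, concept_id)
  exp <- unique(d$truth)
  data.table::setorder(exp, isr, case_id, fu_code, concept_id)
  expect_identical(got, exp)
})

test_that("without lift the joint counts look independent", {
  cfg <- small_cfg(n = 1500, seed = 9,
                   signals = data.frame(drug = character(),
                                        event = character(),
                                        lift = numeric()))
  med <- generate_corpus(cfg, "medline", tempfile())
  truth <- unique(med$truth)
  p <- cfg$background_rate
  n <- cfg$n_docs
  for (pair in list(c("bupropion", "seizure"), c("aspirin", "nausea"))) {
    nx <- truth[concept_id == pair[1], .N]
    ny <- truth[concept_id == pair[2], .N]
    both <- length(intersect(truth[concept_id == pair[1], doc_id],
                             truth[concept_id == pair[2], doc_id]))
    expected <- nx * ny / n
    ## within 3 binomial standard deviations of independence
    sd3 <- 3 * sqrt(n * p^2 * (1 - p^2))
    expect_lt(abs(both - expected), sd3 + 1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(signals = data.frame(
    drug = "bupropion", event = "seizure", lift = 0.5)), "lift")
  expect_error(synth_config(signals = data.frame(
    drug = c("bupropion", "bupropion"), event = c("rash", "seizure"),
    lift = 10)), "distinct")
  expect_error(synth_config(signals = data.frame(
    drug = "notadrug", event = "seizure", lift = 10)), "not in vocab")
  expect_error(synth_config(background_rate = 0), "background_rate")
})
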