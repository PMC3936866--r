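---
title: "Methods: cross-source pharmacovigilance signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-source pharmacovigilance signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

## The problem

Post-marketing drug safety surveillance asks whether a drug and an adverse
event (AE) are reported together more often than chance would predict.  No
single data stream answers this well on its own: spontaneous-report
databases (FAERS) are large but noisy and duplicated, the biomedical
literature is curated but slow, and patient forums surface complaints that
never reach either.  `pvsignal` implements one pipeline over all three
source types: mentions of drugs and events are extracted and normalized per
source, reduced to per-pair document-level contingency counts, scored with
the BCPNN information component, and laid side by side in cross-source
comparison tables.

A "document" — the unit of co-occurrence — differs by source:

* one abstract (title + body) in an abstract corpus,
* one comment thread (root comment plus all replies) in a forum corpus,
* one report instance (ISR × case id × initial/follow-up code) in FAERS.

## Dictionaries and normalization

Both entity classes are matched against hand-maintained dictionaries: a
*drug* dictionary (generic name plus brand names and salts) and an *event*
dictionary (disease and symptom terms).  The event dictionary can be
enriched from a MedDRA-style PT/LLT table: an exactly matching preferred
term contributes its low-level terms as synonyms of the existing concept; a
non-matching preferred term becomes a new entry.  Matching here is exact on
a normalized surface form (lower-cased, internal whitespace collapsed, edge
punctuation stripped) — no fuzzy matching, so the merge is idempotent and
auditable.

One surface form may belong to at most one concept per dictionary.  We
treat a collision as a load-time error rather than letting the last entry
win silently: contingency counting is only well defined when every mention
resolves to a unique concept.  Terms that fail dictionary lookup are not
dropped; they are carried through lower-cased *as-is*, so rare reactions
still reach the scoring stage (they simply cannot be grouped with
synonyms).

## Named-entity recognition

Text sources are tagged by dictionary lookup over *stemmed token
sequences*:

1. tokens are maximal alphanumeric runs plus standalone punctuation, with
   0-based half-open character offsets;
2. each token is stemmed with the classic Porter algorithm (implemented in
   the package; variants such as "seizure"/"seizures" share a stem);
3. dictionary synonyms are compiled to stem-sequence keys, and each field
   is scanned leftmost-longest: at every position the longest matching key
   wins and the scan resumes after it, so returned annotations never nest.

On a span matched by both dictionaries the drug reading wins; this
tie-break is arbitrary but deterministic, and collisions are rare in
practice.

Abstracts define abbreviations in the body and then use them in the title,
so the body is tagged first, local definitions of the form `long form
(SF)` are collected (short form 2–10 characters, at least half of its
letters uppercase, long form the shortest preceding token run whose
initials cover the short form's letters in order, first definition wins),
and the title is tagged with each short form acting as an extra synonym of
whatever concept its long form matched.  Expansion is deliberately
title-ward only.

Part-of-speech tagging is exposed as a pluggable hook with a no-op default
and is never consulted by the matcher.  There is no published rule by which
POS labels should gate dictionary matches in this design, and keeping the
hook inert keeps the pipeline free of model files while preserving the
interface for later work.

## The association score

For an entity $e$, let $A(e)$ be the set of documents mentioning $e$,
$N(t, A)$ the number of occurrences of entity $t$ in the whole collection,
$N(t, A(e))$ its occurrences inside $A(e)$, and $N$ the summed frequency of
all entities.  The tf-idf style association score is

$$B(t \mid e) = N(t, A(e)) \cdot \log\frac{N + 1}{N(t, A)}, \qquad
P(t_i \mid e) = \frac{B(t_i \mid e)}{\sum_j B(t_j \mid e)},$$

where $j$ ranges over *all* entities other than $e$ co-occurring in
$A(e)$ — drugs and events alike — while only drug–event pairs are emitted
into the pair table.  $P$ is invariant to the base of the logarithm (the
base factor cancels in the ratio); $B$ is computed with the natural
logarithm and is reported in nats.  A pair that never co-occurs has no
score: asking for one is an error, not a zero.

Frequencies count every mention; the contingency counts below count each
document once.  Both conventions are needed and they are kept strictly
apart.

## BCPNN information component

For counts $(C_x, C_y, C_{xy}, N)$ — documents with the drug, with the
event, with both, and in total — the information component with priors
$\alpha = \beta = 2$, $\alpha_1 = \beta_1 = 1$, $\gamma_{11} = 1$ is

$$\gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}
           {(C_x+\alpha_1)(C_y+\beta_1)}, \qquad
\mathrm{IC} = \log_2 \frac{(C_{xy}+\gamma_{11})(N+\alpha)(N+\beta)}
      {(N+\gamma)(C_x+\alpha_1)(C_y+\beta_1)}$$

with closed-form variance

$$V(\mathrm{IC}) = \frac{1}{\ln^2 2}\left[
  \frac{N-C_{xy}+\gamma-\gamma_{11}}{(C_{xy}+\gamma_{11})(1+N+\gamma)} +
  \frac{N-C_x+\alpha-\alpha_1}{(C_x+\alpha_1)(1+N+\alpha)} +
  \frac{N-C_y+\beta-\beta_1}{(C_y+\beta_1)(1+N+\beta)}\right].$$

This is the classical closed-form formulation used by the Uppsala
Monitoring Centre; the priors are exposed through `bcpnn_priors()` for
sensitivity analyses.  IC is in bits: zero means no quantitative
dependency, positive means over-reporting relative to independence.  The
default signal criterion is the standard lower-confidence-bound rule
$\mathrm{IC} - 2\,\mathrm{SD} > 0$ (`ic025_positive`); a plain
`ic_positive` criterion is available because the descriptive phrase
"positive variance" sometimes used for this filter is vacuous as written —
the variance is a sum of positive terms and is always positive.

Numerical notes, verified by the test suite:

* IC and variance agree to $10^{-12}$ with an independently coded
  log-space evaluation over the full grid $C_{xy} \le C_x, C_y \le 50$,
  $N \le 200$, and with frozen 50-digit rational-arithmetic spot values;
* at exact independence with counts scaled by $10^6$, $|\mathrm{IC}| <
  10^{-3}$; IC is strictly increasing in $C_{xy}$ and decreasing in the
  margins; variance strictly decreases under count scaling;
* the priors only *attenuate* the raw ratio
  $\log_2(N C_{xy} / C_x C_y)$ when that ratio is at least one bit in
  magnitude.  Near independence the joint pseudo-count $\gamma_{11}$ can
  slightly *inflate* a small joint count, so a global "shrinkage toward
  zero" claim would be false; the tests assert the regime where the bound
  actually holds.

Ranking uses IC descending with (drug, event) lexicographic tie-breaks.
IC, not its variance, is the ranking key: it is the quantity whose
magnitude measures how far a combination stands out from the background.

## FAERS ingestion

Quarterly `$`-delimited DRUG, REAC and DEMO tables are joined on the ISR
field (drug rows × reaction rows per report, enriched with case id,
initial/follow-up code and dates; column names are remappable via
`faers_colmap()` for other dialects).  Deduplication collapses exact
duplicates of `(ISR, case id, follow-up code, drug, event)`; an initial
and a follow-up report of one case are deliberately *two* instances of the
association.  Age, gender and event date are carried but not part of the
key.  Drug and reaction surfaces are then dictionary-normalized (hits
replaced by canonical terms, misses kept as-is), and contingency counts
treat each report instance as one document, windowed on the FDA report
date.

## Time windows

Three windows are used throughout: the complete set, 2008-01-01 to
2009-12-31, and 2010-01-01 to 2012-03-31, all endpoints inclusive.
Undated records are kept only by the unbounded window — a deterministic
rule, so the two bounded windows partition the dated material exactly.

## The synthetic study fixture

Real FAERS archives, abstract corpora and forum crawls are neither
redistributable nor desk-scale, so the package ships a seeded generator
that emulates the *statistical* structure the pipeline consumes:

* a small vocabulary (6 drugs, 12 events, with brand-name and plural
  synonyms) written out in the package's dictionary format;
* per document, each concept appears independently with background
  probability 0.05; for each injected signal pair the joint probability is
  multiplied by a lift of 10 through a bivariate Bernoulli whose marginals
  stay at the background rate, so every recovery property has an analytic
  expectation;
* 2000 documents per source; abstract-style documents occasionally (rate
  0.1) define an acronym for a present multiword event and use it in the
  title, exercising the propagation rule; forum threads put drug mentions
  in the root and events in replies; FAERS tables contain upper-cased
  brand-name surfaces, exact duplicate rows (rate 0.2) and follow-up
  instances (rate 0.1) so normalization and deduplication do real work.

Reports that would be empty receive one uniformly chosen drug/event, which
pads the margins identically on both sides and leaves pair-level
independence intact.  The generator keeps its own per-document concept
bookkeeping, and the tests require the NER and FAERS paths to recover it
*exactly* — this is what makes the end-to-end recovery claim (100% of
injected pairs flagged in every source across 20 seeds, with a background
false-flag rate under 5%) meaningful.

What the fixture does **not** emulate: real linguistic variety (sentences
are neutral templates), misspellings, negation ("no seizures"),
MedDRA-coded hierarchy effects, demographic structure, or report-volume
trends over time.  Passing the recovery tests therefore demonstrates the
statistical machinery and the plumbing, not robustness to messy prose.

## Validation problem sizes

The shipped tests run the full pipeline at 2000 documents per source
(the fixture's reference condition) for recovery and determinism checks,
the oracle-equivalence grid at counts up to 50×50 with totals up to 200,
and property checks on dozens of randomized small corpora with fixed
seeds.  All randomness flows through explicit seeds; two runs on one
fixture produce byte-identical output trees, which the tests verify with
file checksums.

## Known limitations

* Dictionary NER cannot find terms it does not know, and exact (stemmed)
  matching misses misspellings; recall on real forum text will be lower
  than on the fixture.
* The no-op POS hook means noun/verb homographs ("rash decision") can
  false-positive.
* IC says nothing about causality; flagged pairs are candidates for
  clinical review, nothing more.
* The original formulation's demographic stratification and time-scan IC
  trends are out of scope; only the three static windows are provided.
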