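## Shared fixtures and independent oracles for the test suite.

## small dictionaries used across NER / vocab / report tests
toy_drug_dict <- function() {
  dictionary(list(
    bupropion = c("wellbutrin", "quomen", "zyntabac", "zyban"),
    aspirin = c("acetylsalicylic acid", "ecotrin"),
    warfarin = c("coumadin")), "drug")
}

toy_event_dict <- function() {
  dictionary(list(
    "dry mouth" = c("xerostomia"),
    seizure = c("seizures", "convulsion"),
    "adverse event" = character(),
    drowsiness = c("drowsy", "sleepy"),
    nausea = character()), "event")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

write_jsonl_tmp <- function(records) {
  write_lines_tmp(vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE)), ""),
    ext = ".jsonl")
}

## ---- independent BCPNN oracle -----------------------------------------
## Re-evaluates IC and variance from the closed forms in log space, coded
## separately from the package implementation (sums of log terms instead of
## one product/quotient).  Vectorized.
oracle_ic <- function(c_x, c_y, c_xy, n, a = 2, b = 2, a1 = 1, b1 = 1,
                      g11 = 1) {
  lg <- log(g11) + log(n + a) + log(n + b) - log(c_x + a1) - log(c_y + b1)
  g <- exp(lg)
  (log(c_xy + g11) + log(n + a) + log(n + b) -
      log(n + g) - log(c_x + a1) - log(c_y + b1)) / log(2)
}

oracle_ic_variance <- function(c_x, c_y, c_xy, n, a = 2, b = 2, a1 = 1,
                               b1 = 1, g11 = 1) {
  g <- exp(log(g11) + log(n + a) + log(n + b) -
             log(c_x + a1) - log(c_y + b1))
  t1 <- exp(log(n - c_xy + g - g11) - log(c_xy + g11) - log(1 + n + g))
  t2 <- exp(log(n - c_x + a - a1) - log(c_x + a1) - log(1 + n + a))
  t3 <- exp(log(n - c_y + b - b1) - log(c_y + b1) - log(1 + n + b))
  (t1 + t2 + t3) / log(2)^2
}

## frozen high-precision (50-digit rational arithmetic) evaluations of the
## same closed forms, for spot checks of both implementations
bcpnn_reference_values <- function() {
  list(
    list(c_x = 1, c_y = 1, c_xy = 1, n = 1,
         ic = 0.469485283301220202510665233639,
         variance = 0.826425918928697213859980930895),
    list(c_x = 100, c_y = 100, c_xy = 10, n = 1000,
         ic = -0.0208746230503466981801967643328,
         variance = 0.224173957640041367801381410451),
    list(c_x = 50, c_y = 50, c_xy = 50, n = 200,
         ic = 1.89119677564522039319230295957,
         variance = 0.0917315690428458474551862510481),
    list(c_x = 2, c_y = 30, c_xy = 1, n = 150,
         ic = 0.318513356664294618502042171881,
         variance = 1.76161797570386892365542048823),
    list(c_x = 7, c_y = 3, c_xy = 2, n = 12,
         ic = 0.0197632548214299277475848242941,
         variance = 0.999646605365329496819933038221))
}

## the count grid used by the oracle-equivalence checks:
## c_xy <= min(c_x, c_y) <= max(c_x, c_y) <= cap_xy, max <= n <= cap_n
bcpnn_count_grid <- function(cap_xy = 50L, cap_n = 200L, c_xy_from = 0L) {
  g <- data.table::CJ(c_x = seq_len(cap_xy), c_y = seq_len(cap_xy))
  out <- g[, {
    cxy <- seq(c_xy_from, min(c_x, c_y))
    nn <- seq(max(c_x, c_y), cap_n)
    data.table::CJ(c_xy = cxy, n = nn)
  }, by = .(c_x, c_y)]
  out
}

## injected-signal bookkeeping for the default synthetic configuration:
## canonical-name and concept-id forms of the signal pairs
synth_signal_pairs <- function(cfg) {
  data.table::data.table(
    drug = cfg$signals$drug, event = cfg$signals$event,
    drug_id = pvsignal:::slugify(cfg$signals$drug),
    event_id = pvsignal:::slugify(cfg$signals$event))
}
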