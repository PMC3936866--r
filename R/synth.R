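## Seeded synthetic corpora and FAERS-style tables with known injected
## drug-event signals.  Injection uses a bivariate Bernoulli per signal
## pair: both marginals stay at the background rate while the joint
## probability is multiplied by the pair's lift, so every acceptance
## property has an analytic expectation.  Sentence templates are neutral
## filler; linguistic realism is a non-goal.

#' Built-in synthetic vocabulary
#'
#' Six drugs and twelve adverse events with brand-name / variant synonyms
#' (a desk-scale slice of the kind of dictionary the pipeline consumes).
#' @return list with elements `drugs`, `events` (named lists of synonym
#'   vectors, canonical name as list name).
#' @export
default_synth_vocab <- function() {
  list(
    drugs = list(
      bupropion = c("wellbutrin", "zyban", "amfebutamone"),
      carbamazepine = c("tegretol", "epitol"),
      aspirin = c("acetylsalicylic acid", "ecotrin"),
      olanzapine = c("zyprexa"),
      paroxetine = c("paxil", "seroxat"),
      warfarin = c("coumadin", "jantoven")),
    events = list(
      "dry mouth" = c("xerostomia"),
      seizure = c("seizures", "convulsion", "convulsions"),
      dizziness = c("vertigo"),
      nausea = character(),
      headache = c("headaches", "cephalalgia"),
      insomnia = c("sleeplessness"),
      rash = c("rashes", "exanthema"),
      tremor = c("tremors"),
      "weight gain" = character(),
      fatigue = c("tiredness"),
      pruritus = c("itching"),
      vomiting = character()))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the package's reference study conditions: 2000 documents
#' per source, a background per-concept mention probability of 0.05, and
#' three injected signal pairs with lift 10.
#'
#' @param n_docs documents (or FAERS reports) per source.
#' @param vocab list with `drugs`, `events` as in [default_synth_vocab()].
#' @param background_rate per-concept per-document mention probability.
#' @param signals data.frame with columns `drug`, `event`, `lift`
#'   (`lift >= 1`); drugs and events must each be distinct across signals.
#' @param date_range character/Date length 2, documents dated uniformly.
#' @param acronym_rate fraction of abstract-style documents that define an
#'   acronym for a present multiword event and use it in the title.
#' @param duplicate_rate fraction of FAERS drug/reaction rows emitted again
#'   as exact duplicates.
#' @param followup_rate fraction of FAERS cases that get a follow-up report
#'   instance (same case id, follow-up code F).
#' @param seed integer; fixed seed implies byte-identical output.
#' @return list of class `pv_synth_config`.
#' @export
synth_config <- function(n_docs = 2000, vocab = default_synth_vocab(),
                         background_rate = 0.05,
                         signals = data.frame(
                           drug = c("bupropion", "carbamazepine", "aspirin"),
                           event = c("seizure", "rash", "nausea"),
                           lift = 10),
                         date_range = c("2008-01-01", "2012-03-31"),
                         acronym_rate = 0.1, duplicate_rate = 0.2,
                         followup_rate = 0.1, seed = 1L) {
  signals <- as.data.table(signals)
  stopifnot(n_docs >= 0, background_rate > 0, background_rate < 1,
            acronym_rate >= 0, acronym_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            followup_rate >= 0, followup_rate < 1)
  if (nrow(signals)) {
    if (any(signals$lift < 1)) stopf("synth_config: lift must be >= 1")
    if (anyDuplicated(signals$drug) || anyDuplicated(signals$event))
      stopf("synth_config: signal drugs and events must each be distinct")
    bad <- setdiff(c(signals$drug), names(vocab$drugs))
    bad <- c(bad, setdiff(signals$event, names(vocab$events)))
    if (length(bad))
      stopf("synth_config: signal concept '%s' not in vocab", bad[1])
  }
  structure(list(n_docs = as.integer(n_docs), vocab = vocab,
                 background_rate = background_rate, signals = signals,
                 date_range = as.Date(date_range),
                 acronym_rate = acronym_rate,
                 duplicate_rate = duplicate_rate,
                 followup_rate = followup_rate, seed = as.integer(seed)),
            class = "pv_synth_config")
}

#' Dictionaries corresponding to a synthetic configuration
#' @param cfg a [synth_config()].
#' @return list with `drugs`, `events` ([dictionary()] objects).
#' @export
synth_dictionaries <- function(cfg) {
  list(drugs = dictionary(cfg$vocab$drugs, "drug"),
       events = dictionary(cfg$vocab$events, "event"))
}

## presence matrix: n x (drugs, events) logical, signal pairs injected.
## Marginals stay at p; joint of a signal pair is min(p^2 * lift, p).
sample_presence <- function(cfg, n) {
  p <- cfg$background_rate
  dnames <- names(cfg$vocab$drugs)
  enames <- names(cfg$vocab$events)
  k <- length(dnames) + length(enames)
  pres <- matrix(stats::runif(n * k) < p, nrow = n, ncol = k,
                 dimnames = list(NULL, c(dnames, enames)))
  if (nrow(cfg$signals)) {
    for (i in seq_len(nrow(cfg$signals))) {
      d <- cfg$signals$drug[i]; e <- cfg$signals$event[i]
      p11 <- cfg$signals$lift[i] * p^2
      if (p11 > p) {
        warnf("synth: joint probability for (%s, %s) clipped to %.3f", d, e, p)
        p11 <- p
      }
      u <- stats::runif(n)
      pres[, d] <- u < p
      pres[, e] <- u < p11 | (u >= p & u < 2 * p - p11)
    }
  }
  pres
}

pick_surface <- function(canon, syns) {
  surf <- sample(c(canon, syns), 1L)
  if (stats::runif(1) < 0.2) toupper(surf) else surf
}

sample_dates <- function(cfg, n) {
  days <- seq(cfg$date_range[1], cfg$date_range[2], by = "day")
  days[sample.int(length(days), n, replace = TRUE)]
}

#' Generate a synthetic text corpus (JSONL)
#'
#' `medline` style writes `{id, title, text, date}` records (with an
#' acronym-definition sentence plus an abbreviated title mention in a
#' fraction of documents); `blog` style writes `{id, root, replies, date}`
#' comment threads, with drug mentions in the root and event mentions in
#' the replies.
#'
#' @param cfg a [synth_config()].
#' @param style `"medline"` or `"blog"`.
#' @param path output JSONL path.
#' @return (invisibly) list with `path` and `truth`, a data.table
#'   (`doc_id`, `concept_id`) of the generator's own per-document concept
#'   bookkeeping.
#' @export
generate_corpus <- function(cfg, style = c("medline", "blog"), path) {
  style <- match.arg(style)
  offset <- if (style == "medline") 101L else 202L
  with_seed(cfg$seed + offset, {
    n <- cfg$n_docs
    pres <- sample_presence(cfg, n)
    dates <- sample_dates(cfg, n)
    dnames <- names(cfg$vocab$drugs)
    enames <- names(cfg$vocab$events)
    lines <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s%06d", if (style == "medline") "pm" else "th", i)
      drugs_i <- dnames[pres[i, dnames]]
      events_i <- enames[pres[i, enames]]
      truth[[i]] <- data.table(doc_id = id,
                               concept_id = slugify(c(drugs_i, events_i)))
      dsent <- vapply(drugs_i, function(d) sprintf(
        "The patient had been taking %s daily.",
        pick_surface(d, cfg$vocab$drugs[[d]])), "")
      esent <- vapply(events_i, function(e) sprintf(
        "Later the patient experienced %s during follow up.",
        pick_surface(e, cfg$vocab$events[[e]])), "")
      filler <- "No further issues were recorded at the clinic visit."
      if (style == "medline") {
        title <- "A brief clinical record."
        body_extra <- character()
        multi <- events_i[vapply(strsplit(events_i, " "), length, 1L) > 1]
        if (length(multi) && stats::runif(1) < cfg$acronym_rate) {
          ev <- multi[1]
          sf <- toupper(paste(substr(strsplit(ev, " ")[[1]], 1, 1),
                              collapse = ""))
          body_extra <- sprintf("In this record %s (%s) was documented.",
                                ev, sf)
          title <- sprintf("Observations of %s after treatment.", sf)
        }
        rec <- list(id = id, title = title,
                    text = paste(c(dsent, esent, body_extra, filler),
                                 collapse = " "),
                    date = format(dates[i], "%Y-%m-%d"))
      } else {
        rec <- list(id = id,
                    root = paste(c(dsent, filler), collapse = " "),
                    replies = as.list(unname(esent)),
                    date = format(dates[i], "%Y-%m-%d"))
      }
      lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    }
    writeLines(lines, path, useBytes = TRUE)
    truth <- if (n) data.table::rbindlist(truth) else
      data.table(doc_id = character(), concept_id = character())
    invisible(list(path = path, truth = truth))
  })
}

#' Generate synthetic FAERS-style quarterly tables
#'
#' Writes `$`-delimited DRUG, REAC and DEMO files.  Every report instance
#' carries at least one drug and one event; a fraction of cases receives a
#' follow-up instance (same case id, new ISR, code F) and a fraction of
#' drug/reaction rows is emitted twice verbatim so deduplication is
#' exercised.  Drug names and reaction PTs are upper-cased random synonyms,
#' exercising dictionary normalization.  Duplicate rows are drawn after the
#' base tables, so the deduplicated content is identical for the same seed
#' regardless of `duplicate_rate`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with `drug_path`, `reac_path`, `demo_path` and
#'   `truth`, a data.table (`isr`, `case_id`, `fu_code`, `concept_id`).
#' @export
generate_faers <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed + 303L, {
    n <- cfg$n_docs
    pres <- sample_presence(cfg, n)
    dates <- sample_dates(cfg, n)
    dnames <- names(cfg$vocab$drugs)
    enames <- names(cfg$vocab$events)
    drug_rows <- list(); reac_rows <- list(); demo_rows <- list()
    truth <- list()
    emit <- function(isr, case_id, fu, drugs_i, events_i, date) {
      drug_rows[[length(drug_rows) + 1L]] <<- data.table(
        ISR = isr, DRUG_SEQ = as.character(seq_along(drugs_i)),
        DRUGNAME = vapply(drugs_i, function(d)
          toupper(pick_surface(d, cfg$vocab$drugs[[d]])), ""))
      reac_rows[[length(reac_rows) + 1L]] <<- data.table(
        ISR = isr, PT = vapply(events_i, function(e)
          toupper(pick_surface(e, cfg$vocab$events[[e]])), ""))
      demo_rows[[length(demo_rows) + 1L]] <<- data.table(
        ISR = isr, CASE = case_id, I_F_COD = fu,
        EVENT_DT = format(date, "%Y%m%d"),
        FDA_DT = format(date, "%Y%m%d"),
        AGE = as.character(sample(18:90, 1L)),
        GNDR_COD = sample(c("F", "M"), 1L))
      truth[[length(truth) + 1L]] <<- data.table(
        isr = isr, case_id = case_id,
        fu_code = if (fu == "F") "followup" else "initial",
        concept_id = slugify(c(drugs_i, events_i)))
    }
    for (i in seq_len(n)) {
      drugs_i <- dnames[pres[i, dnames]]
      events_i <- enames[pres[i, enames]]
      if (!length(drugs_i)) drugs_i <- sample(dnames, 1L)
      if (!length(events_i)) events_i <- sample(enames, 1L)
      emit(sprintf("I%07d", i), sprintf("C%07d", i), "I",
           drugs_i, events_i, dates[i])
    }
    ## follow-up instances: same case, new ISR, code F, same concepts
    n_fu <- floor(cfg$followup_rate * n)
    if (n_fu > 0) {
      for (i in sort(sample.int(n, n_fu))) {
        drugs_i <- dnames[pres[i, dnames]]
        events_i <- enames[pres[i, enames]]
        if (!length(drugs_i)) drugs_i <- sample(dnames, 1L)
        if (!length(events_i)) events_i <- sample(enames, 1L)
        emit(sprintf("F%07d", i), sprintf("C%07d", i), "F",
             drugs_i, events_i, min(dates[i] + 30L, cfg$date_range[2]))
      }
    }
    drug_dt <- data.table::rbindlist(drug_rows)
    reac_dt <- data.table::rbindlist(reac_rows)
    demo_dt <- data.table::rbindlist(demo_rows)
    ## exact duplicate rows, appended last
    if (cfg$duplicate_rate > 0 && nrow(drug_dt)) {
      di <- sample.int(nrow(drug_dt), floor(cfg$duplicate_rate * nrow(drug_dt)))
      ri <- sample.int(nrow(reac_dt), floor(cfg$duplicate_rate * nrow(reac_dt)))
      drug_dt <- rbind(drug_dt, drug_dt[sort(di)])
      reac_dt <- rbind(reac_dt, reac_dt[sort(ri)])
    }
    paths <- list(drug_path = file.path(dir, "DRUG.txt"),
                  reac_path = file.path(dir, "REAC.txt"),
                  demo_path = file.path(dir, "DEMO.txt"))
    data.table::fwrite(drug_dt, paths$drug_path, sep = "$", quote = FALSE,
                       eol = "\n")
    data.table::fwrite(reac_dt, paths$reac_path, sep = "$", quote = FALSE,
                       eol = "\n")
    data.table::fwrite(demo_dt, paths$demo_path, sep = "$", quote = FALSE,
                       eol = "\n")
    truth <- if (length(truth)) data.table::rbindlist(truth) else
      data.table(isr = character(), case_id = character(),
                 fu_code = character(), concept_id = character())
    invisible(c(paths, list(truth = truth)))
  })
}

#' Write a complete synthetic study fixture
#'
#' Dictionaries, abstract and forum corpora, FAERS tables and the
#' ground-truth table of injected signals, under one directory.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return (invisibly) named list of paths plus the generator truths.
#' @export
synth_write_all <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dicts <- synth_dictionaries(cfg)
  drug_dict_path <- file.path(dir, "drugs.txt")
  event_dict_path <- file.path(dir, "events.txt")
  write_dictionary(dicts$drugs, drug_dict_path)
  write_dictionary(dicts$events, event_dict_path)
  med <- generate_corpus(cfg, "medline", file.path(dir, "medline.jsonl"))
  blog <- generate_corpus(cfg, "blog", file.path(dir, "blogs.jsonl"))
  faers <- generate_faers(cfg, file.path(dir, "faers"))
  sig <- data.table::copy(cfg$signals)
  if (nrow(sig)) {
    sig[, drug := slugify(drug)]
    sig[, event := slugify(event)]
  }
  write_tsv(sig, file.path(dir, "signals.tsv"))
  invisible(list(drug_dict = drug_dict_path, event_dict = event_dict_path,
                 medline = med$path, blogs = blog$path,
                 faers = faers[c("drug_path", "reac_path", "demo_path")],
                 signals = file.path(dir, "signals.tsv"),
                 truth = list(medline = med$truth, blogs = blog$truth,
                              faers = faers$truth)))
}
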