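## End-to-end orchestration: tagging -> association -> contingency -> BCPNN
## -> cross-source comparison, per source and per time window, with a run
## manifest.  No stage reads a later stage's output, and identical inputs
## produce byte-identical output trees.

#' Assemble a pipeline configuration
#'
#' @param drug_dict,event_dict paths to dictionary term-list files.
#' @param meddra optional path to a MedDRA-style PT/LLT TSV merged into the
#'   event dictionary.
#' @param medline,blogs optional JSONL corpus paths.
#' @param faers optional list with `drug`, `reac`, `demo` paths (vectors of
#'   equal length for several quarters).
#' @param windows named list of [time_window()]s; default [default_windows()].
#' @param priors [bcpnn_priors()].
#' @param criterion signal criterion, see [flag_signal()].
#' @param top_k rows kept in the per-source top table.
#' @return list of class `pv_pipeline_config`.
#' @export
pipeline_config <- function(drug_dict, event_dict, meddra = NULL,
                            medline = NULL, blogs = NULL, faers = NULL,
                            windows = default_windows(),
                            priors = bcpnn_priors(),
                            criterion = c("ic025_positive", "ic_positive"),
                            top_k = 10L) {
  criterion <- match.arg(criterion)
  if (is.null(medline) && is.null(blogs) && is.null(faers))
    stopf("pipeline_config: configure at least one source")
  structure(list(drug_dict = drug_dict, event_dict = event_dict,
                 meddra = meddra, medline = medline, blogs = blogs,
                 faers = faers, windows = windows, priors = priors,
                 criterion = criterion, top_k = as.integer(top_k)),
            class = "pv_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror [pipeline_config()]: `drug_dict`, `event_dict`,
#' `meddra`, `medline`, `blogs`, `faers: {drug, reac, demo}`,
#' `windows: {label: [from, to]}` (empty value = unbounded), `priors`,
#' `criterion`, `top_k`.
#'
#' @param path YAML file.
#' @return a `pv_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  windows <- if (is.null(y$windows)) default_windows() else {
    out <- list()
    for (lab in names(y$windows)) {
      w <- y$windows[[lab]]
      out[[lab]] <- if (is.null(w) || !length(w)) time_window(lab)
      else time_window(lab, w[[1]], w[[2]])
    }
    out
  }
  priors <- if (is.null(y$priors)) bcpnn_priors()
  else do.call(bcpnn_priors, y$priors)
  pipeline_config(drug_dict = y$drug_dict, event_dict = y$event_dict,
                  meddra = y$meddra, medline = y$medline, blogs = y$blogs,
                  faers = y$faers, windows = windows, priors = priors,
                  criterion = y$criterion %||% "ic025_positive",
                  top_k = y$top_k %||% 10L)
}

config_inputs <- function(cfg) {
  unlist(c(cfg$drug_dict, cfg$event_dict, cfg$meddra, cfg$medline,
           cfg$blogs, cfg$faers), use.names = FALSE)
}

#' Run the full pipeline
#'
#' For each configured source and each window: annotations (text sources)
#' or normalized unique pair instances (FAERS), the association pair table,
#' the contingency matrix, and the BCPNN signal table; then a cross-source
#' comparison table per window and a run manifest.  If one source fails the
#' others still complete and an error naming the failed source is raised at
#' the end.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) named list: `out_dir`, `signals` (list
#'   source -> window -> signal rows), `comparison` (list window ->
#'   comparison table).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pv_pipeline_config"))
  missing <- config_inputs(cfg)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stopf("run_pipeline: missing input file(s): %s",
          paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  drugs <- load_dictionary(cfg$drug_dict, "drug")
  events <- load_dictionary(cfg$event_dict, "event")
  if (!is.null(cfg$meddra))
    events <- merge_meddra(events, read_meddra(cfg$meddra))

  signals <- list()
  grouped <- list()
  counts_log <- list()
  failures <- character()

  ## concept ids -> canonical display terms, so text-source rows align with
  ## FAERS rows (which carry canonical terms) in the comparison tables
  canon <- c(stats::setNames(drugs$entries$canonical_name,
                             drugs$entries$concept_id),
             stats::setNames(events$entries$canonical_name,
                             events$entries$concept_id))
  to_canon <- function(x) ifelse(x %in% names(canon), canon[x], x)

  process_text <- function(source_name, docs) {
    ann <- tag_corpus(docs, drugs, events)
    res <- list()
    for (lab in names(cfg$windows)) {
      w <- cfg$windows[[lab]]
      docs_w <- filter_by_window(docs, w)
      ann_w <- ann[doc_id %in% docs_w$doc_id]
      dir_w <- file.path(out_dir, source_name, lab)
      dir.create(dir_w, showWarnings = FALSE, recursive = TRUE)
      write_tsv(ann_w, file.path(dir_w, "annotations.tsv"))
      cnt <- count_entities(ann_w, docs_w)
      pairs <- build_pair_table(cnt)
      cont <- contingency_table(cnt,
                                if (nrow(pairs)) pairs[, .(drug, event)])
      pairs[, `:=`(drug = to_canon(drug), event = to_canon(event))]
      cont[, `:=`(drug = to_canon(drug), event = to_canon(event))]
      write_tsv(pairs, file.path(dir_w, "pairs.tsv"))
      write_tsv(cont, file.path(dir_w, "contingency.tsv"))
      sig <- run_bcpnn(cont, cfg$priors, cfg$criterion,
                       source = source_name, window = lab)
      write_tsv(sig, file.path(dir_w, "signals.tsv"))
      grp <- group_events(sig, events)
      write_tsv(grp, file.path(dir_w, "signals_grouped.tsv"))
      write_tsv(top_k(sig, cfg$top_k), file.path(dir_w, "top.tsv"))
      res[[lab]] <- list(signals = sig, grouped = grp,
                         n_docs = nrow(docs_w), n_annotations = nrow(ann_w))
    }
    res
  }

  process_faers <- function() {
    qs <- lapply(seq_along(cfg$faers$drug), function(i)
      read_faers_quarter(cfg$faers$drug[i], cfg$faers$reac[i],
                         cfg$faers$demo[i]))
    records <- data.table::rbindlist(qs)
    inst <- normalize_records(dedupe_reports(records), drugs, events)
    res <- list()
    for (lab in names(cfg$windows)) {
      w <- cfg$windows[[lab]]
      dir_w <- file.path(out_dir, "faers", lab)
      dir.create(dir_w, showWarnings = FALSE, recursive = TRUE)
      if (lab == names(cfg$windows)[1])
        write_tsv(inst, file.path(out_dir, "faers", "instances.tsv"))
      cont <- faers_contingency(inst, w)
      write_tsv(cont, file.path(dir_w, "contingency.tsv"))
      sig <- run_bcpnn(cont, cfg$priors, cfg$criterion,
                       source = "faers", window = lab)
      write_tsv(sig, file.path(dir_w, "signals.tsv"))
      grp <- group_events(sig, events)
      write_tsv(grp, file.path(dir_w, "signals_grouped.tsv"))
      write_tsv(top_k(sig, cfg$top_k), file.path(dir_w, "top.tsv"))
      res[[lab]] <- list(signals = sig, grouped = grp,
                         n_docs = if (nrow(cont)) cont$n[1] else 0L,
                         n_annotations = nrow(inst))
    }
    res
  }

  run_source <- function(name, fn) {
    tryCatch({
      r <- fn()
      signals[[name]] <<- lapply(r, `[[`, "signals")
      grouped[[name]] <<- lapply(r, `[[`, "grouped")
      counts_log[[name]] <<- lapply(r, function(x)
        list(docs = x$n_docs, annotations = x$n_annotations,
             signal_rows = nrow(x$signals)))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(cfg$medline))
    run_source("medline",
               function() process_text("medline",
                                       read_abstract_corpus(cfg$medline)))
  if (!is.null(cfg$blogs))
    run_source("blogs",
               function() process_text("blogs", read_forum_corpus(cfg$blogs)))
  if (!is.null(cfg$faers)) run_source("faers", process_faers)

  comparison <- list()
  for (lab in names(cfg$windows)) {
    per_source <- lapply(grouped, `[[`, lab)
    per_source <- per_source[!vapply(per_source, is.null, TRUE)]
    if (!length(per_source)) next
    cmp <- cross_source_table(per_source)
    write_tsv(cmp, file.path(out_dir, sprintf("comparison_%s.tsv", lab)))
    comparison[[lab]] <- cmp
  }

  inputs <- config_inputs(cfg)
  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    criterion = cfg$criterion,
    priors = unclass(cfg$priors),
    windows = lapply(cfg$windows, function(w)
      list(start = if (is.null(w$start)) NULL else format(w$start),
           end = if (is.null(w$end)) NULL else format(w$end))),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    counts = counts_log)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  if (length(failures))
    stopf("run_pipeline: source failure(s): %s",
          paste(failures, collapse = " | "))
  invisible(list(out_dir = out_dir, signals = signals,
                 comparison = comparison))
}
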