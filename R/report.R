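## Ranking, event grouping and cross-source comparison tables.

#' Group signal rows by event concept
#'
#' Rows whose event terms normalize to the same event-dictionary concept are
#' merged into one group keyed by the canonical name ("drowsy" and "sleepy"
#' reported under one concept become one row, not two).  The group's
#' displayed statistics are those of its maximum-IC member; member terms are
#' listed alphabetically in `members`.  Events absent from the dictionary
#' stay singleton groups under their own term.
#'
#' @param rows signal rows from [run_bcpnn()].
#' @param events the event [dictionary()].
#' @return data.table: `drug`, `event_group`, `members`, `n_members`, `c_x`,
#'   `c_y`, `c_xy`, `n`, `ic`, `variance`, `sd`, `ic025`, `flagged`,
#'   `source`, `window`, sorted by `ic` descending.
#' @export
group_events <- function(rows, events) {
  rows <- as.data.table(rows)
  if (nrow(rows) == 0) {
    return(data.table(drug = character(), event_group = character(),
                      members = character(), n_members = integer(),
                      c_x = integer(), c_y = integer(), c_xy = integer(),
                      n = integer(), ic = numeric(), variance = numeric(),
                      sd = numeric(), ic025 = numeric(), flagged = logical(),
                      source = character(), window = character()))
  }
  nt <- normalize_terms(events, rows$event)
  rows <- data.table::copy(rows)
  rows[, key_ := ifelse(nt$in_dict, paste0("c\r", nt$concept_id),
                        paste0("s\r", tolower(event)))]
  rows[, event_group := ifelse(nt$in_dict, nt$canonical, tolower(event))]
  grouped <- rows[, {
    best <- which.max(ic)
    list(event_group = event_group[best],
         members = paste(sort(unique(event)), collapse = "; "),
         n_members = data.table::uniqueN(event),
         c_x = c_x[best], c_y = c_y[best], c_xy = c_xy[best], n = n[best],
         ic = ic[best], variance = variance[best], sd = sd[best],
         ic025 = ic025[best], flagged = flagged[best],
         source = source[best], window = window[best])
  }, by = .(drug, key_)]
  grouped[, key_ := NULL]
  grouped[order(-ic, drug, event_group)]
}

#' Cross-source comparison table
#'
#' Takes one (grouped) signal table per source and lays them side by side on
#' the union of (drug, event-group) keys; cells are copied from the source
#' rows, never recomputed, and pairs absent from a source stay empty (NA) --
#' no single source covers all pairs.  All inputs must belong to one time
#' window.
#'
#' @param per_source named list, source label -> signal rows (grouped via
#'   [group_events()] or raw [run_bcpnn()] rows).
#' @return data.table keyed by `drug`, `event_group` with per-source columns
#'   `ic_<source>`, `sd_<source>`, `flagged_<source>`, sorted by the maximum
#'   IC across sources, descending.
#' @export
cross_source_table <- function(per_source) {
  stopifnot(is.list(per_source), length(per_source) > 0,
            !is.null(names(per_source)))
  wins <- unique(unlist(lapply(per_source, function(r) {
    r <- as.data.table(r)
    if (nrow(r) && "window" %in% names(r)) unique(r$window) else character()
  })))
  wins <- wins[!is.na(wins)]
  if (length(wins) > 1)
    stopf("cross_source_table: rows from different windows mixed (%s)",
          paste(wins, collapse = ", "))
  pieces <- lapply(names(per_source), function(src) {
    r <- as.data.table(per_source[[src]])
    if (nrow(r) == 0)
      return(data.table(drug = character(), event_group = character(),
                        ic = numeric(), sd = numeric(), flagged = logical(),
                        src = character()))
    if (!"event_group" %in% names(r)) r[, event_group := event]
    data.table(drug = r$drug, event_group = r$event_group, ic = r$ic,
               sd = r$sd, flagged = r$flagged, src = src)
  })
  long <- data.table::rbindlist(pieces)
  keys <- unique(long[, .(drug, event_group)])
  if (nrow(keys) == 0) {
    out <- data.table(drug = character(), event_group = character())
    for (src in names(per_source))
      out[, (paste0(c("ic_", "sd_", "flagged_"), src)) :=
            list(numeric(), numeric(), logical())]
    out[, max_ic := numeric()]
    return(out)
  }
  out <- keys
  for (src_name in names(per_source)) {
    cols <- paste0(c("ic_", "sd_", "flagged_"), src_name)
    sel <- long[["src"]] == src_name
    sdt <- long[sel, .(drug, event_group, ic, sd, flagged)]
    out <- merge(out, sdt, by = c("drug", "event_group"), all.x = TRUE)
    data.table::setnames(out, c("ic", "sd", "flagged"), cols)
  }
  ic_cols <- paste0("ic_", names(per_source))
  out[, max_ic := do.call(pmax, c(.SD, na.rm = TRUE)), .SDcols = ic_cols]
  out[order(-max_ic, drug, event_group)]
}

#' Top-k rows by IC
#'
#' @param rows signal rows (any table with `ic`, `drug` and an event column).
#' @param k number of rows to keep (`k >= 1`).
#' @return the first `k` rows by `ic` descending, ties broken by (drug,
#'   event) lexicographically.
#' @export
top_k <- function(rows, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k %% 1 != 0)
    stopf("top_k: k must be a positive integer")
  rows <- as.data.table(rows)
  evcol <- if ("event" %in% names(rows)) "event" else "event_group"
  ord <- order(-rows$ic, rows$drug, rows[[evcol]])
  rows[ord][seq_len(min(k, nrow(rows)))]
}

#' Annotate event groups with drug-label knowledge
#'
#' Given a per-drug list of label terms (adverse events already on the
#' product label), marks each grouped row as label-known or not.  Terms are
#' compared through the event dictionary so synonym wording does not matter.
#'
#' @param grouped output of [group_events()].
#' @param label_terms data.table/data.frame with columns `drug`, `term`.
#' @param events the event [dictionary()].
#' @return `grouped` with a logical `label_known` column.
#' @export
annotate_label <- function(grouped, label_terms, events) {
  grouped <- data.table::copy(as.data.table(grouped))
  lt <- as.data.table(label_terms)
  if (nrow(grouped) == 0) {
    grouped[, flagged := flagged]  # keep structure
    grouped[, `:=`(label_known = logical())]
    return(grouped)
  }
  canon_of <- function(x) {
    nt <- normalize_terms(events, x)
    ifelse(nt$in_dict, nt$canonical, tolower(x))
  }
  lt_keys <- unique(paste(tolower(lt$drug), canon_of(lt$term), sep = "\r"))
  grouped[, `:=`(label_known = paste(tolower(drug), canon_of(event_group),
                                     sep = "\r") %in% lt_keys)]
  grouped
}
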