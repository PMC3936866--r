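## Corpus-level entity counting, the tf-idf association score P(t|e), and
## reduction of annotations to per-pair contingency counts.
##
## Notation (kept in the field's standard form): for an entity e, A(e) is
## the set of documents mentioning e; N(t, A) is the total number of
## occurrences of t over the whole collection; N(t, A(e)) the occurrences of
## t within A(e); N the summed frequency of all entities.  Then
##   B(t|e) = N(t, A(e)) * log((N + 1) / N(t, A))
##   P(t|e) = B(t|e) / sum_j B(t_j|e)
## with t_j ranging over all entities other than e co-occurring in A(e).
## P is invariant to the base of the logarithm; B is reported in nats.

#' Count entity mentions over an annotated corpus
#'
#' Every annotation (mention occurrence) increments frequency counts;
#' document sets collect distinct documents.  Totals follow the convention
#' that contingency counts are document counts while N(.) frequencies count
#' every occurrence.
#'
#' @param annotations annotation data.table (from [tag_corpus()]).
#' @param docs the corpus the annotations refer to (data.table with
#'   `doc_id`), or a character vector of document ids.
#' @return object of class `pv_entity_counts` with fields `doc_concept`
#'   (data.table: `doc_id`, `concept_id`, `entity_class`, `n_mentions`),
#'   `freq_total` (named numeric, N(t, A)), `total_freq` (N), `n_docs`,
#'   `class_of` (named character concept -> class).
#' @export
count_entities <- function(annotations, docs) {
  doc_ids <- if (is.character(docs)) docs else docs$doc_id
  unknown <- setdiff(unique(annotations$doc_id), doc_ids)
  if (length(unknown))
    stopf("count_entities: annotation references unknown doc_id '%s'",
          unknown[1])
  dc <- if (nrow(annotations)) {
    annotations[, .(n_mentions = .N), by = .(doc_id, concept_id, entity_class)]
  } else {
    data.table(doc_id = character(), concept_id = character(),
               entity_class = character(), n_mentions = integer())
  }
  ft <- dc[, .(freq = sum(n_mentions)), by = concept_id]
  freq_total <- ft$freq
  names(freq_total) <- ft$concept_id
  cls <- unique(dc[, .(concept_id, entity_class)])
  if (anyDuplicated(cls$concept_id))
    stopf("count_entities: concept '%s' annotated with two entity classes",
          cls$concept_id[duplicated(cls$concept_id)][1])
  class_of <- cls$entity_class
  names(class_of) <- cls$concept_id
  structure(list(doc_concept = dc, freq_total = freq_total,
                 total_freq = sum(dc$n_mentions), n_docs = length(doc_ids),
                 class_of = class_of),
            class = "pv_entity_counts")
}

#' @export
print.pv_entity_counts <- function(x, ...) {
  cat(sprintf("<pv_entity_counts: %d docs, %d concepts, total frequency %d>\n",
              x$n_docs, length(x$freq_total), x$total_freq))
  invisible(x)
}

#' The tf-idf association score of one entity pair
#'
#' Computes `B(t|e) = N(t, A(e)) * log((N + 1) / N(t, A))` and the
#' normalized `P(t|e)` whose denominator sums B over *all* entities (drugs
#' and events alike) other than `e` that co-occur with `e`.  Requesting a
#' pair that never co-occurs is an error, not a zero.
#'
#' @param counts a [count_entities()] result.
#' @param e context entity (concept id).
#' @param t target entity (concept id).
#' @param base logarithm base; P is provably invariant to it.
#' @return list with `b_score`, `p_score`.
#' @export
association_score <- function(counts, e, t, base = exp(1)) {
  tab <- assoc_b_table(counts, e, base = base)
  row <- tab[concept_id == t]
  if (!nrow(row))
    stopf("association_score: '%s' does not co-occur with '%s'", t, e)
  list(b_score = row$B, p_score = row$B / sum(tab$B))
}

## B scores of every entity co-occurring with e (excluding e itself)
assoc_b_table <- function(counts, e, base = exp(1)) {
  dc <- counts$doc_concept
  docs_e <- dc[concept_id == e, unique(doc_id)]
  if (!length(docs_e))
    stopf("association_score: entity '%s' occurs in no document", e)
  inA <- dc[doc_id %in% docs_e & concept_id != e,
            .(freq_in = sum(n_mentions)), by = concept_id]
  N <- counts$total_freq
  inA[, B := freq_in * log((N + 1) / counts$freq_total[concept_id],
                           base = base)]
  inA
}

#' Build the drug-event association pair table
#'
#' One row per (drug, event) pair sharing at least one document, with the
#' pair's `b_score`, `p_score` and `n_docs_together`.  The P denominator
#' ranges over all co-occurring entities of the drug, but only drug-event
#' pairs are emitted.
#'
#' @param counts a [count_entities()] result.
#' @param base logarithm base for B (default natural log).
#' @return data.table: `drug`, `event`, `b_score`, `p_score`,
#'   `n_docs_together`, sorted by drug then p_score descending.
#' @export
build_pair_table <- function(counts, base = exp(1)) {
  empty <- data.table(drug = character(), event = character(),
                      b_score = numeric(), p_score = numeric(),
                      n_docs_together = integer())
  dc <- counts$doc_concept
  drugs <- names(counts$class_of)[counts$class_of == "drug"]
  out <- list(empty)
  for (e in sort(drugs)) {
    tab <- assoc_b_table(counts, e, base = base)
    denom <- sum(tab$B)
    ev <- tab[counts$class_of[concept_id] == "event"]
    if (!nrow(ev)) next
    docs_e <- dc[concept_id == e, unique(doc_id)]
    together <- dc[doc_id %in% docs_e & concept_id %in% ev$concept_id,
                   .(n_docs_together = data.table::uniqueN(doc_id)),
                   by = concept_id]
    ev <- merge(ev, together, by = "concept_id")
    out[[length(out) + 1L]] <- data.table(
      drug = e, event = ev$concept_id, b_score = ev$B,
      p_score = if (denom > 0) ev$B / denom else rep(NaN, nrow(ev)),
      n_docs_together = ev$n_docs_together)
  }
  res <- data.table::rbindlist(out)
  res[order(drug, -p_score, event)]
}

#' Contingency counts for one drug-event pair
#'
#' Document-level counts: `c_x` = documents mentioning the drug, `c_y` =
#' documents mentioning the event, `c_xy` = documents mentioning both,
#' `n` = all documents.  Multiple mentions within a document count once.
#'
#' @param counts a [count_entities()] result.
#' @param drug,event concept ids known to `counts`.
#' @return list of class `pv_contingency`: `c_x`, `c_y`, `c_xy`, `n`.
#' @export
pair_contingency <- function(counts, drug, event) {
  dc <- counts$doc_concept
  for (cc in c(drug, event))
    if (!cc %in% names(counts$freq_total))
      stopf("pair_contingency: unknown concept '%s'", cc)
  dx <- dc[concept_id == drug, unique(doc_id)]
  dy <- dc[concept_id == event, unique(doc_id)]
  structure(list(c_x = length(dx), c_y = length(dy),
                 c_xy = length(intersect(dx, dy)), n = counts$n_docs),
            class = "pv_contingency")
}

#' Contingency table for all co-occurring drug-event pairs
#'
#' @param counts a [count_entities()] result.
#' @param pairs optional data.table (`drug`, `event`) restricting which
#'   pairs to count; defaults to all pairs with `c_xy >= 1`.
#' @return data.table: `drug`, `event`, `c_x`, `c_y`, `c_xy`, `n`.
#' @export
contingency_table <- function(counts, pairs = NULL) {
  dc <- unique(counts$doc_concept[, .(doc_id, concept_id, entity_class)])
  dd <- dc[entity_class == "drug", .(doc_id, drug = concept_id)]
  de <- dc[entity_class == "event", .(doc_id, event = concept_id)]
  joint <- merge(dd, de, by = "doc_id", allow.cartesian = TRUE)[
    , .(c_xy = data.table::uniqueN(doc_id)), by = .(drug, event)]
  if (!is.null(pairs)) {
    pairs <- as.data.table(pairs)[, .(drug, event)]
    joint <- merge(pairs, joint, by = c("drug", "event"), all.x = TRUE)
    joint[is.na(c_xy), c_xy := 0L]
  }
  nx <- dd[, .(c_x = data.table::uniqueN(doc_id)), by = drug]
  ny <- de[, .(c_y = data.table::uniqueN(doc_id)), by = event]
  out <- merge(joint, nx, by = "drug", all.x = TRUE, allow.cartesian = TRUE)
  out <- merge(out, ny, by = "event", all.x = TRUE, allow.cartesian = TRUE)
  out[is.na(c_x), c_x := 0L]
  out[is.na(c_y), c_y := 0L]
  out[, n := counts$n_docs]
  out[order(drug, event), .(drug, event, c_x, c_y, c_xy, n)]
}
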