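## Drug / event dictionaries: construction, MedDRA-style merging, and
## normalization of raw mentions to canonical concepts.

#' Construct a concept dictionary
#'
#' A dictionary holds canonical concepts (drugs or adverse events), each with
#' a synonym set, plus an exact-match index from normalized surface term to
#' concept id.  One surface term may belong to at most one concept within a
#' dictionary; collisions are a hard error because co-occurrence counting
#' requires every mention to resolve unambiguously.
#'
#' @param concepts named list: canonical name -> character vector of synonyms
#'   (the canonical name is always included as a synonym of itself).
#' @param entity_class `"drug"` or `"event"`.
#' @param ids optional character vector of concept ids, parallel to
#'   `concepts`; defaults to a slug of each canonical name.
#' @return an object of class `pv_dictionary` with fields `entity_class`,
#'   `entries` (data.table: `concept_id`, `canonical_name`), `synonyms`
#'   (data.table: `concept_id`, `synonym`, `norm`) and `term_index` (named
#'   character vector, normalized term -> concept id).
#' @export
#' @examples
#' d <- dictionary(list(bupropion = c("wellbutrin", "zyban")), "drug")
#' normalize_term(d, "ZYBAN")
dictionary <- function(concepts, entity_class = c("drug", "event"),
                       ids = NULL) {
  entity_class <- match.arg(entity_class)
  if (length(concepts) == 0) {
    return(new_dictionary(entity_class,
                          entries = data.table(concept_id = character(),
                                               canonical_name = character()),
                          synonyms = data.table(concept_id = character(),
                                                synonym = character(),
                                                norm = character())))
  }
  canon <- norm_term_string(names(concepts))
  if (anyNA(canon) || any(!nzchar(canon)))
    stopf("dictionary: every concept needs a non-empty canonical name")
  ids <- ids %||% slugify(canon)
  if (anyDuplicated(ids))
    stopf("dictionary: duplicate concept id '%s'", ids[duplicated(ids)][1])
  syn <- data.table(
    concept_id = rep(ids, lengths(concepts) + 1L),
    synonym = unlist(Map(c, names(concepts), concepts), use.names = FALSE)
  )
  syn[, norm := norm_term_string(synonym)]
  syn <- syn[nzchar(norm)]
  syn <- unique(syn, by = c("concept_id", "norm"))
  new_dictionary(entity_class,
                 entries = data.table(concept_id = ids, canonical_name = canon),
                 synonyms = syn)
}

## low-level constructor: builds the term index and enforces uniqueness
new_dictionary <- function(entity_class, entries, synonyms) {
  dup <- synonyms[, .(nid = data.table::uniqueN(concept_id)), by = norm][nid > 1]
  if (nrow(dup)) {
    term <- dup$norm[1]
    owners <- unique(synonyms[norm == term, concept_id])
    stopf("dictionary: term '%s' maps to multiple concepts (%s)",
          term, paste(owners, collapse = ", "))
  }
  idx <- synonyms$concept_id
  names(idx) <- synonyms$norm
  structure(list(entity_class = entity_class,
                 entries = data.table::copy(entries),
                 synonyms = data.table::copy(synonyms),
                 term_index = idx),
            class = "pv_dictionary")
}

#' @export
print.pv_dictionary <- function(x, ...) {
  cat(sprintf("<pv_dictionary: %s, %d concepts, %d terms>\n",
              x$entity_class, nrow(x$entries), nrow(x$synonyms)))
  invisible(x)
}

#' Load a dictionary from a term-list file
#'
#' File format: UTF-8, one concept per line, `|`-separated synonyms, the
#' first field being the canonical name; `#` starts a comment.  Example:
#' `bupropion | wellbutrin | zyban`.
#'
#' @param path file path.
#' @param entity_class `"drug"` or `"event"`.
#' @return a [dictionary()] object.
#' @export
load_dictionary <- function(path, entity_class = c("drug", "event")) {
  entity_class <- match.arg(entity_class)
  if (!file.exists(path)) stopf("load_dictionary: no such file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  concepts <- list()
  canon_seen <- character()
  for (i in keep) {
    fields <- trimws(strsplit(lines[i], "|", fixed = TRUE)[[1]])
    if (length(fields) == 0 || !nzchar(norm_term_string(fields[1])))
      stopf("load_dictionary: malformed line %d in '%s'", i, path)
    fields <- fields[nzchar(fields)]
    canon <- norm_term_string(fields[1])
    if (canon %in% canon_seen)
      stopf("load_dictionary: concept '%s' defined twice (line %d)", canon, i)
    canon_seen <- c(canon_seen, canon)
    concepts[[fields[1]]] <- fields[-1]
  }
  dictionary(concepts, entity_class)
}

#' Read a MedDRA-style PT/LLT term list
#'
#' Expected dialect: UTF-8 TSV with columns `pt` and `llt`, one low-level
#' term per line, grouped by preferred term; `llt` may be empty.
#'
#' @param path file path.
#' @return data.table with columns `pt`, `llt`.
#' @export
read_meddra <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  if (!all(c("pt", "llt") %in% names(dt)))
    stopf("read_meddra: '%s' must have columns 'pt' and 'llt'", path)
  if (any(!nzchar(trimws(dt$pt))))
    stopf("read_meddra: empty preferred term in '%s'", path)
  dt[, .(pt, llt)]
}

#' Merge MedDRA-style PT/LLT terms into an event dictionary
#'
#' For each preferred term (PT) that exactly matches an existing dictionary
#' synonym after normalization, its low-level terms (LLTs) are added as
#' synonyms of that concept.  PTs with no exact match become new entries
#' with their LLTs as synonyms.  No fuzzy or pattern matching is performed,
#' and the operation is idempotent.
#'
#' @param d an event [dictionary()].
#' @param terms data.table/data.frame with columns `pt`, `llt` (as returned
#'   by [read_meddra()]), or a list of lists with fields `pt` and `llts`.
#' @return a new `pv_dictionary`.
#' @export
merge_meddra <- function(d, terms) {
  stopifnot(inherits(d, "pv_dictionary"))
  if (d$entity_class != "event")
    stopf("merge_meddra: MedDRA terms merge into the event dictionary only")
  if (is.data.frame(terms)) {
    terms <- as.data.table(terms)
    grp <- terms[nzchar(trimws(pt)) | nzchar(trimws(llt))]
    spl <- split(grp$llt, grp$pt)
    terms <- Map(function(p, l) list(pt = p, llts = l[nzchar(trimws(l))]),
                 names(spl), spl)
  }
  if (length(terms) == 0) return(d)
  ## deterministic order: by normalized PT
  ord <- order(vapply(terms, function(t) norm_term_string(t$pt), ""))
  terms <- terms[ord]

  entries <- data.table::copy(d$entries)
  synonyms <- data.table::copy(d$synonyms)
  idx <- d$term_index
  for (tm in terms) {
    ptn <- norm_term_string(tm$pt)
    if (!nzchar(ptn)) stopf("merge_meddra: empty preferred term")
    llts <- unique(norm_term_string(tm$llts %||% character()))
    llts <- llts[nzchar(llts)]
    if (ptn %in% names(idx)) {
      cid <- unname(idx[[ptn]])
    } else {
      cid <- slugify(ptn)
      if (cid %in% entries$concept_id)
        stopf("merge_meddra: generated id '%s' collides with existing entry",
              cid)
      entries <- rbind(entries,
                       data.table(concept_id = cid, canonical_name = ptn))
      synonyms <- rbind(synonyms,
                        data.table(concept_id = cid, synonym = ptn, norm = ptn))
      idx[ptn] <- cid
    }
    for (l in llts) {
      if (l %in% names(idx)) {
        if (unname(idx[[l]]) != cid)
          stopf("merge_meddra: LLT '%s' of PT '%s' already belongs to concept '%s'",
                l, ptn, unname(idx[[l]]))
        next  # same concept: idempotent no-op
      }
      synonyms <- rbind(synonyms,
                        data.table(concept_id = cid, synonym = l, norm = l))
      idx[l] <- cid
    }
  }
  new_dictionary("event", entries, synonyms)
}

#' Normalize a raw mention against a dictionary
#'
#' Exact match on the normalized surface form (see [norm_term_string()]).
#' A hit returns the concept's canonical name; a miss returns the surface
#' lower-cased, flagged `in_dictionary = FALSE` so the mention can be carried
#' through the pipeline as-is.
#'
#' @param d a `pv_dictionary`.
#' @param raw non-empty string.
#' @return list with fields `surface`, `canonical`, `concept_id`
#'   (NA when absent) and `in_dictionary`.
#' @export
normalize_term <- function(d, raw) {
  stopifnot(inherits(d, "pv_dictionary"))
  if (length(raw) != 1 || is.na(raw) || !nzchar(raw))
    stopf("normalize_term: 'raw' must be a single non-empty string")
  r <- normalize_terms(d, raw)
  list(surface = raw, canonical = r$canonical,
       concept_id = if (r$in_dict) r$concept_id else NA_character_,
       in_dictionary = r$in_dict)
}

## vectorized core used by normalize_term and the FAERS module
normalize_terms <- function(d, raw) {
  norm <- norm_term_string(raw)
  cid <- unname(d$term_index[norm])
  hit <- !is.na(cid) & nzchar(norm)
  canon <- tolower(raw)
  if (any(hit)) {
    canon_map <- d$entries$canonical_name
    names(canon_map) <- d$entries$concept_id
    canon[hit] <- unname(canon_map[cid[hit]])
  }
  data.table(surface = as.character(raw), canonical = canon,
             concept_id = ifelse(hit, cid, NA_character_), in_dict = hit)
}

#' Write a dictionary to its term-list file format
#'
#' Inverse of [load_dictionary()] (up to normalization).
#' @param d a `pv_dictionary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(d, path) {
  stopifnot(inherits(d, "pv_dictionary"))
  lines <- vapply(seq_len(nrow(d$entries)), function(i) {
    cid <- d$entries$concept_id[i]
    canon <- d$entries$canonical_name[i]
    syns <- setdiff(d$synonyms[concept_id == cid, norm], canon)
    paste(c(canon, sort(syns)), collapse = " | ")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
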