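## Reading abstract-style and forum-style corpora into the unified document
## model, and time-window filtering.  One abstract = one document; one forum
## comment thread (root + replies) = one document.

#' Define a time window
#'
#' `start`/`end` of `NULL` mean unbounded on that side; a window unbounded on
#' both sides is the "complete set" window, the only one that keeps undated
#' documents.
#'
#' @param label short window name used in output tables.
#' @param start,end `Date` or ISO-8601 string or `NULL`.
#' @return object of class `pv_window`.
#' @export
time_window <- function(label, start = NULL, end = NULL) {
  start <- if (is.null(start)) NULL else as.Date(start)
  end <- if (is.null(end)) NULL else as.Date(end)
  if (!is.null(start) && !is.null(end) && start > end)
    stopf("time_window: start %s after end %s", start, end)
  structure(list(label = as.character(label), start = start, end = end),
            class = "pv_window")
}

#' The three analysis windows used throughout the package
#'
#' `complete` (unbounded), `w1` = 2008-01-01..2009-12-31 and
#' `w2` = 2010-01-01..2012-03-31.
#' @return named list of [time_window()] objects.
#' @export
default_windows <- function() {
  list(complete = time_window("complete"),
       w1 = time_window("w1", "2008-01-01", "2009-12-31"),
       w2 = time_window("w2", "2010-01-01", "2012-03-31"))
}

is_unbounded <- function(w) is.null(w$start) && is.null(w$end)

#' Read an abstract corpus (JSONL)
#'
#' One JSON object per line with fields `id`, `title`, `text`, `date`
#' (ISO-8601 `YYYY-MM-DD`).  Title and body are kept distinct because
#' acronym propagation tags the abstract before the title.  Unparseable
#' dates yield `date = NA` with a warning; a missing id is an error.
#'
#' @param path JSONL file.
#' @return data.table with columns `doc_id`, `source` (= "medline"),
#'   `title`, `body`, `date`.
#' @export
read_abstract_corpus <- function(path) {
  recs <- read_jsonl(path)
  out <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$id) || !nzchar(as.character(r$id)))
      stopf("read_abstract_corpus: record %d has no id", i)
    list(doc_id = as.character(r$id),
         title = as.character(r$title %||% ""),
         body = as.character(r$text %||% ""),
         raw_date = as.character(r$date %||% NA_character_))
  })
  finish_corpus(out, source = "medline", path = path)
}

#' Read a forum corpus (JSONL comment threads)
#'
#' One JSON object per line with fields `id`, `root` (the opening comment),
#' `replies` (array, may be empty), `date`.  Each thread becomes one
#' document whose body is the root comment followed by each reply, joined
#' with single newlines in file order; the title is empty.
#'
#' @param path JSONL file.
#' @return data.table with columns `doc_id`, `source` (= "blog"), `title`,
#'   `body`, `date`.
#' @export
read_forum_corpus <- function(path) {
  recs <- read_jsonl(path)
  out <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$id) || !nzchar(as.character(r$id)))
      stopf("read_forum_corpus: record %d has no id", i)
    if (is.null(r$root))
      stopf("read_forum_corpus: thread %d has no root comment", i)
    replies <- unlist(r$replies %||% character(), use.names = FALSE)
    list(doc_id = as.character(r$id),
         title = "",
         body = paste(c(as.character(r$root), as.character(replies)),
                      collapse = "\n"),
         raw_date = as.character(r$date %||% NA_character_))
  })
  finish_corpus(out, source = "blog", path = path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) stopf("no such corpus file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

finish_corpus <- function(recs, source, path) {
  if (length(recs) == 0)
    return(data.table(doc_id = character(), source = character(),
                      title = character(), body = character(),
                      date = as.Date(character())))
  dt <- data.table::rbindlist(recs)
  if (anyDuplicated(dt$doc_id))
    stopf("duplicate doc_id '%s' in '%s'", dt$doc_id[duplicated(dt$doc_id)][1],
          path)
  dates <- parse_iso_date(dt$raw_date)
  bad <- !is.na(dt$raw_date) & nzchar(dt$raw_date) & is.na(dates)
  if (any(bad))
    warnf("%d record(s) in '%s' have unparseable dates (kept with date = NA)",
          sum(bad), path)
  data.table(doc_id = dt$doc_id, source = source, title = dt$title,
             body = dt$body, date = dates)
}

#' Filter documents by a time window
#'
#' Keeps documents with `start <= date <= end` (both ends inclusive).
#' Undated documents are kept only by the unbounded "complete set" window,
#' so the bounded windows partition dated documents deterministically.
#'
#' @param docs corpus data.table (from the `read_*_corpus` readers).
#' @param w a [time_window()].
#' @return filtered data.table.
#' @export
filter_by_window <- function(docs, w) {
  stopifnot(inherits(w, "pv_window"))
  if (is_unbounded(w)) return(docs)
  keep <- !is.na(docs$date)
  if (!is.null(w$start)) keep <- keep & docs$date >= w$start
  if (!is.null(w$end)) keep <- keep & docs$date <= w$end
  docs[keep]
}
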