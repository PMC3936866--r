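## Dictionary-based named-entity recognition: tokenizer, sentence splitter,
## acronym handler and stemmed longest-match tagging.  The body of an
## abstract is tagged before its title so that local abbreviation
## definitions found in the body extend to the title.
##
## Part-of-speech tagging is a pluggable hook with a no-op default;
## dictionary matching never consults POS labels (see the methods vignette).

#' Tokenize text
#'
#' Tokens are maximal runs of letters/digits plus standalone punctuation
#' characters.  Offsets are 0-based, half-open character positions into the
#' input, so `substr(text, start + 1, end)` recovers each token.  Stems are
#' Porter stems of the lower-cased token ([porter_stem()]); tokens without
#' letters keep their lower-cased text as stem.
#'
#' @param text a single string.
#' @return data.table with columns `text`, `stem`, `start`, `end`.
#' @export
#' @examples
#' tokenize("Dry mouth was reported.")
tokenize <- function(text) {
  tok <- tokenize_raw(text)
  data.table(text = tok$text, stem = porter_stem(tok$text),
             start = tok$start, end = tok$end)
}

## low-level tokenizer used by the matcher (plain lists, no stemming)
tokenize_raw <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text))
    return(list(text = character(), start = integer(), end = integer()))
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1]]
  if (m[1] == -1)
    return(list(text = character(), start = integer(), end = integer()))
  len <- attr(m, "match.length")
  list(text = substring(text, m, m + len - 1L),
       start = as.integer(m - 1L), end = as.integer(m + len - 1L))
}

#' Split text into sentence spans
#'
#' Splits at `.`, `!` or `?` followed by whitespace and an uppercase letter,
#' never inside parentheses (so a parenthesized short form such as "(AE)"
#' cannot end a sentence).  Returned spans are 0-based half-open character
#' ranges trimmed of surrounding whitespace; together they cover all
#' non-whitespace text.
#'
#' @param text a single string.
#' @return data.table with columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  empty <- data.table(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  m <- gregexpr("[.!?](?=\\s+[[:upper:]])", text, perl = TRUE)[[1]]
  breaks <- if (m[1] == -1) integer() else as.integer(m)
  breaks <- breaks[depth[breaks] <= 0]   # never inside parentheses
  bounds <- c(0L, breaks, nchar(text))   # candidate span edges (0-based)
  spans <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    if (s + lead < e - trail)
      spans[[length(spans) + 1L]] <- c(s + lead, e - trail)
  }
  if (!length(spans)) return(empty)
  data.table(start = vapply(spans, `[`, 0, 1), end = vapply(spans, `[`, 0, 2))
}

#' Detect locally defined acronyms
#'
#' Finds patterns `long form (SF)` where the short form SF is 2-10
#' characters with at least half of its letters uppercase.  The long form is
#' the shortest run of word tokens immediately before the parenthesis whose
#' initial letters cover the short form's letters in order (the first token's
#' initial must match the first letter).  The first definition of a short
#' form wins.
#'
#' @param text the text to scan (for abstracts, the body).
#' @return named character vector: short form -> long form.
#' @export
#' @examples
#' detect_acronyms("Each adverse event (AE) was recorded.")
detect_acronyms <- function(text) {
  out <- character()
  if (is.na(text) || !nzchar(text)) return(out)
  tok <- tokenize_raw(text)
  word <- grepl("^[[:alnum:]]", tok$text)
  m <- gregexpr("\\(([^()]{1,12})\\)", text)[[1]]
  if (m[1] == -1) return(out)
  len <- attr(m, "match.length")
  for (k in seq_along(m)) {
    sf <- substr(text, m[k] + 1L, m[k] + len[k] - 2L)
    sf <- trimws(sf)
    nlet <- nchar(gsub("[^[:alpha:]]", "", sf))
    nup <- nchar(gsub("[^[:upper:]]", "", sf))
    if (nchar(sf) < 2 || nchar(sf) > 10 || nlet == 0 || nup < nlet / 2) next
    if (sf %in% names(out)) next                    # first definition wins
    paren0 <- as.integer(m[k]) - 1L                 # 0-based offset of "("
    prev <- which(word & tok$end <= paren0)
    if (!length(prev)) next
    sfl <- strsplit(tolower(gsub("[^[:alpha:]]", "", sf)), "")[[1]]
    found <- NULL
    for (L in seq_len(min(length(prev), 2L * length(sfl) + 2L))) {
      idx <- prev[(length(prev) - L + 1L):length(prev)]
      inits <- tolower(substr(tok$text[idx], 1, 1))
      if (inits[1] == sfl[1] && is_subsequence(sfl, inits)) {
        found <- idx
        break                                       # shortest sequence wins
      }
    }
    if (is.null(found)) next
    out[sf] <- substr(text, tok$start[found[1]] + 1L,
                      tok$end[found[length(found)]])
  }
  out
}

is_subsequence <- function(needle, hay) {
  j <- 1L
  for (h in hay) {
    if (j <= length(needle) && h == needle[j]) j <- j + 1L
  }
  j > length(needle)
}

## ---- dictionary match index -------------------------------------------

## Builds a stemmed-phrase lookup for the matcher.  Keys are the stems of a
## synonym's tokens joined by spaces; values carry concept id and class.
## Events are inserted first and drugs second, so a drug wins any identical
## span (span-tie precedence drug > event).
build_match_index <- function(drugs, events) {
  env <- new.env(parent = emptyenv())
  max_len <- 1L
  add <- function(dict) {
    if (is.null(dict)) return()
    for (i in seq_len(nrow(dict$synonyms))) {
      tok <- tokenize_raw(dict$synonyms$norm[i])
      if (!length(tok$text)) next
      key <- paste(porter_stem(tok$text), collapse = " ")
      assign(key, list(concept_id = dict$synonyms$concept_id[i],
                       entity_class = dict$entity_class),
             envir = env)
      max_len <<- max(max_len, length(tok$text))
    }
  }
  add(events)
  add(drugs)
  structure(list(env = env, max_len = max_len), class = "pv_match_index")
}

## copy of an index with extra (key -> concept) entries layered on top;
## used for title tagging with acronym short forms
index_with_extra <- function(index, extra) {
  if (!length(extra)) return(index)
  env <- new.env(parent = emptyenv())
  for (k in ls(index$env)) assign(k, get(k, envir = index$env), envir = env)
  max_len <- index$max_len
  for (k in names(extra)) {
    tok <- tokenize_raw(norm_term_string(k))
    if (!length(tok$text)) next
    key <- paste(porter_stem(tok$text), collapse = " ")
    if (!exists(key, envir = env, inherits = FALSE))
      assign(key, extra[[k]], envir = env)
    max_len <- max(max_len, length(tok$text))
  }
  structure(list(env = env, max_len = max_len), class = "pv_match_index")
}

## Leftmost-longest matcher over one field's text.  Returns a list of
## equal-length vectors (start, end, concept_id, entity_class, surface).
match_field <- function(text, index) {
  none <- list(start = integer(), end = integer(), concept_id = character(),
               entity_class = character(), surface = character())
  tok <- tokenize_raw(text)
  nt <- length(tok$text)
  if (nt == 0) return(none)
  stems <- porter_stem(tok$text)
  ## candidate keys for every (position, length): hit_len[i] = longest match
  hit_len <- integer(nt)
  hit_key <- character(nt)
  for (L in seq_len(min(index$max_len, nt))) {
    if (L == 1) keys <- stems
    else {
      parts <- lapply(seq_len(L), function(j) stems[j:(nt - L + j)])
      keys <- do.call(paste, parts)
    }
    pos <- seq_len(nt - L + 1L)
    ex <- vapply(keys, exists, TRUE, envir = index$env, inherits = FALSE,
                 USE.NAMES = FALSE)
    hit_len[pos[ex]] <- L          # larger L overwrites: longest wins
    hit_key[pos[ex]] <- keys[ex]
  }
  starts <- integer(); ends <- integer(); keys <- character()
  i <- 1L
  while (i <= nt) {
    if (hit_len[i] > 0L) {
      L <- hit_len[i]
      starts <- c(starts, tok$start[i])
      ends <- c(ends, tok$end[i + L - 1L])
      keys <- c(keys, hit_key[i])
      i <- i + L
    } else i <- i + 1L
  }
  if (!length(starts)) return(none)
  hits <- lapply(keys, get, envir = index$env)
  list(start = starts, end = ends,
       concept_id = vapply(hits, `[[`, "", "concept_id"),
       entity_class = vapply(hits, `[[`, "", "entity_class"),
       surface = substring(text, starts + 1L, ends))
}

#' Tag a document with drug and event mentions
#'
#' The body is tagged first by case-insensitive leftmost-longest matching of
#' stemmed contiguous token sequences against both dictionaries; acronyms
#' defined in the body are then detected, and the title is tagged with each
#' short form acting as an extra synonym of whatever concept its long form
#' matches.  On identical spans a drug match takes precedence over an event
#' match.
#'
#' @param doc one-row corpus data.table (or list) with `doc_id`, `title`,
#'   `body`.
#' @param drugs,events dictionaries ([dictionary()]).
#' @param index optional prebuilt [build_match_index()] (for corpus loops).
#' @return data.table of annotations: `doc_id`, `field` ("title"/"body"),
#'   `start`, `end` (0-based half-open offsets into that field),
#'   `concept_id`, `entity_class`, `surface`.
#' @export
tag_document <- function(doc, drugs = NULL, events = NULL, index = NULL) {
  index <- index %||% build_match_index(drugs, events)
  title <- as.character(doc$title %||% "")
  body <- as.character(doc$body %||% "")

  bm <- match_field(body, index)
  acro <- detect_acronyms(body)
  extra <- list()
  for (sf in names(acro)) {
    tokl <- tokenize_raw(norm_term_string(acro[[sf]]))
    if (!length(tokl$text)) next
    key <- paste(porter_stem(tokl$text), collapse = " ")
    if (exists(key, envir = index$env, inherits = FALSE))
      extra[[sf]] <- get(key, envir = index$env)
  }
  tm <- match_field(title, index_with_extra(index, extra))

  out <- data.table(
    doc_id = rep(as.character(doc$doc_id), length(tm$start) + length(bm$start)),
    field = c(rep("title", length(tm$start)), rep("body", length(bm$start))),
    start = c(tm$start, bm$start), end = c(tm$end, bm$end),
    concept_id = c(tm$concept_id, bm$concept_id),
    entity_class = c(tm$entity_class, bm$entity_class),
    surface = c(tm$surface, bm$surface))
  out
}

#' Tag every document in a corpus
#'
#' @param docs corpus data.table from the `read_*_corpus` readers.
#' @param drugs,events dictionaries.
#' @return rbind of [tag_document()] results (possibly zero rows).
#' @export
tag_corpus <- function(docs, drugs, events) {
  index <- build_match_index(drugs, events)
  res <- lapply(seq_len(nrow(docs)), function(i)
    tag_document(docs[i], index = index))
  empty <- data.table(doc_id = character(), field = character(),
                      start = integer(), end = integer(),
                      concept_id = character(), entity_class = character(),
                      surface = character())
  if (!length(res)) return(empty)
  data.table::rbindlist(c(list(empty), res))
}
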