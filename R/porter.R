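## Porter stemming (the original 1980 algorithm).  Used by the NER matcher
## so that surface variants such as "seizure"/"seizures" unify on one key.
## Words of one or two letters are returned unchanged, as in the reference
## implementation.

.porter_cache <- new.env(parent = emptyenv())

## consonant/vowel profile of a word: TRUE = consonant.
## 'y' is a vowel exactly when preceded by a consonant.
porter_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  if (n > 0 && chars[1] == "y") cons[1] <- TRUE
  if (n > 1) {
    ys <- which(chars[-1] == "y") + 1L
    for (i in ys) cons[i] <- !cons[i - 1L]
  }
  cons
}

## m = number of VC sequences in [C](VC)^m[V]
porter_m <- function(chars) {
  cons <- porter_cons(chars)
  if (!length(cons)) return(0L)
  v <- rle(cons)$values
  if (v[1]) v <- v[-1]  # drop leading consonant run: [C](VC)^m[V]
  sum(v)                # each consonant run left completes one VC
}

porter_has_vowel <- function(chars) any(!porter_cons(chars))

porter_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2 && chars[n] == chars[n - 1] && porter_cons(chars)[n]
}

## *o: ends consonant-vowel-consonant, final consonant not w, x or y
porter_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3) return(FALSE)
  cons <- porter_cons(chars)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(chars[n] %in% c("w", "x", "y"))
}

ends_with <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw >= ns && substr(w, nw - ns + 1L, nw) == suf
}

chars_of <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

## apply the first matching rule from a (suffix -> replacement) table,
## subject to measure condition on the stem; returns word (possibly changed)
porter_rule_step <- function(w, rules, min_m) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suf[i]
    if (ends_with(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (porter_m(chars_of(stem)) > min_m)
        return(paste0(stem, rules$rep[i]))
      return(w)  # suffix matched but condition failed: stop scanning
    }
  }
  w
}

porter_stem_word <- function(w) {
  if (nchar(w) <= 2) return(w)

  ## Step 1a
  if (ends_with(w, "sses")) w <- substr(w, 1, nchar(w) - 2)
  else if (ends_with(w, "ies")) w <- substr(w, 1, nchar(w) - 2)
  else if (ends_with(w, "ss")) w <- w
  else if (ends_with(w, "s")) w <- substr(w, 1, nchar(w) - 1)

  ## Step 1b
  step1b_cleanup <- FALSE
  if (ends_with(w, "eed")) {
    stem <- substr(w, 1, nchar(w) - 3)
    if (porter_m(chars_of(stem)) > 0) w <- paste0(stem, "ee")
  } else if (ends_with(w, "ed")) {
    stem <- substr(w, 1, nchar(w) - 2)
    if (porter_has_vowel(chars_of(stem))) { w <- stem; step1b_cleanup <- TRUE }
  } else if (ends_with(w, "ing")) {
    stem <- substr(w, 1, nchar(w) - 3)
    if (porter_has_vowel(chars_of(stem))) { w <- stem; step1b_cleanup <- TRUE }
  }
  if (step1b_cleanup) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else {
      ch <- chars_of(w)
      if (porter_double_cons(ch) && !(ch[length(ch)] %in% c("l", "s", "z"))) {
        w <- substr(w, 1, nchar(w) - 1)
      } else if (porter_m(ch) == 1L && porter_cvc(ch)) {
        w <- paste0(w, "e")
      }
    }
  }

  ## Step 1c
  if (ends_with(w, "y")) {
    stem <- substr(w, 1, nchar(w) - 1)
    if (porter_has_vowel(chars_of(stem))) w <- paste0(stem, "i")
  }

  ## Step 2 (m > 0); longest suffixes first so e.g. IZATION beats ATION
  step2 <- data.frame(
    suf = c("ational", "ization", "iveness", "fulness", "ousness",
            "tional", "biliti", "alism", "aliti", "iviti", "entli",
            "ousli", "ation", "enci", "anci", "izer", "abli", "alli",
            "ator", "eli"),
    rep = c("ate", "ize", "ive", "ful", "ous",
            "tion", "ble", "al", "al", "ive", "ent",
            "ous", "ate", "ence", "ance", "ize", "able", "al",
            "ate", "e"),
    stringsAsFactors = FALSE)
  w <- porter_rule_step(w, step2, min_m = 0L)

  ## Step 3 (m > 0)
  step3 <- data.frame(
    suf = c("icate", "ative", "alize", "iciti", "ical", "ness", "ful"),
    rep = c("ic", "", "al", "ic", "ic", "", ""),
    stringsAsFactors = FALSE)
  w <- porter_rule_step(w, step3, min_m = 0L)

  ## Step 4 (m > 1); ION needs the stem to end in s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
             "ic", "ou")
  for (suf in step4) {
    if (ends_with(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      ok <- porter_m(chars_of(stem)) > 1L
      if (suf == "ion")
        ok <- ok && (ends_with(stem, "s") || ends_with(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  ## Step 5a
  if (ends_with(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1)
    ch <- chars_of(stem)
    m <- porter_m(ch)
    if (m > 1L || (m == 1L && !porter_cvc(ch))) w <- stem
  }

  ## Step 5b
  ch <- chars_of(w)
  if (porter_m(ch) > 1L && porter_double_cons(ch) && ch[length(ch)] == "l")
    w <- substr(w, 1, nchar(w) - 1)

  w
}

#' Porter stem of each word
#'
#' Implements the classic Porter suffix-stripping algorithm.  Input is
#' lower-cased; tokens without any ASCII letter are returned unchanged
#' (lower-cased).  Results are memoized, so repeated corpus tagging is cheap.
#'
#' @param words character vector.
#' @return character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("seizures", "dizziness", "caresses"))
porter_stem <- function(words) {
  words <- tolower(as.character(words))
  uq <- unique(words)
  new <- uq[!vapply(uq, exists, TRUE, envir = .porter_cache,
                    inherits = FALSE, USE.NAMES = FALSE)]
  for (w in new) {
    s <- if (grepl("[a-z]", w) && !grepl("[^a-z]", w)) porter_stem_word(w) else w
    assign(w, s, envir = .porter_cache)
  }
  vapply(words, get, "", envir = .porter_cache, USE.NAMES = FALSE)
}
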