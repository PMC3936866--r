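## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a term string for exact dictionary matching
#'
#' Lower-cases, collapses internal whitespace to single spaces, and strips
#' leading/trailing punctuation and whitespace.  This is the canonical form
#' used by dictionary term indexes and by [normalize_term()]; stemming is
#' *not* applied here (stemmed matching belongs to the NER layer).
#'
#' @param x character vector of raw terms.
#' @return character vector of normalized terms (possibly empty strings).
#' @export
#' @examples
#' norm_term_string(c("  Dry   Mouth ", "ZYBAN", "(aspirin)"))
norm_term_string <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

## slug used for generated concept ids: "Dry mouth" -> "dry-mouth"
slugify <- function(x) gsub("[^a-z0-9]+", "-", norm_term_string(x))

## Run code with a temporary RNG state; fully pins the generator kind so
## synthetic fixtures are reproducible across R versions.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

## Deterministic TSV writer (C locale, "\n" line endings, NA as empty).
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n", dateTimeAs = "write.csv")
  invisible(path)
}

## Strict ISO-8601 date parser: anything not YYYY-MM-DD becomes NA.
parse_iso_date <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
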