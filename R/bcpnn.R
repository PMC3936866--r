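## The BCPNN information component and its closed-form variance.
##
## For a drug X and event Y in one source, with document counts c_x, c_y,
## joint count c_xy and total n, the information component is
##
##   IC = log2[ (c_xy + g11)(n + a)(n + b) /
##              ((n + gamma)(c_x + a1)(c_y + b1)) ],
##   gamma = g11 (n + a)(n + b) / ((c_x + a1)(c_y + b1))
##
## with Dirichlet-style priors a = b = 2, a1 = b1 = 1, g11 = 1 (the classic
## Bate et al. 1998 formulation used by the Uppsala Monitoring Centre); the
## variance of IC is
##
##   V = (1/ln 2)^2 [ (n - c_xy + gamma - g11)/((c_xy + g11)(1 + n + gamma))
##                  + (n - c_x + a - a1)    /((c_x + a1)(1 + n + a))
##                  + (n - c_y + b - b1)    /((c_y + b1)(1 + n + b)) ].
##
## IC = 0 means no quantitative dependency; IC > 0 over-reporting relative
## to independence; the standard signal criterion is IC - 2*SD > 0 (IC025).

#' BCPNN prior parameters
#'
#' Marginal pseudo-totals `alpha`, `beta` (default 2), marginal pseudo-counts
#' `alpha1`, `beta1` (default 1) and joint pseudo-count `gamma11` (default 1).
#'
#' @param alpha,beta,alpha1,beta1,gamma11 strictly positive priors with
#'   `alpha1 <= alpha`, `beta1 <= beta`.
#' @return list of class `pv_priors`.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  p <- list(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
            gamma11 = gamma11)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 TRUE)))
    stopf("bcpnn_priors: all priors must be single positive numbers")
  if (alpha1 > alpha || beta1 > beta)
    stopf("bcpnn_priors: need alpha1 <= alpha and beta1 <= beta")
  structure(p, class = "pv_priors")
}

check_counts <- function(c_x, c_y, c_xy, n) {
  v <- c(c_x, c_y, c_xy, n)
  if (any(!is.finite(v)) || any(v %% 1 != 0) || any(v < 0))
    stopf("bcpnn: counts must be finite non-negative integers")
  if (any(n < 1)) stopf("bcpnn: total document count n must be >= 1")
  if (any(c_xy > pmin(c_x, c_y)) || any(pmax(c_x, c_y) > n))
    stopf("bcpnn: need c_xy <= min(c_x, c_y) and max(c_x, c_y) <= n")
}

#' BCPNN information component (IC)
#'
#' Vectorized over counts.
#'
#' @param c_x,c_y documents with the drug / the event.
#' @param c_xy documents with both.
#' @param n total documents in the source.
#' @param priors a [bcpnn_priors()] object.
#' @return IC in bits (base-2 log).
#' @export
#' @examples
#' information_component(100, 100, 10, 1000)  # independence: about 0
information_component <- function(c_x, c_y, c_xy, n,
                                  priors = bcpnn_priors()) {
  check_counts(c_x, c_y, c_xy, n)
  g <- priors$gamma11 * (n + priors$alpha) * (n + priors$beta) /
    ((c_x + priors$alpha1) * (c_y + priors$beta1))
  log2((c_xy + priors$gamma11) * (n + priors$alpha) * (n + priors$beta) /
         ((n + g) * (c_x + priors$alpha1) * (c_y + priors$beta1)))
}

#' Variance and standard deviation of the IC
#'
#' @inheritParams information_component
#' @return list with `variance` (bits squared) and `sd` (bits), each
#'   vectorized like the inputs.
#' @export
ic_variance <- function(c_x, c_y, c_xy, n, priors = bcpnn_priors()) {
  check_counts(c_x, c_y, c_xy, n)
  a <- priors$alpha; b <- priors$beta
  a1 <- priors$alpha1; b1 <- priors$beta1; g11 <- priors$gamma11
  g <- g11 * (n + a) * (n + b) / ((c_x + a1) * (c_y + b1))
  v <- (1 / log(2))^2 *
    ((n - c_xy + g - g11) / ((c_xy + g11) * (1 + n + g)) +
       (n - c_x + a - a1) / ((c_x + a1) * (1 + n + a)) +
       (n - c_y + b - b1) / ((c_y + b1) * (1 + n + b)))
  list(variance = v, sd = sqrt(v))
}

#' Signal flag for a scored pair
#'
#' `ic025_positive` (default): flagged when `ic - 2*sd > 0` (the standard
#' lower-confidence-bound criterion); `ic_positive`: flagged when `ic > 0`.
#'
#' @param ic,sd numeric vectors.
#' @param criterion `"ic025_positive"` or `"ic_positive"`.
#' @return logical vector.
#' @export
flag_signal <- function(ic, sd, criterion = c("ic025_positive",
                                              "ic_positive")) {
  criterion <- match.arg(criterion)
  if (criterion == "ic025_positive") ic - 2 * sd > 0 else ic > 0
}

#' Score a table of drug-event contingency counts with BCPNN
#'
#' @param pair_counts data.table/data.frame with columns `drug`, `event`,
#'   `c_x`, `c_y`, `c_xy`, `n` (one source and window per call).
#' @param priors a [bcpnn_priors()].
#' @param criterion signal criterion, see [flag_signal()].
#' @param source,window optional labels copied onto the output rows.
#' @return data.table of signal rows sorted by `ic` descending (ties broken
#'   by drug then event): `drug`, `event`, `c_x`, `c_y`, `c_xy`, `n`, `ic`,
#'   `variance`, `sd`, `ic025`, `flagged` plus the labels.
#' @export
run_bcpnn <- function(pair_counts, priors = bcpnn_priors(),
                      criterion = c("ic025_positive", "ic_positive"),
                      source = NA_character_, window = NA_character_) {
  criterion <- match.arg(criterion)
  pc <- as.data.table(pair_counts)
  need <- c("drug", "event", "c_x", "c_y", "c_xy", "n")
  if (!all(need %in% names(pc)))
    stopf("run_bcpnn: pair_counts needs columns %s", paste(need, collapse = ", "))
  if (nrow(pc) == 0) {
    return(data.table(drug = character(), event = character(),
                      c_x = integer(), c_y = integer(), c_xy = integer(),
                      n = integer(), ic = numeric(), variance = numeric(),
                      sd = numeric(), ic025 = numeric(), flagged = logical(),
                      source = character(), window = character()))
  }
  ic <- information_component(pc$c_x, pc$c_y, pc$c_xy, pc$n, priors)
  vv <- ic_variance(pc$c_x, pc$c_y, pc$c_xy, pc$n, priors)
  out <- data.table(drug = pc$drug, event = pc$event,
                    c_x = pc$c_x, c_y = pc$c_y, c_xy = pc$c_xy, n = pc$n,
                    ic = ic, variance = vv$variance, sd = vv$sd,
                    ic025 = ic - 2 * vv$sd,
                    flagged = flag_signal(ic, vv$sd, criterion),
                    source = source, window = window)
  out[order(-ic, drug, event)]
}
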