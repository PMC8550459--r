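#' Population variance of an attention-weight vector
#'
#' Increasing attention intensity is expected to make the weights more
#' extreme; the population variance (divisor n) summarises that spread.
#'
#' @param weights An [attention_weights()] object or numeric vector of length
#'   at least 2.
#' @return Non-negative number.
#' @examples
#' weight_variance(c(0, 2))
#' @export
weight_variance <- function(weights) {
  v <- .gain_values(weights)
  if (length(v) < 2L) stop("need at least 2 weights")
  mean((v - mean(v))^2)
}

#' Number of switched-off filters
#'
#' Counts weights at (or numerically indistinguishable from) zero. With the
#' non-negativity projection, turned-off filters are exactly 0; the default
#' tolerance guards serialised round-trips.
#'
#' @param weights An [attention_weights()] object or numeric vector.
#' @param eps Non-negative tolerance; `eps = 0` counts exact zeros only.
#' @return Integer count.
#' @export
count_zeroed <- function(weights, eps = 1e-6) {
  if (eps < 0) stop("`eps` must be non-negative")
  sum(.gain_values(weights) <= eps)
}

#' Rank agreement between adjacent intensity levels
#'
#' Spearman rank correlation of the attention-weight vectors for each
#' adjacent pair in an intensity-ordered list, with average ranks for ties.
#' A constant vector makes the correlation undefined for that pair; the pair
#' is flagged with `NA` rather than an error.
#'
#' @param weights_by_alpha List of [attention_weights()] objects (or numeric
#'   vectors of equal length), ordered by intensity.
#' @param alphas Optional numeric labels for the levels (taken from the
#'   weights' `alpha` fields when available).
#' @return Tibble with columns `alpha_from`, `alpha_to`, `rho`.
#' @export
adjacent_alpha_correlation <- function(weights_by_alpha, alphas = NULL) {
  if (length(weights_by_alpha) < 2L) stop("need at least 2 weight vectors")
  vals <- lapply(weights_by_alpha, .gain_values)
  len <- vapply(vals, length, integer(1))
  if (any(len != len[1L])) stop("weight vectors must have equal lengths")
  if (is.null(alphas)) {
    alphas <- vapply(weights_by_alpha, function(w) {
      if (inherits(w, "attention_weights")) w$alpha else NA_real_
    }, numeric(1))
  }
  n <- length(vals)
  rho <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- vals[[i]]; b <- vals[[i + 1L]]
    rho[i] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      NA_real_
    } else {
      stats::cor(a, b, method = "spearman")
    }
  }
  tibble::tibble(
    alpha_from = alphas[-n],
    alpha_to = alphas[-1L],
    rho = rho
  )
}
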