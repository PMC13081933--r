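#' Work metrics over per-iteration weight-change magnitudes
#'
#' Aggregates a list of per-iteration absolute weight changes `|dw_i|` into a
#' work series under one of four metrics: `sum` (the primary metric,
#' `sum(|dw_i|)` per iteration), `sum_sq` (`sum(dw_i^2)`), `max`
#' (`max(|dw_i|)`) and `rate` (first difference of the cumulative sum series,
#' which equals the per-iteration sum for unit iteration spacing). Absolute
#' magnitudes are summed so that opposing updates of equal size add rather
#' than cancel: irreversible entropy is generated locally at each
#' modification site regardless of the direction of change elsewhere.
#'
#' @param deltas List with one numeric vector of `|dw_i|` per iteration (an
#'   empty iteration contributes 0).
#' @param metric One of `"sum"`, `"sum_sq"`, `"max"`, `"rate"`.
#' @return Numeric work series, one non-negative value per iteration.
#' @examples
#' work_metrics(list(c(0.1, 0.1)), "sum")     # 0.2
#' work_metrics(list(c(0.1, 0.1)), "sum_sq")  # 0.02
#' @export
work_metrics <- function(deltas, metric = c("sum", "sum_sq", "max", "rate")) {
  metric <- match.arg(metric)
  stopifnot(is.list(deltas), length(deltas) >= 1L)
  agg <- function(f) vapply(deltas, function(d) {
    d <- abs(as.numeric(d))
    if (length(d) == 0L) 0 else f(d)
  }, numeric(1))
  switch(metric,
    sum = agg(sum),
    sum_sq = agg(function(d) sum(d^2)),
    max = agg(max),
    rate = diff(c(0, cumsum(agg(sum))))
  )
}

#' Shannon entropy in bits
#'
#' `H = -sum(p_i * log2(p_i))` with the convention `0 * log 0 = 0`.
#'
#' @param p Probability vector: non-negative, summing to 1 within `tol`.
#' @param tol Normalization tolerance.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))   # 2 bits
#' shannon_entropy(c(0.25, 0.75))  # ~0.8113 bits
#' @export
shannon_entropy <- function(p, tol = 1e-8) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("probabilities must sum to 1 (within tolerance)", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized activation entropy of a level
#'
#' Informational entropy of one level's activation pattern: probabilities are
#' the normalized absolute activations `p_i = |y_i| / sum(|y_j|)` (uniform if
#' all activations are zero), and the Shannon entropy is divided by
#' `log2(n)` so the result lies in \[0, 1\], reaching 1 exactly when all
#' activation magnitudes are equal and 0 when a single node carries all the
#' activity. This informational entropy is distinct from the thermodynamic
#' entropy-generation index tracked by the work metrics.
#'
#' @param activations Numeric vector of a level's node activations (>= 2).
#' @return Normalized entropy in \[0, 1\].
#' @examples
#' level_entropy(c(0.2, 0.6))  # p = (0.25, 0.75) -> ~0.8113
#' @export
level_entropy <- function(activations) {
  n <- length(activations)
  stopifnot(n >= 2L)
  a <- abs(activations)
  s <- sum(a)
  p <- if (s == 0) rep(1 / n, n) else a / s
  shannon_entropy(p) / log2(n)
}
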