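#' Weighted summary statistics (population-style)
#'
#' Survey-weighted mean, variance, skewness, quantiles and threshold
#' proportions. All moments use the population convention: the denominator is
#' the sum of weights, not `sum(w) - 1`. Quantiles interpolate the weighted
#' empirical CDF linearly at plotting positions `(cumsum(w) - w/2) / sum(w)`,
#' clamping to the observed extremes.
#'
#' @param x numeric vector.
#' @param w positive weights, recycled if length 1.
#' @param probs quantile probabilities in `[0, 1]`.
#' @return `weighted_mean`, `weighted_var`, `weighted_skewness` return a
#'   scalar; `weighted_quantile` a named vector the length of `probs`;
#'   `weighted_pct_below`/`weighted_pct_above` a percentage in `[0, 100]`
#'   using strict inequality (ties at the threshold are not counted).
#' @keywords internal
#' @name weighted-stats
NULL

check_weights <- function(x, w) {
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(w) == length(x))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and strictly positive", call. = FALSE)
  }
  w
}

#' @rdname weighted-stats
#' @export
weighted_mean <- function(x, w = NULL) {
  w <- check_weights(x, w)
  sum(w * x) / sum(w)
}

#' @rdname weighted-stats
#' @export
weighted_var <- function(x, w = NULL) {
  w <- check_weights(x, w)
  m <- sum(w * x) / sum(w)
  sum(w * (x - m)^2) / sum(w)
}

#' @rdname weighted-stats
#' @export
weighted_skewness <- function(x, w = NULL) {
  w <- check_weights(x, w)
  m <- sum(w * x) / sum(w)
  m2 <- sum(w * (x - m)^2) / sum(w)
  if (m2 <= 0) return(0)
  m3 <- sum(w * (x - m)^3) / sum(w)
  m3 / m2^1.5
}

#' @rdname weighted-stats
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  w <- check_weights(x, w)
  stopifnot(all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  out <- stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
  names(out) <- paste0("p", formatC(100 * probs, format = "fg"))
  out
}

#' @rdname weighted-stats
#' @param threshold cut-point on the scale of `x`.
#' @export
weighted_pct_below <- function(x, threshold, w = NULL) {
  w <- check_weights(x, w)
  # clamp: partial sums can exceed the total by rounding
  min(100, max(0, 100 * sum(w[x < threshold]) / sum(w)))
}

#' @rdname weighted-stats
#' @export
weighted_pct_above <- function(x, threshold, w = NULL) {
  w <- check_weights(x, w)
  min(100, max(0, 100 * sum(w[x > threshold]) / sum(w)))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored on exit so generators never perturb user RNG flow.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
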