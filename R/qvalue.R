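#' Storey-Tibshirani q-values
#'
#' Converts p-values to q-values with the smoother estimate of the null
#' proportion pi0: `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` is
#' evaluated on a lambda grid and a natural cubic smoothing spline (df = 3)
#' is read off at the largest lambda. When too few p-values are available to
#' estimate pi0 (fewer than 100), or the estimate is non-positive, pi0 falls
#' back to 1 with a warning, at which point the q-values coincide with
#' Benjamini-Hochberg step-up values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion (e.g. `pi0 = 1` for BH
#'   behaviour); estimated when `NULL`.
#' @param lambda Grid for the smoother (default `seq(0.05, 0.95, 0.05)`).
#' @return Numeric vector of q-values, same order as `p`; monotone
#'   non-decreasing in `p` and never above 1. The pi0 used is attached as
#'   attribute `pi0`.
#' @export
storey_q <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (length(p) == 0) abort("storey_q: empty p-value vector.")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- tryCatch(estimate_pi0(p, lambda), error = function(e) NA_real_)
    if (is.na(pi0) || pi0 <= 0) {
      warn("storey_q: pi0 estimation unavailable; falling back to pi0 = 1 (BH).")
      pi0 <- 1
    }
  }
  stopifnot(pi0 > 0, pi0 <= 1)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))
  attr(q, "pi0") <- pi0
  q
}

estimate_pi0 <- function(p, lambda) {
  m <- length(p)
  if (m < 100) stop("too few p-values for the pi0 smoother")
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 0), 1)
}
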