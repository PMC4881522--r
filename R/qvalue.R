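#' Storey q-values from chi-squared outlier p-values
#'
#' Secondary significance criterion: converts the per-feature p-values to
#' q-values with the null proportion pi0 estimated by Storey's smoother —
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))} evaluated
#' over \code{lambda}, smoothed with a cubic spline (df = 3) and read off
#' at the largest lambda, clamped into (0, 1].  Sorted q-values are
#' \eqn{q_{(r)} = \min_{r' \ge r} \pi_0 m p_{(r')} / r'}, so they are
#' order-isotonic with the p-values, and with \code{pi0 = 1} they reduce
#' exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in [0,1]; length >= 20 unless \code{pi0} is
#'   supplied (the smoother needs a tail to estimate from).
#' @param pi0 optional fixed null proportion in (0,1], bypassing
#'   estimation.
#' @param threshold significance cutoff on q (default 0.01).
#' @param lambda grid for the pi0 smoother.
#' @return a [QValueResult-class].
#' @export
computeQvalues <- function(p, pi0 = NULL, threshold = 0.01,
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20)
      stop("need at least 20 p-values to estimate pi0 (or supply pi0)")
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(p)
  q <- pmin(rev(cummin(rev(pi0 * m * p[o] / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- q
  names(out) <- names(p)
  methods::new("QValueResult", qvalues = out, pi0 = pi0,
               threshold = threshold, significant = unname(out < threshold))
}
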