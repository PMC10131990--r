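#' Chapman two-source estimator
#'
#' Bias-corrected Lincoln-Petersen estimate of a closed population from two
#' capture occasions: `(n1+1)(n2+1)/(m+1) - 1`, finite even with zero
#' overlap. The 95% CI uses the standard Chapman variance transferred to the
#' log scale, which keeps the bounds positive.
#'
#' @param n1,n2 Per-occasion capture totals.
#' @param m Number captured on both occasions (`m <= min(n1, n2)`).
#' @param pair Optional length-2 label of the occasions used.
#' @return An object of class `pairwise_estimate` with the point estimate,
#'   variance and CI; also computed for the plain Lincoln-Petersen variant
#'   via `estimator = "lincoln_petersen"`.
#' @export
#' @examples
#' chapman(2465, 1314, 721)
chapman <- function(n1, n2, m, pair = c(1L, 2L)) {
  n1 <- as.numeric(assert_count(n1, "n1"))
  n2 <- as.numeric(assert_count(n2, "n2"))
  m <- as.numeric(assert_count(m, "m"))
  if (m > min(n1, n2)) stop("overlap exceeds an occasion total", call. = FALSE)
  est <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
  v <- (n1 + 1) * (n2 + 1) * (n1 - m) * (n2 - m) / ((m + 1)^2 * (m + 2))
  se <- sqrt(v)
  ci <- if (est > 0) exp(log(est) + c(-1, 1) * 1.96 * se / est) else c(0, 0)
  structure(list(pair = pair, estimator = "chapman", estimate = est,
                 variance = v, ci = ci),
            class = "pairwise_estimate")
}

#' Lincoln-Petersen two-source estimator
#'
#' Classical ratio estimate `n1 * n2 / m`; undefined (infinite) when the
#' overlap is zero, where [chapman()] stays finite.
#'
#' @inheritParams chapman
#' @return A `pairwise_estimate`.
#' @export
lincoln_petersen <- function(n1, n2, m, pair = c(1L, 2L)) {
  n1 <- as.numeric(assert_count(n1, "n1"))
  n2 <- as.numeric(assert_count(n2, "n2"))
  m <- as.numeric(assert_count(m, "m"))
  if (m > min(n1, n2)) stop("overlap exceeds an occasion total", call. = FALSE)
  est <- if (m > 0) n1 * n2 / m else Inf
  v <- if (m > 0) n1 * n2 * (n1 - m) * (n2 - m) / m^3 else Inf
  ci <- if (is.finite(est) && est > 0) {
    exp(log(est) + c(-1, 1) * 1.96 * sqrt(v) / est)
  } else c(NA_real_, NA_real_)
  structure(list(pair = pair, estimator = "lincoln_petersen", estimate = est,
                 variance = v, ci = ci),
            class = "pairwise_estimate")
}

#' @export
print.pairwise_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (occasions %s): %.1f [%.1f, %.1f]\n",
              x$estimator, paste(x$pair, collapse = "-"),
              x$estimate, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Independence MLE for a three-source table
#'
#' Maximum-likelihood population size under mutually independent,
#' homogeneous-per-occasion captures. Capture probabilities are profiled out
#' (`p_j = n_j / N`), leaving a one-dimensional profile log-likelihood in N
#' maximized numerically (golden-section/parabolic search via
#' `stats::optimize`) over `[n_observed, 100 * n_observed]`. Serves as the
#' closed-form oracle for the single-class reduction of [fit_lcmcr()].
#'
#' @param t A [capture_history_table()] with k = 3.
#' @return Point estimate of N (numeric).
#' @export
independence_mle_3list <- function(t) {
  stopifnot(inherits(t, "capture_history_table"), t$k == 3)
  m <- marginals_from_table(t)
  if (all(m$pair_overlaps == 0) && m$triple_overlap == 0) {
    stop("all overlaps are zero; the independence likelihood is unbounded in N",
         call. = FALSE)
  }
  n_obs <- sum(t$cells)
  nj <- m$n
  loglik <- function(N) {
    lgamma(N + 1) - lgamma(N - n_obs + 1) +
      sum(ifelse(nj > 0, nj * log(nj / N), 0) + (N - nj) * log1p(-nj / N))
  }
  lo <- max(n_obs, max(nj)) + 1e-6
  hi <- 100 * n_obs
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.4)
  # profile likelihood can be monotone decreasing (everyone seen everywhere):
  # the MLE then sits at the boundary N = n_observed
  if (loglik(lo) >= opt$objective) return(max(n_obs, max(nj)))
  opt$maximum
}
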