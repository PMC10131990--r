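#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when matching printed survey
#' tables; `base::round()` rounds half to even, which disagrees on exact
#' halves (e.g. `round(0.125, 2)`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(54.865, 2)  # 54.87
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# clip probabilities away from {0, 1}
clip01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

# deterministic per-stratum stream seeds, kept well below 2^31
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2003 + i * 7919) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0) {
  if (length(x) == 0 || anyNA(x) || any(!is.finite(x)) ||
      any(x < min) || any(abs(x - round(x)) > 1e-8)) {
    stop(sprintf("`%s` must contain non-negative integers (>= %d)", name, min),
         call. = FALSE)
  }
  invisible(as.integer(round(x)))
}
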