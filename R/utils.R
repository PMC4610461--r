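# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; accuracy percentages are reported with
#' conventional half-up rounding at a fixed number of decimals.
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny guard so values that are exactly representable halves round up
  floor(x * p + 0.5 + 1e-9) / p
}

# log(sum(exp(x))) without overflow; returns -Inf for all--Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log density of a multivariate normal with full covariance (small d).
dmvnorm_log <- function(x, mean, sigma) {
  d <- length(mean)
  ch <- chol(sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Multiply two polynomials given as coefficient vectors (ascending powers).
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
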