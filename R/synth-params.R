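# Parameters of the synthetic signal generator.
#
# Each hand-shape class is given, per sEMG channel, an activation amplitude
# (how strongly that muscle group fires for that finger configuration) and an
# AR(4) spectral shape (a pair of damped resonances whose centre frequency
# varies with the class). The accelerometer model is a per-orientation gravity
# vector plus, for inward gestures, a smooth biphasic acceleration pulse on
# the movement axis.

#' AR(4) coefficients from two damped resonances
#'
#' Builds a stable AR(4) filter whose poles are the conjugate pairs
#' `r1 * exp(+-2i*pi*f1)` and `r2 * exp(+-2i*pi*f2)`. Coefficients follow the
#' convention `x_t = a1*x_{t-1} + ... + a4*x_{t-4} + e_t`.
#'
#' @param f1,f2 Resonance centre frequencies as fractions of the sampling
#'   rate, in (0, 0.5).
#' @param r1,r2 Pole radii in (0, 1); closer to 1 means a sharper resonance.
#' @return Numeric vector of 4 AR coefficients.
#' @export
ar_from_resonances <- function(f1, r1, f2, r2) {
  for (f in c(f1, f2)) {
    if (f <= 0 || f >= 0.5) stop("resonance frequencies must lie in (0, 0.5)",
                                 call. = FALSE)
  }
  for (r in c(r1, r2)) {
    if (r <= 0 || r >= 1) stop("pole radii must lie in (0, 1)", call. = FALSE)
  }
  p1 <- c(1, -2 * r1 * cos(2 * pi * f1), r1^2)
  p2 <- c(1, -2 * r2 * cos(2 * pi * f2), r2^2)
  -poly_mult(p1, p2)[-1]
}

# Stationarity: roots of 1 - a1 z - ... - ap z^p must lie outside the unit circle.
ar_is_stable <- function(a) {
  all(Mod(polyroot(c(1, -a))) > 1 + 1e-10)
}

# Stationary standard deviation of an AR(p) process with unit innovation
# variance, via the companion-form Lyapunov equation vec(P) = (I - F(x)F)^-1 vec(Q).
ar_stationary_sd <- function(a) {
  p <- length(a)
  F <- matrix(0, p, p)
  F[1, ] <- a
  if (p > 1) F[cbind(2:p, 1:(p - 1))] <- 1
  Q <- matrix(0, p, p)
  Q[1, 1] <- 1
  vecP <- solve(diag(p * p) - kronecker(F, F), as.vector(Q))
  sqrt(matrix(vecP, p, p)[1, 1])
}

# Simulate n samples of a unit-variance AR process (innovations already drawn
# upstream from the session RNG); burn-in discards transients.
ar_simulate_unit <- function(n, a, burn = 256L) {
  e <- rnorm(n + burn)
  x <- stats::filter(e, a, method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)]) / ar_stationary_sd(a)
}

#' Default synthetic-signal parameters
#'
#' Returns the parameter set under which the simulator emulates the
#' acquisition setup: 4 sEMG channels at 1927 Hz (arbitrary units, baseline
#' noise sd `sigma0`), one triaxial accelerometer at 148 Hz clipped to
#' +/- 1.5 g. Hand-shape classes differ in their per-channel activation
#' amplitudes (12..18 `sigma0`) and in the centre frequency of their AR(4)
#' spectra; the maximal-voluntary-contraction amplitude used for threshold
#' calibration is 20 `sigma0`. Movements are biphasic 0.4 g pulses: U/D share
#' the vertical axis (z, axis 3) with opposite signs, R/L the horizontal axis
#' (y, axis 2). Gravity is (1, 0, 0) g for palm-Inward and (0, 0, 1) g for
#' palm-Downward.
#'
#' @param sigma0 Baseline sEMG noise standard deviation (a.u.).
#' @param amplitude_jitter_sd Standard deviation of the multiplicative
#'   log-normal amplitude jitter applied per gesture execution.
#' @return A list of class `synth_params`.
#' @export
default_synth_params <- function(sigma0 = 1, amplitude_jitter_sd = 0.05) {
  assert_scalar_number(sigma0, "sigma0", positive = TRUE)
  n_class <- N_HANDSHAPES
  n_chan <- 4L

  # distinct, fixed activation pattern per (class, channel); range [12, 18]*sigma0
  w <- outer(seq_len(n_class), seq_len(n_chan),
             function(c, k) (1 + sin(1.7 * c * k + c)) / 2)
  amplitude <- (12 + 6 * w) * sigma0

  # class-specific resonance, slight per-channel detuning; common broad second pole
  ar <- vector("list", n_class)
  for (c in seq_len(n_class)) {
    f_c <- 0.04 + 0.3 * (c - 1) / (n_class - 1)
    ar[[c]] <- lapply(seq_len(n_chan), function(k) {
      ar_from_resonances(f_c + 0.008 * (k - 1), 0.75, 0.42, 0.4)
    })
  }

  params <- list(
    emg_rate = 1927,
    acc_rate = 148,
    n_channels = n_chan,
    sigma0 = sigma0,
    amplitude = amplitude,
    ar = ar,
    amplitude_jitter_sd = amplitude_jitter_sd,
    mvc_amplitude = 20 * sigma0,
    downward_amplitude = rep(12 * sigma0, n_chan),
    downward_ar = lapply(seq_len(n_chan),
                         function(k) ar_from_resonances(0.2, 0.5, 0.42, 0.3)),
    gravity = list(Inward = c(1, 0, 0), Downward = c(0, 0, 1)),
    movement_axis = c(U = 3L, D = 3L, R = 2L, L = 2L),
    movement_sign = c(U = 1, D = -1, R = 1, L = -1),
    movement_amplitude = 0.4,
    movement_bob = 0.2,
    acc_noise_sd = 0.02,
    acc_clip = 1.5,
    envelope_edge = 0.1
  )
  class(params) <- "synth_params"
  validate_synth_params(params)
  params
}

validate_synth_params <- function(params) {
  stopifnot(is.list(params))
  if (min(params$amplitude) < 5 * params$sigma0) {
    stop("every class/channel amplitude must be at least 5 * sigma0 ",
         "(detectable bursts)", call. = FALSE)
  }
  all_ar <- c(unlist(params$ar, recursive = FALSE), params$downward_ar)
  ok <- vapply(all_ar, ar_is_stable, logical(1))
  if (!all(ok)) {
    stop("unstable AR filter in synth params (roots must lie inside the unit circle)",
         call. = FALSE)
  }
  invisible(params)
}
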