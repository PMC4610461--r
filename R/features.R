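# Component feature extraction from an active segment.
#
# Three feature sets feed the three component classifiers:
#   * palm orientation  — per-axis ACC means + variance of the resultant
#     magnitude (4-D vector);
#   * hand movement     — each ACC axis time-normalised to 32 points;
#   * hand shape        — per sEMG frame (128 samples, step 64), per channel,
#     MAV followed by 4 Burg AR coefficients: 4 x (1+4) = 20-D frames.

#' Palm-orientation features of an ACC segment
#'
#' Per-axis means plus the unbiased variance of the per-sample resultant
#' magnitude `sqrt(x^2 + y^2 + z^2)`. A static palm-downward hold has a
#' near-zero resultant variance; a moving inward gesture does not.
#'
#' @param acc_segment Numeric matrix 3 x n (g), n >= 2.
#' @return One-row tibble: `mean_x`, `mean_y`, `mean_z`, `resultant_var`.
#' @export
orientation_features <- function(acc_segment) {
  stopifnot(is.matrix(acc_segment), nrow(acc_segment) == 3L)
  if (ncol(acc_segment) < 2L) {
    stop("need at least 2 ACC samples (variance undefined)", call. = FALSE)
  }
  m <- rowMeans(acc_segment)
  r <- sqrt(colSums(acc_segment^2))
  tibble::tibble(mean_x = m[1], mean_y = m[2], mean_z = m[3],
                 resultant_var = var(r))
}

#' Time-normalised movement sequence
#'
#' Linearly interpolates each ACC axis onto `n_points` equally spaced points
#' spanning the first to the last sample, removing execution-speed
#' differences before DTW comparison. Endpoints are pinned to the source
#' endpoints.
#'
#' @param acc_segment Numeric matrix 3 x n (g), n >= 2.
#' @param n_points Number of output points per axis (default 32).
#' @return Numeric matrix 3 x `n_points` with attribute `source_length`.
#' @export
movement_sequence <- function(acc_segment, n_points = 32L) {
  stopifnot(is.matrix(acc_segment), nrow(acc_segment) == 3L)
  n <- ncol(acc_segment)
  if (n < 2L) stop("need at least 2 ACC samples", call. = FALSE)
  xout <- seq(1, n, length.out = n_points)
  out <- t(apply(acc_segment, 1L, function(y) {
    approx(seq_len(n), y, xout = xout)$y
  }))
  attr(out, "source_length") <- n
  out
}

#' Mean absolute value of a frame
#'
#' @param frame Non-empty numeric vector.
#' @return The mean of the absolute values.
#' @export
mav <- function(frame) {
  if (length(frame) == 0L) stop("empty frame", call. = FALSE)
  mean(abs(frame))
}

#' Autoregressive coefficients of a frame (Burg)
#'
#' Burg-method AR estimate with the sign convention
#' `x_t ~ a1*x_{t-1} + ... + a_p*x_{t-p} + e_t`. AR coefficients capture the
#' frame's spectral shape and are invariant to amplitude scaling.
#'
#' @param frame Numeric vector, length > `2 * order`, non-constant.
#' @param order Model order (default 4).
#' @return Numeric vector of `order` coefficients.
#' @export
ar_coefficients <- function(frame, order = 4L) {
  if (length(frame) <= 2L * order) {
    stop("frame too short for the requested AR order", call. = FALSE)
  }
  if (var(frame) < .Machine$double.eps) {
    stop("degenerate frame: constant signal has no AR representation",
         call. = FALSE)
  }
  fit <- ar.burg(frame, aic = FALSE, order.max = order, demean = TRUE)
  as.numeric(fit$ar)
}

#' Hand-shape observation sequence from an sEMG segment
#'
#' Frames the segment with a 128-sample window stepped by 64 samples (frames
#' that would overrun the segment end are dropped) and stacks, per frame,
#' the per-channel feature blocks `[MAV, a1, a2, a3, a4]` in channel order
#' Ch1..Ch4, giving 20-dimensional frame vectors for 4 channels.
#'
#' @param emg_segment Numeric matrix channels x n, n >= `frame_window`.
#' @param frame_window Frame length in samples (default 128).
#' @param frame_step Step between frames in samples (default 64).
#' @param ar_order AR model order per channel (default 4).
#' @return Numeric matrix T x (channels * (1 + ar_order)); attribute
#'   `frame_window`/`frame_step` record the framing.
#' @export
emg_observation_sequence <- function(emg_segment, frame_window = 128L,
                                     frame_step = 64L, ar_order = 4L) {
  stopifnot(is.matrix(emg_segment))
  n <- ncol(emg_segment)
  n_chan <- nrow(emg_segment)
  if (n < frame_window) {
    stop("segment too short for hand-shape classification ",
         sprintf("(%d < %d samples)", n, frame_window), call. = FALSE)
  }
  starts <- seq.int(1L, n - frame_window + 1L, by = frame_step)
  d <- n_chan * (1L + ar_order)
  out <- matrix(NA_real_, length(starts), d)
  for (t in seq_along(starts)) {
    fr <- emg_segment[, starts[t]:(starts[t] + frame_window - 1L),
                      drop = FALSE]
    feats <- numeric(0)
    for (k in seq_len(n_chan)) {
      feats <- c(feats, mav(fr[k, ]), ar_coefficients(fr[k, ], ar_order))
    }
    out[t, ] <- feats
  }
  attr(out, "frame_window") <- as.integer(frame_window)
  attr(out, "frame_step") <- as.integer(frame_step)
  out
}
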