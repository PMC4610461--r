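# Active-segment detection from sEMG.
#
# The detector squares the across-channel mean signal, averages it in an
# overlapped sliding window (64 points, step 1), and opens/closes segments
# at crossings of a single on/off threshold calibrated as a small fraction
# of the maximal-voluntary-contraction energy above the background-noise
# energy floor. Sample intervals are 0-based and half-open throughout.

#' Overlapped sliding averaged energy
#'
#' The value at position `k` is the mean, over the window starting at sample
#' `k`, of the squared across-channel mean signal. Index `k` is aligned to
#' the window's first sample.
#'
#' @param emg Numeric matrix (channels x samples) or vector (one channel).
#' @param window Window length in samples (default 64).
#' @param step Step between window starts in samples (default 1, i.e. fully
#'   overlapped).
#' @param rate Optional sampling rate (Hz), carried for time conversion.
#' @return An object of class `energy_series`: list with `values`, `window`,
#'   `step`, `rate`, and `degenerate` flag (input shorter than one window).
#' @export
sliding_average_energy <- function(emg, window = 64L, step = 1L, rate = NULL) {
  if (is.vector(emg)) emg <- matrix(emg, nrow = 1L)
  stopifnot(is.matrix(emg), window >= 1L, step >= 1L)
  n <- ncol(emg)
  if (n < window) {
    return(structure(list(values = numeric(0), window = as.integer(window),
                          step = as.integer(step), rate = rate,
                          degenerate = TRUE),
                     class = "energy_series"))
  }
  s <- colMeans(emg)
  cs <- c(0, cumsum(s^2))
  starts <- seq.int(1L, n - window + 1L, by = step)
  values <- (cs[starts + window] - cs[starts]) / window
  structure(list(values = values, window = as.integer(window),
                 step = as.integer(step), rate = rate, degenerate = FALSE),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %d values | window %d | step %d%s\n",
              length(x$values), x$window, x$step,
              if (isTRUE(x$degenerate)) " | degenerate" else ""))
  invisible(x)
}

#' Calibrate the segmentation threshold
#'
#' The single on/off threshold is placed a small fraction of the way from
#' the background-noise energy floor up to the maximal-voluntary-contraction
#' (MVC) energy: `threshold = E_noise + fraction * (E_mvc - E_noise)`, where
#' each `E` is the mean sliding-average energy of the respective recording.
#'
#' @param mvc_session A [recording_session()] of a sustained maximal grasp.
#' @param noise_session A rest-only [recording_session()].
#' @param fraction Fraction in (0, 1]; 2% is the standard setting.
#' @param min_duration Segments shorter than this (seconds) are discarded.
#' @param window,step Energy window parameters.
#' @return A list of class `threshold_spec` with equal `on_threshold` and
#'   `off_threshold`.
#' @export
calibrate_threshold <- function(mvc_session, noise_session, fraction = 0.02,
                                min_duration = 0.25, window = 64L, step = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  e_mvc <- mean(sliding_average_energy(mvc_session$emg, window, step)$values)
  e_noise <- mean(sliding_average_energy(noise_session$emg, window, step)$values)
  if (!is.finite(e_mvc) || !is.finite(e_noise)) {
    stop("calibration recordings too short for one energy window",
         call. = FALSE)
  }
  if (e_mvc <= e_noise) {
    stop("invalid calibration recordings: MVC energy must exceed noise energy",
         call. = FALSE)
  }
  thr <- e_noise + fraction * (e_mvc - e_noise)
  structure(list(on_threshold = thr, off_threshold = thr, fraction = fraction,
                 min_duration = min_duration,
                 e_mvc = e_mvc, e_noise = e_noise),
            class = "threshold_spec")
}

#' Detect active segments from an energy series
#'
#' A segment opens at the first energy index whose value exceeds the on
#' threshold and closes at the first subsequent index at or below the off
#' threshold (or at the series end). Segments shorter than `min_duration`
#' are discarded. Sample indices are 0-based half-open `[emg_on, emg_off)`
#' and are reported at the centre of the crossing window: the windowed mean
#' crosses the threshold when the instantaneous energy crossing sits near
#' the window midpoint, so centring is the unbiased sample-domain estimate
#' of both boundaries (start-of-window reporting would shift every boundary
#' half a window early).
#'
#' @param energy An [sliding_average_energy()] result.
#' @param spec A [calibrate_threshold()] result (or compatible list).
#' @param emg_rate EMG sampling rate in Hz.
#' @return A tibble with columns `onset_s`, `offset_s`, `emg_on`, `emg_off`,
#'   in temporal order, non-overlapping; zero rows if nothing is active.
#' @export
detect_active_segments <- function(energy, spec, emg_rate) {
  if (isTRUE(energy$degenerate)) {
    stop("degenerate energy series (input shorter than one window)",
         call. = FALSE)
  }
  assert_scalar_number(emg_rate, "emg_rate", positive = TRUE)
  v <- energy$values
  active <- v > spec$on_threshold
  empty <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          emg_on = integer(), emg_off = integer())
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values] + 1L  # first index at/below threshold (may be past end)
  # energy index k (1-based, window start at sample k-1) -> centre of window
  centre <- energy$window %/% 2L
  emg_on <- (on_idx - 1L) * energy$step + centre
  emg_off <- (off_idx - 1L) * energy$step + centre
  onset_s <- emg_on / emg_rate
  offset_s <- emg_off / emg_rate
  keep <- (offset_s - onset_s) >= spec$min_duration
  tibble::tibble(onset_s = onset_s, offset_s = offset_s,
                 emg_on = as.integer(emg_on),
                 emg_off = as.integer(emg_off))[keep, ]
}

#' Map EMG segment boundaries into the ACC stream
#'
#' Rescales each 0-based half-open EMG sample interval by the rate ratio,
#' rounding outward, and clips to the ACC stream length. Segments whose
#' mapped ACC span is shorter than 2 samples are flagged unusable for the
#' ACC-based (orientation/movement) features.
#'
#' @param segments Tibble with `emg_on`, `emg_off` (from
#'   [detect_active_segments()]).
#' @param emg_rate,acc_rate Sampling rates in Hz.
#' @param acc_len Optional ACC stream length in samples, for clipping.
#' @return The input tibble with added `acc_on`, `acc_off`, `acc_usable`.
#' @export
map_segment_to_acc <- function(segments, emg_rate, acc_rate, acc_len = NULL) {
  assert_scalar_number(emg_rate, "emg_rate", positive = TRUE)
  assert_scalar_number(acc_rate, "acc_rate", positive = TRUE)
  ratio <- acc_rate / emg_rate
  acc_on <- floor(segments$emg_on * ratio)
  acc_off <- ceiling(segments$emg_off * ratio)
  if (!is.null(acc_len)) {
    acc_on <- pmin(acc_on, acc_len)
    acc_off <- pmin(acc_off, acc_len)
  }
  dplyr::mutate(segments,
                acc_on = as.integer(acc_on),
                acc_off = as.integer(acc_off),
                acc_usable = (acc_off - acc_on) >= 2L)
}

#' Segment a whole session
#'
#' Convenience wrapper: energy, detection and ACC mapping in one call.
#'
#' @param session A [recording_session()].
#' @param spec Threshold spec from [calibrate_threshold()].
#' @param window,step Energy window parameters.
#' @return Segment tibble with EMG and ACC sample ranges.
#' @export
segment_session <- function(session, spec, window = 64L, step = 1L) {
  energy <- sliding_average_energy(session$emg, window, step,
                                   rate = session$emg_rate)
  segs <- detect_active_segments(energy, spec, session$emg_rate)
  map_segment_to_acc(segs, session$emg_rate, session$acc_rate,
                     acc_len = ncol(session$acc))
}

#' Segment ranges from ground-truth annotations
#'
#' Converts annotated onset/offset times into the same 0-based half-open
#' EMG/ACC sample ranges the detector produces, for supervised training and
#' for scoring detection against ground truth.
#'
#' @param session An annotated [recording_session()].
#' @return Segment tibble with `label` column.
#' @export
segments_from_annotations <- function(session) {
  ann <- session$annotations
  segs <- tibble::tibble(
    onset_s = ann$onset_s, offset_s = ann$offset_s,
    emg_on = as.integer(floor(ann$onset_s * session$emg_rate)),
    emg_off = as.integer(pmin(ncol(session$emg),
                              floor(ann$offset_s * session$emg_rate))))
  segs <- map_segment_to_acc(segs, session$emg_rate, session$acc_rate,
                             acc_len = ncol(session$acc))
  segs$label <- ann$label
  segs
}

# Slice helpers for 0-based half-open sample ranges.
extract_emg <- function(session, emg_on, emg_off) {
  session$emg[, (emg_on + 1L):emg_off, drop = FALSE]
}

extract_acc <- function(session, acc_on, acc_off) {
  session$acc[, (acc_on + 1L):acc_off, drop = FALSE]
}
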