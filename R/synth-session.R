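# Synthetic session generator.
#
# A session is a wall-clock timeline of alternating rests and gestures. sEMG
# is baseline Gaussian noise on every channel; during a gesture a burst of
# AR(4)-filtered noise, scaled by a trapezoidal envelope of the class
# amplitude, is superimposed. The accelerometer records the orientation
# gravity vector plus, for inward gestures, a biphasic sine pulse on the
# movement axis, plus noise, clipped to the hardware range. EMG and ACC run
# on independent sample clocks over the same timeline.

#' Specify one gesture
#'
#' @param handshape Hand-shape index 1..13 (ignored for downward gestures).
#' @param movement One of `"U"`, `"D"`, `"R"`, `"L"` (ignored for downward).
#' @param orientation `"Inward"` (default) or `"Downward"`.
#' @param duration Gesture duration in seconds (> 0).
#' @return A list of class `gesture_spec` with the derived `label`.
#' @export
gesture_spec <- function(handshape = NA, movement = NA,
                         orientation = "Inward", duration = 1) {
  if (!orientation %in% ORIENTATION_CLASSES) {
    stop("`orientation` must be \"Inward\" or \"Downward\"", call. = FALSE)
  }
  assert_scalar_number(duration, "duration", positive = TRUE)
  if (orientation == "Downward") {
    label <- DEFAULT_LABEL
    handshape <- NA_integer_
    movement <- NA_character_
  } else {
    label <- decode_gesture("Inward", movement, handshape)
    handshape <- as.integer(handshape)
  }
  structure(list(handshape = handshape, movement = movement,
                 orientation = orientation, duration = duration,
                 label = label),
            class = "gesture_spec")
}

gesture_spec_from_label <- function(label, duration = 1) {
  p <- parse_gesture_label(label)
  gesture_spec(p$handshape, p$movement, p$orientation, duration)
}

#' Define a session protocol
#'
#' @param gestures A list of [gesture_spec()] objects, in execution order.
#' @param rest_range Length-2 numeric, the (min, max) seconds of natural rest
#'   between gestures; must lie within `[0.5, 5]`. Default `c(1, 2)`.
#' @param seed Integer seed driving every random draw of the simulation.
#' @return A list of class `session_protocol`.
#' @export
session_protocol <- function(gestures, rest_range = c(1, 2), seed = 1L) {
  if (!is.list(gestures) ||
      !all(vapply(gestures, inherits, logical(1), "gesture_spec"))) {
    stop("`gestures` must be a list of gesture_spec objects", call. = FALSE)
  }
  if (length(rest_range) != 2L || rest_range[1] > rest_range[2]) {
    stop("`rest_range` must be (min, max) with min <= max", call. = FALSE)
  }
  if (rest_range[1] < 0.5 || rest_range[2] > 5) {
    stop("`rest_range` must lie within [0.5, 5] seconds", call. = FALSE)
  }
  structure(list(gestures = gestures, rest_range = rest_range,
                 seed = as.integer(seed)),
            class = "session_protocol")
}

#' Build a protocol from gesture labels
#'
#' Durations are drawn uniformly from `duration_range` under `seed`.
#'
#' @param labels Character vector of valid gesture labels.
#' @param seed Integer seed.
#' @param duration_range Length-2 numeric range of gesture durations (s).
#' @param rest_range Passed to [session_protocol()].
#' @return A `session_protocol`.
#' @export
protocol_from_labels <- function(labels, seed = 1L,
                                 duration_range = c(0.9, 1.1),
                                 rest_range = c(1, 2)) {
  durations <- withr::with_seed(seed,
    runif(length(labels), duration_range[1], duration_range[2]))
  gestures <- purrr::map2(labels, durations, gesture_spec_from_label)
  session_protocol(gestures, rest_range = rest_range, seed = seed)
}

#' Random protocol over the 53 coded gestures
#'
#' @param n_gestures Number of gestures.
#' @param seed Integer seed.
#' @param labels Pool of labels to draw from (default: all 53).
#' @inheritParams protocol_from_labels
#' @return A `session_protocol`.
#' @export
random_protocol <- function(n_gestures, seed = 1L, labels = valid_gesture_labels(),
                            duration_range = c(0.9, 1.1), rest_range = c(1, 2)) {
  drawn <- withr::with_seed(seed,
    sample(labels, n_gestures, replace = TRUE))
  protocol_from_labels(drawn, seed = seed, duration_range = duration_range,
                       rest_range = rest_range)
}

#' Construct a recording session
#'
#' Container for one synchronised recording: an sEMG matrix
#' (channels x samples, arbitrary units), an ACC matrix (3 x samples, g),
#' their sampling rates, and optional ground-truth annotations.
#'
#' @param emg Numeric matrix, channels x samples.
#' @param acc Numeric matrix, 3 x samples.
#' @param emg_rate,acc_rate Sampling rates in Hz.
#' @param annotations Optional tibble with columns `onset_s`, `offset_s`,
#'   `label`.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(emg, acc, emg_rate = 1927, acc_rate = 148,
                              annotations = NULL) {
  stopifnot(is.matrix(emg), is.matrix(acc), nrow(acc) == 3L)
  assert_scalar_number(emg_rate, "emg_rate", positive = TRUE)
  assert_scalar_number(acc_rate, "acc_rate", positive = TRUE)
  span_diff <- abs(ncol(emg) / emg_rate - ncol(acc) / acc_rate)
  if (span_diff > 1 / acc_rate + 1e-9) {
    stop("emg and acc streams must cover the same wall-clock span ",
         "within one ACC sample period", call. = FALSE)
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                                  label = character())
  }
  structure(list(emg = emg, emg_rate = emg_rate, acc = acc,
                 acc_rate = acc_rate,
                 annotations = tibble::as_tibble(annotations)),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %.2f s | sEMG %d ch @ %g Hz | ACC 3 ax @ %g Hz | %d annotated gesture(s)\n",
    ncol(x$emg) / x$emg_rate, nrow(x$emg), x$emg_rate, x$acc_rate,
    nrow(x$annotations)))
  invisible(x)
}

trapezoid_envelope <- function(n, edge) {
  t <- (seq_len(n) - 0.5) / n
  pmin(1, t / edge, (1 - t) / edge)
}

#' Simulate a recording session
#'
#' Generates synchronised sEMG and ACC streams for a protocol, with
#' ground-truth annotations. Identical protocol and parameters give
#' bit-identical sessions (all randomness is driven by the protocol seed).
#'
#' @param protocol A [session_protocol()].
#' @param params A [default_synth_params()] parameter set.
#' @return A [recording_session()].
#' @export
simulate_session <- function(protocol, params = default_synth_params()) {
  if (!inherits(protocol, "session_protocol")) {
    stop("`protocol` must be a session_protocol", call. = FALSE)
  }
  validate_synth_params(params)
  withr::with_seed(protocol$seed, simulate_session_impl(protocol, params))
}

simulate_session_impl <- function(protocol, params) {
  gestures <- protocol$gestures
  n_g <- length(gestures)
  rr <- protocol$rest_range
  rests <- runif(n_g + 1L, rr[1], rr[2])
  durations <- vapply(gestures, `[[`, numeric(1), "duration")

  onsets <- numeric(n_g)
  t_cur <- 0
  for (i in seq_len(n_g)) {
    t_cur <- t_cur + rests[i]
    onsets[i] <- t_cur
    t_cur <- t_cur + durations[i]
  }
  total <- t_cur + rests[n_g + 1L]
  offsets <- onsets + durations

  emg_n <- max(1L, round(total * params$emg_rate))
  acc_n <- max(1L, round(total * params$acc_rate))
  n_chan <- params$n_channels

  emg <- matrix(rnorm(n_chan * emg_n, sd = params$sigma0), n_chan, emg_n)
  acc <- matrix(params$gravity$Inward, 3L, acc_n)

  for (i in seq_len(n_g)) {
    g <- gestures[[i]]
    i0 <- floor(onsets[i] * params$emg_rate) + 1L
    i1 <- min(emg_n, floor(offsets[i] * params$emg_rate))
    n_s <- i1 - i0 + 1L
    if (n_s < 2L) next
    env <- trapezoid_envelope(n_s, params$envelope_edge)
    jit <- exp(rnorm(1, 0, params$amplitude_jitter_sd))
    if (g$orientation == "Inward") {
      amps <- params$amplitude[g$handshape, ]
      ars <- params$ar[[g$handshape]]
    } else {
      amps <- params$downward_amplitude
      ars <- params$downward_ar
    }
    for (k in seq_len(n_chan)) {
      burst <- amps[k] * jit * env * ar_simulate_unit(n_s, ars[[k]])
      emg[k, i0:i1] <- emg[k, i0:i1] + burst
    }

    j0 <- floor(onsets[i] * params$acc_rate) + 1L
    j1 <- min(acc_n, floor(offsets[i] * params$acc_rate))
    if (j1 < j0) next
    if (g$orientation == "Downward") {
      acc[, j0:j1] <- params$gravity$Downward
    } else {
      ax <- params$movement_axis[[g$movement]]
      phase <- pmin(pmax(((j0:j1 - 0.5) / params$acc_rate - onsets[i]) /
                           durations[i], 0), 1)
      pulse <- params$movement_sign[[g$movement]] * params$movement_amplitude *
        sin(2 * pi * phase)
      acc[ax, j0:j1] <- acc[ax, j0:j1] + pulse
      # slight execution bob along the gravity axis, common to all movements
      acc[1, j0:j1] <- acc[1, j0:j1] + params$movement_bob * sin(pi * phase)^2
    }
  }

  acc <- acc + matrix(rnorm(3L * acc_n, sd = params$acc_noise_sd), 3L, acc_n)
  acc <- pmin(pmax(acc, -params$acc_clip), params$acc_clip)

  ann <- tibble::tibble(
    onset_s = onsets, offset_s = offsets,
    label = vapply(gestures, `[[`, character(1), "label"))
  recording_session(emg, acc, params$emg_rate, params$acc_rate, ann)
}

#' Simulate threshold-calibration recordings
#'
#' Returns a maximal-voluntary-contraction (sustained grasp at the maximal
#' amplitude) session and a rest-only background-noise session, both without
#' annotations, for use with [calibrate_threshold()].
#'
#' @param params Synth parameter set.
#' @param seed Integer seed.
#' @param duration Length of each recording in seconds.
#' @return A list with elements `mvc` and `noise`, both `recording_session`s.
#' @export
simulate_calibration <- function(params = default_synth_params(), seed = 1L,
                                 duration = 5) {
  assert_scalar_number(duration, "duration", positive = TRUE)
  withr::with_seed(seed, {
    emg_n <- round(duration * params$emg_rate)
    acc_n <- round(duration * params$acc_rate)
    n_chan <- params$n_channels
    noise_emg <- matrix(rnorm(n_chan * emg_n, sd = params$sigma0),
                        n_chan, emg_n)
    mvc_emg <- matrix(rnorm(n_chan * emg_n, sd = params$sigma0),
                      n_chan, emg_n)
    for (k in seq_len(n_chan)) {
      mvc_emg[k, ] <- mvc_emg[k, ] +
        params$mvc_amplitude * ar_simulate_unit(emg_n, params$downward_ar[[k]])
    }
    make_acc <- function() {
      a <- matrix(params$gravity$Inward, 3L, acc_n) +
        matrix(rnorm(3L * acc_n, sd = params$acc_noise_sd), 3L, acc_n)
      pmin(pmax(a, -params$acc_clip), params$acc_clip)
    }
    list(
      mvc = recording_session(mvc_emg, make_acc(),
                              params$emg_rate, params$acc_rate),
      noise = recording_session(noise_emg, make_acc(),
                                params$emg_rate, params$acc_rate)
    )
  })
}
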