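# Sliding-average energy and active-segment detection.

energy_series_of <- function(values, window = 64L, step = 1L, rate = 1927) {
  structure(list(values = values, window = as.integer(window),
                 step = as.integer(step), rate = rate, degenerate = FALSE),
            class = "energy_series")
}

thr_spec <- function(thr, min_duration = 0.25) {
  structure(list(on_threshold = thr, off_threshold = thr,
                 fraction = NA_real_, min_duration = min_duration),
            class = "threshold_spec")
}

test_that("sliding average energy matches its windowed definition", {
  # constant channels at value a -> every energy value a^2
  emg <- matrix(3, nrow = 4, ncol = 150)
  e <- sliding_average_energy(emg, window = 64)
  expect_equal(e$values, rep(9, 150 - 64 + 1))

  # all-zero input, length contract 200 - 64 + 1
  e0 <- sliding_average_energy(matrix(0, 2, 200), window = 64)
  expect_equal(e0$values, rep(0, 137))

  # single channel, one unit impulse: 1/64 on the 64 covering windows
  x <- numeric(200)
  x[100] <- 1
  e1 <- sliding_average_energy(x, window = 64)
  expected <- numeric(137)
  expected[(100 - 63):100] <- 1 / 64
  expect_equal(e1$values, expected)

  # shorter than one window -> degenerate empty series
  ed <- sliding_average_energy(matrix(1, 4, 30), window = 64)
  expect_true(ed$degenerate)
  expect_length(ed$values, 0)
})

test_that("threshold calibration interpolates between noise and MVC energies", {
  mk <- function(val) recording_session(matrix(val, 4, 200),
                                        matrix(0, 3, round(200 / 1927 * 148)),
                                        1927, 148)
  # E_noise = 0, E_mvc = 100, fraction 0.02 -> threshold 2
  spec <- calibrate_threshold(mk(10), mk(0), fraction = 0.02)
  expect_equal(spec$on_threshold, 2)
  expect_equal(spec$off_threshold, spec$on_threshold)
  # fraction 1 -> threshold = E_mvc
  expect_equal(calibrate_threshold(mk(10), mk(0), fraction = 1)$on_threshold, 100)
  expect_error(calibrate_threshold(mk(0), mk(10)), "must exceed")

  # synthetic MVC and rest recordings: threshold strictly between the means
  spec2 <- test_threshold()
  expect_gt(spec2$on_threshold, spec2$e_noise)
  expect_lt(spec2$on_threshold, spec2$e_mvc)
})

test_that("detection opens at upward crossings and closes at downward crossings", {
  # everywhere below threshold -> empty
  e <- energy_series_of(rep(0.5, 500))
  expect_equal(nrow(detect_active_segments(e, thr_spec(1), 1927)), 0L)

  # one rectangular supra-threshold block of exactly 1.0 s; boundaries sit
  # at the crossings, reported at the centre of the crossing window
  v <- c(rep(0, 100), rep(5, 1927), rep(0, 100))
  segs <- detect_active_segments(energy_series_of(v), thr_spec(1), 1927)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$emg_on, 100L + 32L)
  expect_equal(segs$emg_off, 100L + 1927L + 32L)
  expect_equal(segs$offset_s - segs$onset_s, 1.0)

  # active run to the very end closes at the series end
  v2 <- c(rep(0, 100), rep(5, 1000))
  segs2 <- detect_active_segments(energy_series_of(v2), thr_spec(1), 1927)
  expect_equal(segs2$emg_off, 1100L + 32L)

  # blips shorter than min_duration are discarded
  v3 <- c(rep(0, 100), rep(5, 50), rep(0, 100))
  expect_equal(nrow(detect_active_segments(energy_series_of(v3),
                                           thr_spec(1), 1927)), 0L)
  expect_error(detect_active_segments(
    sliding_average_energy(matrix(0, 1, 10), 64), thr_spec(1), 1927),
    "degenerate")
})

test_that("EMG-to-ACC range mapping rounds outward and preserves duration", {
  segs <- tibble::tibble(onset_s = 0, offset_s = 1,
                         emg_on = 0L, emg_off = 1927L)
  m <- map_segment_to_acc(segs, 1927, 148)
  expect_equal(m$acc_on, 0L)
  expect_true(abs((m$acc_off - m$acc_on) - 148L) <= 1L)
  expect_true(m$acc_usable)

  # random ranges: mapped duration within one ACC sample period
  withr::with_seed(4, {
    for (i in 1:25) {
      on <- sample.int(5e4, 1)
      off <- on + sample.int(5e3, 1)
      s <- tibble::tibble(onset_s = NA, offset_s = NA,
                          emg_on = on, emg_off = off)
      m <- map_segment_to_acc(s, 1927, 148)
      emg_dur <- (off - on) / 1927
      acc_dur <- (m$acc_off - m$acc_on) / 148
      expect_lt(abs(acc_dur - emg_dur), 2 / 148)
      expect_gte(m$acc_on * 1927 / 148, on - 1927 / 148)
    }
  })

  # degenerate mapped span flagged unusable
  tiny <- tibble::tibble(onset_s = 0, offset_s = 0.005, emg_on = 0L, emg_off = 10L)
  expect_false(map_segment_to_acc(tiny, 1927, 148)$acc_usable)
})

test_that("lowering the threshold fraction widens segments without losing any", {
  sess <- simulate_session(random_protocol(6, seed = 31), test_params())
  cal <- simulate_calibration(test_params(), seed = 8)
  energy <- sliding_average_energy(sess$emg, rate = sess$emg_rate)
  fractions <- c(0.3, 0.1, 0.05, 0.02, 0.01)
  prev <- NULL
  for (f in fractions) {
    spec <- calibrate_threshold(cal$mvc, cal$noise, fraction = f)
    segs <- detect_active_segments(energy, spec, sess$emg_rate)
    if (!is.null(prev)) {
      expect_gte(nrow(segs), nrow(prev))
      # every previously detected segment lies inside one wider segment
      for (i in seq_len(nrow(prev))) {
        inside <- segs$onset_s <= prev$onset_s[i] + 1e-9 &
          segs$offset_s >= prev$offset_s[i] - 1e-9
        expect_true(any(inside))
      }
    }
    prev <- segs
  }
})

test_that("energy of concatenated sessions matches away from the junction", {
  withr::with_seed(99, {
    a <- matrix(rnorm(4 * 500), 4)
    b <- matrix(rnorm(4 * 400), 4)
  })
  ea <- sliding_average_energy(a)$values
  eb <- sliding_average_energy(b)$values
  eab <- sliding_average_energy(cbind(a, b))$values
  expect_equal(eab[seq_along(ea)], ea)
  expect_equal(tail(eab, length(eb)), eb)
})
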