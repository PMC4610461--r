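# Synthetic signal generator.

test_that("an empty protocol yields baseline noise only and no annotations", {
  proto <- session_protocol(list(), seed = 5)
  sess <- simulate_session(proto, test_params())
  expect_s3_class(sess, "recording_session")
  expect_equal(nrow(sess$annotations), 0L)
  # pure baseline: per-channel sd close to sigma0, no bursts anywhere
  sds <- apply(sess$emg, 1, sd)
  expect_true(all(abs(sds - 1) < 0.1))
  expect_lt(max(abs(sess$emg)), 6)
})

test_that("the simulator is deterministic in the protocol seed", {
  proto <- random_protocol(4, seed = 21)
  s1 <- simulate_session(proto, test_params())
  s2 <- simulate_session(proto, test_params())
  expect_identical(s1, s2)
  s3 <- simulate_session(random_protocol(4, seed = 22), test_params())
  expect_false(identical(s1$emg, s3$emg))
})

test_that("invalid protocols and parameters are rejected", {
  expect_error(session_protocol(list(), rest_range = c(2, 1)), "min <= max")
  expect_error(session_protocol(list(), rest_range = c(0.1, 1)), "0.5")
  bad <- test_params()
  bad$ar[[1]][[1]] <- c(2, 0, 0, 0)  # explosive filter
  expect_error(simulate_session(random_protocol(1, seed = 1), bad),
               "unstable AR filter")
})

test_that("the segmenter recovers every annotated gesture from a simulated session", {
  proto <- random_protocol(10, seed = 42)
  sess <- simulate_session(proto, test_params())
  segs <- segment_session(sess, test_threshold())
  expect_equal(nrow(segs), 10L)
  expect_lt(max(abs(segs$onset_s - sess$annotations$onset_s)), 0.05)
  expect_lt(max(abs(segs$offset_s - sess$annotations$offset_s)), 0.05)
})

test_that("burst-to-rest energy ratio is at least 25 on every channel", {
  proto <- random_protocol(8, seed = 3,
                           labels = paste0(1:13, "U"))  # inward bursts
  sess <- simulate_session(proto, test_params())
  ann <- sess$annotations
  in_burst <- rep(FALSE, ncol(sess$emg))
  for (i in seq_len(nrow(ann))) {
    in_burst[(floor(ann$onset_s[i] * sess$emg_rate) + 1):
               floor(ann$offset_s[i] * sess$emg_rate)] <- TRUE
  }
  for (k in 1:4) {
    ratio <- mean(sess$emg[k, in_burst]^2) / mean(sess$emg[k, !in_burst]^2)
    expect_gte(ratio, 25)
  }
})

test_that("a long single-class burst recovers its generating AR(4) coefficients", {
  params <- test_params()
  proto <- protocol_from_labels("4R", seed = 9,
                                duration_range = c(8, 8))
  sess <- simulate_session(proto, params)
  ann <- sess$annotations
  # fit on the trapezoid plateau (constant-amplitude, stationary part)
  i0 <- floor((ann$onset_s + 0.15 * (ann$offset_s - ann$onset_s)) *
                sess$emg_rate)
  i1 <- floor((ann$offset_s - 0.15 * (ann$offset_s - ann$onset_s)) *
                sess$emg_rate)
  expect_gte(i1 - i0, 1e4)
  for (k in 1:2) {
    a_hat <- ar_coefficients(sess$emg[k, i0:i1], order = 4)
    expect_lt(max(abs(a_hat - params$ar[[4]][[k]])), 0.1)
  }
})

test_that("ACC over a downward segment averages to the downward gravity vector", {
  params <- test_params()
  proto <- protocol_from_labels(rep("00", 3), seed = 13)
  sess <- simulate_session(proto, params)
  segs <- segments_from_annotations(sess)
  for (i in seq_len(nrow(segs))) {
    # drop the outward-rounded edge samples, which straddle the hold's start/end
    a <- sess$acc[, (segs$acc_on[i] + 2):(segs$acc_off[i] - 1)]
    se <- params$acc_noise_sd / sqrt(ncol(a))
    expect_true(all(abs(rowMeans(a) - params$gravity$Downward) < 3 * se))
  }
})

test_that("toy code tables are valid, distinct and reproducible", {
  t1 <- make_toy_code_table(1, seed = 2)
  expect_equal(nrow(t1), 1L)
  expect_equal(decode_character(t1$gesture1, t1$gesture2, t1),
               t1$character_id)

  # 223 characters -> 223 distinct pairs -> 446 gesture slots in one repetition
  t223 <- make_toy_code_table(223, seed = 5)
  expect_equal(nrow(t223), 223L)
  expect_equal(anyDuplicated(paste(t223$gesture1, t223$gesture2)), 0L)
  seqn <- character_gesture_sequence(t223)
  expect_length(seqn, 446L)
  expect_true(all(c(t223$gesture1, t223$gesture2) %in% valid_gesture_labels()))

  expect_identical(t223, make_toy_code_table(223, seed = 5))
  expect_error(make_toy_code_table(53^2 + 1, seed = 1), "distinct ordered pairs")
  expect_error(make_toy_code_table(0, seed = 1), "positive integer")
})

test_that("gesture label grammar accepts exactly the 53 coded labels", {
  labs <- valid_gesture_labels()
  expect_length(labs, 53L)
  expect_length(unique(labs), 53L)
  for (l in labs) {
    p <- parse_gesture_label(l)
    expect_true(p$orientation %in% c("Inward", "Downward"))
  }
  expect_error(parse_gesture_label("14U"), "invalid")
  expect_error(parse_gesture_label("0U"), "invalid")
  expect_error(parse_gesture_label("5X"), "invalid")
})
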