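# Shared fixtures. Heavier objects (trained model bundles, end-to-end runs)
# are built lazily once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_params <- function() fixture("params", default_synth_params)

test_threshold <- function() {
  fixture("threshold", function() {
    cal <- simulate_calibration(test_params(), seed = 7)
    calibrate_threshold(cal$mvc, cal$noise)
  })
}

# Small-scale trained bundle shared by the pipeline tests (reduced training
# size relative to the full study conditions keeps the suite fast; the
# full-scale conditions are exercised in the end-to-end accuracy suite).
test_models <- function() {
  fixture("models", function() {
    train_models(test_params(), pipeline_config(seed = 11),
                 reps_handshape = 6L, reps_movement = 5L,
                 reps_orientation = 6L)
  })
}

# Observation sequences for one synthetic burst of a given hand-shape class.
burst_observation <- function(handshape, movement = "R", seed = 1L,
                              duration = 1) {
  proto <- protocol_from_labels(paste0(handshape, movement), seed = seed,
                                duration_range = c(duration, duration))
  sess <- simulate_session(proto, test_params())
  segs <- segments_from_annotations(sess)
  emg_observation_sequence(
    sess$emg[, (segs$emg_on[1] + 1):segs$emg_off[1], drop = FALSE])
}

# One full end-to-end cycle at the study-scale conditions: train at
# `reps_handshape` repetitions per hand shape / 10 per movement, recognise a
# held-out continuous session covering the 53 gesture classes, and return
# predictions with ground truth. Cached per seed.
e2e_run <- function(seed, reps_handshape = 30L, test_reps = 2L) {
  fixture(paste0("e2e_", seed, "_", reps_handshape), function() {
    params <- test_params()
    cfg <- pipeline_config(seed = seed)
    models <- train_models(params, cfg, reps_handshape = reps_handshape,
                           reps_movement = 10L, reps_orientation = 20L)
    labels <- rep(valid_gesture_labels(), test_reps)
    proto <- protocol_from_labels(
      withr::with_seed(seed + 5000L, sample(labels)), seed = seed + 9000L)
    sess <- simulate_session(proto, params)
    res <- run_pipeline(sess, models, cfg = cfg)
    list(models = models, session = sess, result = res,
         truth = sess$annotations$label)
  })
}
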