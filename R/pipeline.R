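# End-to-end pipeline: segmentation -> per-segment orientation ->
# (inward only) movement + hand shape -> coded-gesture label -> character
# decoding, mirroring the framework's block diagram.

#' Pipeline configuration
#'
#' All tunables with their standard defaults: 64-point fully overlapped
#' energy window with a 2% threshold fraction and 0.25 s minimum segment
#' duration; 32-point movement sequences; 128/64 sEMG framing with 4th-order
#' AR features; 5-state, 3-mixture left-to-right HMMs.
#'
#' @param window,step Energy window length and step (samples).
#' @param fraction Threshold fraction of the MVC-above-noise energy.
#' @param min_duration Minimum segment duration (seconds).
#' @param n_points Movement sequence length (points per axis).
#' @param frame_window,frame_step sEMG frame length and step (samples).
#' @param ar_order AR model order per channel.
#' @param n_states,n_mix HMM states and mixtures per state.
#' @param max_iter,tol Baum-Welch iteration cap and stopping tolerance.
#' @param seed Integer seed for model training.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 64L, step = 1L, fraction = 0.02,
                            min_duration = 0.25, n_points = 32L,
                            frame_window = 128L, frame_step = 64L,
                            ar_order = 4L, n_states = 5L, n_mix = 3L,
                            max_iter = 40L, tol = 1e-4, seed = 1L) {
  structure(list(window = as.integer(window), step = as.integer(step),
                 fraction = fraction, min_duration = min_duration,
                 n_points = as.integer(n_points),
                 frame_window = as.integer(frame_window),
                 frame_step = as.integer(frame_step),
                 ar_order = as.integer(ar_order),
                 n_states = as.integer(n_states), n_mix = as.integer(n_mix),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% (.Machine$integer.max - 1L))
}

#' Train the full model bundle on simulated data
#'
#' Simulates seeded training sessions, slices them with their ground-truth
#' annotations, and fits the three component classifiers plus the
#' segmentation threshold: the orientation Gaussian discriminant, the
#' movement DTW template bank (`reps_movement` templates per movement), and
#' one hand-shape HMM per class trained on `reps_handshape` repetitions
#' pooled across the four movements.
#'
#' @param params Synth parameter set ([default_synth_params()]).
#' @param cfg A [pipeline_config()].
#' @param reps_handshape Training repetitions per hand-shape class.
#' @param reps_movement Templates per movement class.
#' @param reps_orientation Downward training gestures (inward features come
#'   from the hand-shape repetitions).
#' @return An object of class `model_bundle`.
#' @export
train_models <- function(params = default_synth_params(),
                         cfg = pipeline_config(),
                         reps_handshape = 30L, reps_movement = 10L,
                         reps_orientation = 20L) {
  seed <- cfg$seed
  orient_feats <- list()
  orient_labels <- character(0)
  move_seqs <- list()
  move_labels <- character(0)
  hmms <- vector("list", N_HANDSHAPES)

  for (c in seq_len(N_HANDSHAPES)) {
    # cycle the movements, rotated per class so every movement is covered
    # across classes even at very small training sizes
    mv <- MOVEMENT_CLASSES[((c - 1L + seq_len(reps_handshape) - 1L) %% 4L) + 1L]
    labels <- paste0(c, mv)
    proto <- protocol_from_labels(labels, seed = derive_seed(seed, c))
    sess <- simulate_session(proto, params)
    segs <- segments_from_annotations(sess)
    obs <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      acc_seg <- extract_acc(sess, segs$acc_on[i], segs$acc_off[i])
      emg_seg <- extract_emg(sess, segs$emg_on[i], segs$emg_off[i])
      orient_feats <- c(orient_feats, list(orientation_features(acc_seg)))
      orient_labels <- c(orient_labels, "Inward")
      move_seqs <- c(move_seqs, list(movement_sequence(acc_seg, cfg$n_points)))
      move_labels <- c(move_labels, parse_gesture_label(segs$label[i])$movement)
      obs[[i]] <- emg_observation_sequence(emg_seg, cfg$frame_window,
                                           cfg$frame_step, cfg$ar_order)
    }
    hmms[[c]] <- fit_hmm(obs, hmm_config(cfg$n_states, cfg$n_mix,
                                         cfg$max_iter, cfg$tol,
                                         seed = derive_seed(seed, 100 + c)))
    hmms[[c]]$class_index <- c
  }

  proto_dn <- protocol_from_labels(rep(DEFAULT_LABEL, reps_orientation),
                                   seed = derive_seed(seed, 200))
  sess_dn <- simulate_session(proto_dn, params)
  segs_dn <- segments_from_annotations(sess_dn)
  for (i in seq_len(nrow(segs_dn))) {
    acc_seg <- extract_acc(sess_dn, segs_dn$acc_on[i], segs_dn$acc_off[i])
    orient_feats <- c(orient_feats, list(orientation_features(acc_seg)))
    orient_labels <- c(orient_labels, "Downward")
  }

  ldc <- fit_ldc(dplyr::bind_rows(orient_feats), orient_labels)

  keep <- unlist(lapply(MOVEMENT_CLASSES, function(cl) {
    head(which(move_labels == cl), reps_movement)
  }))
  bank <- movement_template_bank(move_seqs[keep], move_labels[keep])

  cal <- simulate_calibration(params, seed = derive_seed(seed, 300))
  threshold <- calibrate_threshold(cal$mvc, cal$noise, cfg$fraction,
                                   cfg$min_duration, cfg$window, cfg$step)

  structure(list(ldc = ldc, bank = bank, hmms = hmms, threshold = threshold,
                 cfg = cfg),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> LDC (%s) | DTW templates: %s | %d hand-shape HMMs | threshold %.3g\n",
    paste(x$ldc$classes, collapse = "/"),
    paste(lengths(x$bank), collapse = "/"), length(x$hmms),
    x$threshold$on_threshold))
  invisible(x)
}

classify_segment <- function(session, seg_row, models, cfg) {
  out <- list(orientation = NA_character_, movement = NA_character_,
              handshape = NA_integer_, label = NA_character_)
  if (!isTRUE(seg_row$acc_usable)) return(out)
  acc_seg <- extract_acc(session, seg_row$acc_on, seg_row$acc_off)
  ori <- classify_orientation(models$ldc, orientation_features(acc_seg))
  out$orientation <- ori$class
  if (ori$class == "Downward") {
    out$label <- DEFAULT_LABEL
    return(out)
  }
  mov <- classify_movement(models$bank,
                           movement_sequence(acc_seg, cfg$n_points))
  out$movement <- mov$class
  emg_seg <- extract_emg(session, seg_row$emg_on, seg_row$emg_off)
  if (ncol(emg_seg) < cfg$frame_window) return(out)
  obs <- emg_observation_sequence(emg_seg, cfg$frame_window, cfg$frame_step,
                                  cfg$ar_order)
  hs <- classify_handshape(models$hmms, obs)
  out$handshape <- hs$class
  out$label <- decode_gesture("Inward", mov$class, hs$class)
  out
}

#' Run the recognition pipeline on a session
#'
#' Segments the session, classifies palm orientation per segment, sends
#' inward segments on to the movement and hand-shape classifiers, fuses the
#' component decisions into coded-gesture labels, and (when a code table is
#' supplied) decodes consecutive gesture pairs into characters. When the
#' session carries ground-truth annotations and the detected segment count
#' matches, gesture- and character-level evaluation reports are attached.
#'
#' @param session A [recording_session()].
#' @param models A [train_models()] bundle.
#' @param table Optional code table for character decoding.
#' @param cfg A [pipeline_config()] (defaults to the bundle's).
#' @return An object of class `pipeline_result` with `segments`, `gestures`,
#'   `characters`, and optional `report_gestures` / `report_characters`.
#' @export
run_pipeline <- function(session, models, table = NULL, cfg = NULL) {
  stopifnot(inherits(models, "model_bundle"))
  cfg <- cfg %||% models$cfg
  segs <- segment_session(session, models$threshold, cfg$window, cfg$step)

  res <- purrr::map(seq_len(nrow(segs)), function(i) {
    tryCatch(classify_segment(session, segs[i, ], models, cfg),
             error = function(e) {
               stop(sprintf("segment %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  gestures <- tibble::tibble(
    segment = seq_len(nrow(segs)),
    onset_s = segs$onset_s, offset_s = segs$offset_s,
    orientation = purrr::map_chr(res, "orientation"),
    movement = purrr::map_chr(res, "movement"),
    handshape = purrr::map_int(res, "handshape"),
    label = purrr::map_chr(res, "label"))

  characters <- NULL
  if (!is.null(table) && nrow(gestures) >= 2L) {
    n_pair <- nrow(gestures) %/% 2L
    g1 <- gestures$label[2L * seq_len(n_pair) - 1L]
    g2 <- gestures$label[2L * seq_len(n_pair)]
    ok <- !is.na(g1) & !is.na(g2)
    ids <- rep(NA_character_, n_pair)
    ids[ok] <- decode_character(g1[ok], g2[ok], table)
    characters <- tibble::tibble(pair = seq_len(n_pair), gesture1 = g1,
                                 gesture2 = g2, character_id = ids)
  }

  report_gestures <- NULL
  report_characters <- NULL
  truth <- session$annotations
  if (nrow(truth) > 0L && nrow(truth) == nrow(gestures)) {
    report_gestures <- evaluate_recognition(gestures$label, truth$label)
    if (!is.null(characters)) {
      n_pair <- nrow(characters)
      t1 <- truth$label[2L * seq_len(n_pair) - 1L]
      t2 <- truth$label[2L * seq_len(n_pair)]
      truth_ids <- decode_character(t1, t2, table)
      report_characters <- evaluate_recognition(characters$character_id,
                                                truth_ids)
    }
  }

  structure(list(segments = segs, gestures = gestures,
                 characters = characters,
                 report_gestures = report_gestures,
                 report_characters = report_characters),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d segment(s), %d character pair(s)\n",
              nrow(x$gestures),
              if (is.null(x$characters)) 0L else nrow(x$characters)))
  if (!is.null(x$report_gestures)) {
    cat(sprintf("gesture accuracy %.2f%%\n",
                x$report_gestures$summary$pooled_pct))
  }
  if (!is.null(x$report_characters)) {
    cat(sprintf("character accuracy %.2f%%\n",
                x$report_characters$summary$pooled_pct))
  }
  invisible(x)
}
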