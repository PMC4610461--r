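# Plain-text file formats.
#
# Signal streams are tab-separated files, one column per channel, with
# commented header rows carrying the stream name, sampling rate and units.
# Annotations, segments and code tables are plain TSV. Model bundles are
# serialised to a documented JSON schema.

write_stream_tsv <- function(mat, path, stream, rate, unit) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stream: %s", stream),
               sprintf("# rate: %.10g", rate),
               sprintf("# unit: %s", unit)), con)
  df <- as.data.frame(t(mat))
  names(df) <- paste0("ch", seq_len(nrow(mat)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_stream_tsv <- function(path) {
  hdr <- readLines(path, n = 3L)
  rate <- as.numeric(sub("# rate: ", "", hdr[2]))
  df <- utils::read.delim(path, comment.char = "#")
  list(mat = t(as.matrix(df)), rate = rate)
}

#' Write / read a recording session as delimited text
#'
#' `write_session()` writes `<prefix>_emg.tsv`, `<prefix>_acc.tsv` and, when
#' annotations are present, `<prefix>_annotations.tsv`; `read_session()`
#' reassembles the session.
#'
#' @param session A [recording_session()].
#' @param prefix Path prefix for the three files.
#' @return `write_session()` returns the prefix invisibly; `read_session()`
#'   returns a `recording_session`.
#' @export
write_session <- function(session, prefix) {
  stopifnot(inherits(session, "recording_session"))
  write_stream_tsv(session$emg, paste0(prefix, "_emg.tsv"), "emg",
                   session$emg_rate, "a.u.")
  write_stream_tsv(session$acc, paste0(prefix, "_acc.tsv"), "acc",
                   session$acc_rate, "g")
  if (nrow(session$annotations) > 0L) {
    utils::write.table(session$annotations,
                       paste0(prefix, "_annotations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_session
#' @export
read_session <- function(prefix) {
  emg <- read_stream_tsv(paste0(prefix, "_emg.tsv"))
  acc <- read_stream_tsv(paste0(prefix, "_acc.tsv"))
  ann_path <- paste0(prefix, "_annotations.tsv")
  ann <- if (file.exists(ann_path)) {
    tibble::as_tibble(utils::read.delim(ann_path))
  } else NULL
  recording_session(emg$mat, acc$mat, emg$rate, acc$rate, ann)
}

#' Write / read a segment table
#'
#' @param segments Segment tibble (see [segment_session()]).
#' @param path File path (TSV).
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}

#' Write / read a code table
#'
#' TSV with columns `gesture1`, `gesture2`, `character_id`.
#'
#' @param table Code table tibble.
#' @param path File path (TSV).
#' @export
write_code_table <- function(table, path) {
  validate_code_table(table)
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_code_table
#' @export
read_code_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path,
                                             colClasses = "character"))
  validate_code_table(tab)
  tab
}

serialize_hmm <- function(h) {
  list(n_states = h$n_states, n_mix = h$n_mix, dim = h$dim, A = h$A,
       pi = h$pi, weights = h$weights, means = h$means, vars = h$vars,
       loglik_trace = as.numeric(h$loglik_trace),
       converged = isTRUE(h$converged), class_index = h$class_index)
}

# Rebuild numeric vectors/matrices from the un-simplified JSON tree
# (nested lists), which keeps deserialisation independent of jsonlite's
# simplification heuristics.
json_num <- function(x) as.numeric(unlist(x))

json_mat <- function(x) {
  do.call(rbind, lapply(x, json_num))
}

deserialize_hmm <- function(x) {
  structure(list(n_states = as.integer(x$n_states),
                 n_mix = as.integer(x$n_mix), dim = as.integer(x$dim),
                 A = json_mat(x$A), pi = json_num(x$pi),
                 weights = json_mat(x$weights),
                 means = lapply(x$means, json_mat),
                 vars = lapply(x$vars, json_mat),
                 loglik_trace = json_num(x$loglik_trace),
                 converged = isTRUE(x$converged),
                 class_index = as.integer(x$class_index)),
            class = "hmm_model")
}

#' Write / read a trained model bundle (JSON)
#'
#' Serialises the orientation discriminant, the DTW template bank, the
#' hand-shape HMMs and the segmentation threshold to a single documented
#' JSON file.
#'
#' @param models A [train_models()] bundle.
#' @param path File path (.json).
#' @export
write_model_bundle <- function(models, path) {
  stopifnot(inherits(models, "model_bundle"))
  ser <- list(
    ldc = list(classes = models$ldc$classes,
               means = lapply(models$ldc$means, unname),
               covs = models$ldc$covs,
               prior = unname(models$ldc$prior), d = models$ldc$d),
    bank = lapply(unclass(models$bank), function(tmpls) {
      lapply(tmpls, function(m) unclass(m)[, , drop = FALSE])
    }),
    hmms = lapply(models$hmms, serialize_hmm),
    threshold = unclass(models$threshold),
    cfg = unclass(models$cfg))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- as.character(unlist(x$ldc$classes))
  ldc <- structure(list(classes = classes,
                        means = lapply(x$ldc$means, json_num),
                        covs = lapply(x$ldc$covs, json_mat),
                        prior = stats::setNames(json_num(x$ldc$prior),
                                                classes),
                        d = as.integer(x$ldc$d)),
                   class = "ldc_model")
  bank <- lapply(x$bank, function(tmpls) lapply(tmpls, json_mat))
  bank <- structure(bank[MOVEMENT_CLASSES], class = "template_bank")
  hmms <- lapply(x$hmms, deserialize_hmm)
  threshold <- structure(lapply(x$threshold, json_num),
                         class = "threshold_spec")
  cfg <- do.call(pipeline_config, lapply(x$cfg, function(v) unlist(v)))
  structure(list(ldc = ldc, bank = bank, hmms = hmms, threshold = threshold,
                 cfg = cfg),
            class = "model_bundle")
}
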