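# Tidiers and ggplot2 autoplot methods for the signal containers and
# reports.

#' @rdname recording_session
#' @param x A `recording_session`.
#' @param ... Unused.
#' @method tidy recording_session
#' @export
tidy.recording_session <- function(x, ...) {
  emg <- tibble::tibble(
    time_s = rep((seq_len(ncol(x$emg)) - 1) / x$emg_rate,
                 each = nrow(x$emg)),
    stream = "emg",
    channel = rep(paste0("ch", seq_len(nrow(x$emg))), ncol(x$emg)),
    value = as.vector(x$emg))
  acc <- tibble::tibble(
    time_s = rep((seq_len(ncol(x$acc)) - 1) / x$acc_rate, each = 3L),
    stream = "acc",
    channel = rep(c("x", "y", "z"), ncol(x$acc)),
    value = as.vector(x$acc))
  dplyr::bind_rows(emg, acc)
}

#' @rdname recording_session
#' @param object A `recording_session`.
#' @param max_points Per-channel cap on plotted points (signals are thinned
#'   for display).
#' @method autoplot recording_session
#' @export
autoplot.recording_session <- function(object, max_points = 4000L, ...) {
  df <- tidy(object)
  df <- df |>
    dplyr::group_by(.data$stream, .data$channel) |>
    dplyr::slice(unique(round(seq(1, dplyr::n(),
                                  length.out = min(dplyr::n(), max_points))))) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                        colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stream, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (nrow(object$annotations) > 0L) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$annotations$onset_s,
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' @rdname sliding_average_energy
#' @param x An `energy_series`.
#' @param ... Unused.
#' @method tidy energy_series
#' @export
tidy.energy_series <- function(x, ...) {
  idx <- seq_along(x$values)
  tb <- tibble::tibble(index = idx, energy = x$values)
  if (!is.null(x$rate)) {
    tb$time_s <- ((idx - 1) * x$step) / x$rate
  }
  tb
}

#' @rdname sliding_average_energy
#' @param object An `energy_series`.
#' @param threshold Optional [calibrate_threshold()] spec drawn as a line.
#' @method autoplot energy_series
#' @export
autoplot.energy_series <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  xvar <- if ("time_s" %in% names(df)) "time_s" else "index"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$energy)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = if (xvar == "time_s") "time (s)" else "window index",
                  y = "sliding average energy (a.u.²)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold$on_threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname evaluate_recognition
#' @param object An `eval_report`.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$by_group,
                  ggplot2::aes(.data$group, .data$accuracy_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$mean_pct,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "accuracy (%)")
}
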