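# Recognition evaluation reports.
#
# Per-group (typically per-subject) counts and accuracy percentages, plus a
# summary of mean +/- sample standard deviation of the per-group
# percentages and a pooled-count accuracy. Percentages are rounded half-up
# to two decimals for display, and the summary statistics are computed on
# the rounded per-group percentages (the precision at which such tables are
# conventionally reported).

#' Evaluate recognition results
#'
#' @param predictions Vector of predicted labels; `NA` counts as an error.
#' @param truth Vector of ground-truth labels, same length.
#' @param group Optional grouping vector (e.g. subject ids); default puts
#'   everything in one group.
#' @return An object of class `eval_report`: `by_group` tibble
#'   (`group`, `n_real`, `n_correct`, `accuracy_pct`) and `summary` tibble
#'   (`n_groups`, `mean_pct`, `sd_pct`, `pooled_pct`). `sd_pct` uses the
#'   n-1 sample standard deviation and is `NA` for a single group.
#' @export
evaluate_recognition <- function(predictions, truth, group = NULL) {
  if (length(predictions) != length(truth)) {
    stop("`predictions` and `truth` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) {
    stop("cannot evaluate an empty result set", call. = FALSE)
  }
  if (is.null(group)) group <- rep("all", length(truth))
  if (length(group) != length(truth)) {
    stop("`group` must match the prediction length", call. = FALSE)
  }
  correct <- !is.na(predictions) & predictions == truth
  by_group <- tibble::tibble(group = as.character(group), correct = correct) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_real = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::mutate(accuracy_pct = round_half_up(100 * .data$n_correct / .data$n_real))
  summary <- tibble::tibble(
    n_groups = nrow(by_group),
    mean_pct = round_half_up(mean(by_group$accuracy_pct)),
    sd_pct = if (nrow(by_group) > 1L) round_half_up(sd(by_group$accuracy_pct))
             else NA_real_,
    pooled_pct = round_half_up(100 * sum(by_group$n_correct) /
                                 sum(by_group$n_real))
  )
  structure(list(by_group = by_group, summary = summary),
            class = "eval_report")
}

#' Summarise accuracy percentages
#'
#' Mean and n-1 sample standard deviation of a vector of per-group accuracy
#' percentages, rounded half-up to two decimals — the arithmetic used for
#' "mean % +/- sd %" summary rows.
#'
#' @param pct Numeric vector of accuracy percentages.
#' @return One-row tibble with `mean_pct` and `sd_pct`.
#' @export
summarize_accuracies <- function(pct) {
  if (length(pct) == 0L) stop("empty percentage vector", call. = FALSE)
  tibble::tibble(
    mean_pct = round_half_up(mean(pct)),
    sd_pct = if (length(pct) > 1L) round_half_up(sd(pct)) else NA_real_
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$by_group)
  cat(sprintf("mean %.2f%% +/- %.2f%% | pooled %.2f%%\n",
              x$summary$mean_pct, x$summary$sd_pct, x$summary$pooled_pct))
  invisible(x)
}

#' @rdname evaluate_recognition
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$by_group

#' @rdname evaluate_recognition
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) x$summary
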