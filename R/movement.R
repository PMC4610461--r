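# Hand-movement classifier.
#
# Each ACC axis of the time-normalised test sequence is aligned to each
# training template by dynamic time warping with squared-difference local
# cost and a global slope corridor (path slope between 1/2 and 2, anchored
# at both endpoints, i.e. an Itakura-style parallelogram). Per-axis costs
# are combined into an overall cost (sum of squared axis costs), averaged
# over each class's templates, and the smallest averaged cost wins.

#' DTW configuration
#'
#' @param slope_min,slope_max Global slope bounds of the warping path;
#'   defaults 1/2 and 2 (reciprocal pair).
#' @return A list of class `dtw_config`.
#' @export
dtw_config <- function(slope_min = 0.5, slope_max = 2) {
  if (!(slope_min < 1 && 1 < slope_max)) {
    stop("need slope_min < 1 < slope_max", call. = FALSE)
  }
  if (abs(slope_min * slope_max - 1) > 1e-9) {
    stop("slope bounds must be reciprocal (slope_min * slope_max = 1)",
         call. = FALSE)
  }
  structure(list(slope_min = slope_min, slope_max = slope_max),
            class = "dtw_config")
}

# Cells (m, n) of the N x N grid reachable under the global slope corridor
# anchored at (1,1) and (N,N). With bounds (s, 1/s): n-1 <= (m-1)/s,
# m-1 <= (n-1)/s, and symmetrically from the (N,N) end.
dtw_corridor <- function(N, cfg) {
  i <- matrix(seq_len(N), N, N)
  j <- matrix(seq_len(N), N, N, byrow = TRUE)
  s_max <- cfg$slope_max
  (j - 1) <= s_max * (i - 1) & (i - 1) <= s_max * (j - 1) &
    (N - j) <= s_max * (N - i) & (N - i) <= s_max * (N - j)
}

#' Slope-constrained DTW cost of one axis
#'
#' Accumulates squared differences `d(m, n) = (t_m - r_n)^2` along monotone
#' warping paths from `(1, 1)` to `(N, N)`:
#' `D(m, n) = d(m, n) + min(D(m-1, n), D(m-1, n-1), D(m, n-1))`, with cells
#' outside the slope corridor excluded.
#'
#' @param t,r Equal-length numeric vectors.
#' @param cfg A [dtw_config()].
#' @return The accumulated cost `D(N, N)` (non-negative scalar).
#' @export
dtw_axis_cost <- function(t, r, cfg = dtw_config()) {
  N <- length(t)
  if (N == 0L || length(r) != N) {
    stop("`t` and `r` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  allowed <- dtw_corridor(N, cfg)
  D <- matrix(Inf, N, N)
  D[1, 1] <- (t[1] - r[1])^2
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      if (m == 1L && n == 1L) next
      if (!allowed[m, n]) next
      prev <- Inf
      if (m > 1L) prev <- min(prev, D[m - 1L, n], D[m - 1L, n - 1L])
      if (n > 1L) prev <- min(prev, D[m, n - 1L])
      D[m, n] <- (t[m] - r[n])^2 + prev
    }
  }
  if (!is.finite(D[N, N])) {
    stop("slope corridor pruned every warping path", call. = FALSE)
  }
  D[N, N]
}

#' Overall DTW cost across the three ACC axes
#'
#' The per-axis accumulated costs are combined as the sum of their squares,
#' `D = D1^2 + D2^2 + D3^2`.
#'
#' @param test,template Movement sequences (3 x N matrices, see
#'   [movement_sequence()]).
#' @param cfg A [dtw_config()].
#' @return Overall cost (non-negative scalar).
#' @export
dtw_overall <- function(test, template, cfg = dtw_config()) {
  stopifnot(is.matrix(test), is.matrix(template),
            nrow(test) == 3L, nrow(template) == 3L)
  axis_costs <- vapply(1:3, function(i) {
    dtw_axis_cost(test[i, ], template[i, ], cfg)
  }, numeric(1))
  sum(axis_costs^2)
}

#' Build a movement template bank
#'
#' @param sequences List of movement sequences (3 x N matrices).
#' @param labels Movement class per sequence (`"U"`, `"D"`, `"R"`, `"L"`).
#' @return A list of class `template_bank`: per class, its templates.
#' @export
movement_template_bank <- function(sequences, labels) {
  labels <- as.character(labels)
  if (length(sequences) != length(labels)) {
    stop("`sequences` and `labels` lengths differ", call. = FALSE)
  }
  if (!all(labels %in% MOVEMENT_CLASSES)) {
    stop("movement labels must be U, D, R or L", call. = FALSE)
  }
  bank <- lapply(MOVEMENT_CLASSES, function(cl) sequences[labels == cl])
  names(bank) <- MOVEMENT_CLASSES
  if (any(lengths(bank) == 0L)) {
    stop("every movement class needs at least one template", call. = FALSE)
  }
  structure(bank, class = "template_bank")
}

#' Classify a hand movement by averaged DTW
#'
#' Computes the overall DTW cost of the test sequence against every template
#' of every class, averages within class, and returns the class with the
#' smallest averaged cost. Ties break by the fixed class order U, D, R, L.
#'
#' @param bank A [movement_template_bank()].
#' @param test A movement sequence (3 x N matrix).
#' @param cfg A [dtw_config()].
#' @return List with `class` and the named `costs` vector (averaged DTW per
#'   class, ordered U, D, R, L).
#' @export
classify_movement <- function(bank, test, cfg = dtw_config()) {
  if (!inherits(bank, "template_bank") || length(bank) == 0L) {
    stop("`bank` must be a non-empty template_bank", call. = FALSE)
  }
  costs <- vapply(MOVEMENT_CLASSES, function(cl) {
    mean(vapply(bank[[cl]], function(tmpl) dtw_overall(test, tmpl, cfg),
                numeric(1)))
  }, numeric(1))
  list(class = MOVEMENT_CLASSES[which.min(costs)], costs = costs)
}
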