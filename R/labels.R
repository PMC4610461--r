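# Gesture label grammar.
#
# A coded gesture is either the palm-downward default "00", or one of 13 hand
# shapes (indexed 1..13) held while executing one of four movements: U (up),
# D (down), R (rightward), L (leftward). Labels concatenate the hand-shape
# index with the movement letter, e.g. "5R". 52 + 1 = 53 labels in total.

MOVEMENT_CLASSES <- c("U", "D", "R", "L")
ORIENTATION_CLASSES <- c("Inward", "Downward")
DEFAULT_LABEL <- "00"
N_HANDSHAPES <- 13L

#' All valid coded-gesture labels
#'
#' The 52 inward labels (`"1U"` .. `"13L"`, hand shape by movement) plus the
#' palm-downward default `"00"`.
#'
#' @return Character vector of length 53.
#' @export
valid_gesture_labels <- function() {
  c(DEFAULT_LABEL,
    as.vector(t(outer(seq_len(N_HANDSHAPES), MOVEMENT_CLASSES, paste0))))
}

#' Parse a coded-gesture label
#'
#' @param label A single label such as `"5R"` or `"00"`.
#' @return A list with `orientation` (`"Inward"` or `"Downward"`), and for
#'   inward labels `handshape` (integer 1..13) and `movement` (one of
#'   `"U","D","R","L"`); both `NA` for `"00"`.
#' @export
parse_gesture_label <- function(label) {
  if (!is.character(label) || length(label) != 1L) {
    stop("`label` must be a single character string", call. = FALSE)
  }
  if (label == DEFAULT_LABEL) {
    return(list(orientation = "Downward", handshape = NA_integer_,
                movement = NA_character_))
  }
  m <- regmatches(label, regexec("^([1-9]|1[0-3])([UDRL])$", label))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("invalid gesture label: '%s'", label), call. = FALSE)
  }
  list(orientation = "Inward", handshape = as.integer(m[2]), movement = m[3])
}

is_valid_gesture_label <- function(label) {
  label %in% valid_gesture_labels()
}

#' Fuse component decisions into a coded-gesture label
#'
#' A palm-Downward decision short-circuits to the default label `"00"`;
#' movement and hand shape are only consulted for palm-Inward gestures,
#' mirroring the pipeline in which only inward segments reach the movement
#' and hand-shape classifiers.
#'
#' @param orientation `"Inward"` or `"Downward"`.
#' @param movement Movement class (`"U"`, `"D"`, `"R"`, `"L"`); may be `NULL`
#'   for downward gestures.
#' @param handshape Hand-shape index in 1..13; may be `NULL` for downward
#'   gestures.
#' @return A single gesture label.
#' @examples
#' decode_gesture("Inward", "R", 5)   # "5R"
#' decode_gesture("Downward")         # "00"
#' @export
decode_gesture <- function(orientation, movement = NULL, handshape = NULL) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      !orientation %in% ORIENTATION_CLASSES) {
    stop("`orientation` must be \"Inward\" or \"Downward\"", call. = FALSE)
  }
  if (orientation == "Downward") {
    return(DEFAULT_LABEL)
  }
  if (is.null(movement) || is.null(handshape)) {
    stop("inward gestures need both `movement` and `handshape`", call. = FALSE)
  }
  if (!is.character(movement) || length(movement) != 1L ||
      !movement %in% MOVEMENT_CLASSES) {
    stop(sprintf("invalid movement class: '%s'", as.character(movement)[1]),
         call. = FALSE)
  }
  hs <- suppressWarnings(as.integer(handshape))
  if (length(hs) != 1L || is.na(hs) || hs != handshape ||
      hs < 1L || hs > N_HANDSHAPES) {
    stop("`handshape` must be an integer in 1..13", call. = FALSE)
  }
  paste0(hs, movement)
}
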