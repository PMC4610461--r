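# Code tables: ordered pairs of coded-gesture labels -> character identifier.
#
# Two executions of coded gestures determine one character (the first encodes
# the pronunciation, the second the radicals). The real character coding is
# treated as a pluggable table; for testing, a toy table over synthetic
# character ids is generated.

#' Generate a toy code table
#'
#' Draws `n_characters` distinct ordered pairs of valid gesture labels
#' (either slot may be the `"00"` default) and maps each to a unique
#' synthetic character id `C001`, `C002`, ...
#'
#' @param n_characters Number of characters (1 .. 53^2).
#' @param seed Integer seed.
#' @return A tibble with columns `gesture1`, `gesture2`, `character_id`.
#' @export
make_toy_code_table <- function(n_characters, seed = 1L) {
  labels <- valid_gesture_labels()
  n_pairs <- length(labels)^2
  if (!is.numeric(n_characters) || length(n_characters) != 1L ||
      n_characters < 1 || n_characters != floor(n_characters)) {
    stop("`n_characters` must be a positive integer", call. = FALSE)
  }
  if (n_characters > n_pairs) {
    stop(sprintf("`n_characters` cannot exceed the %d distinct ordered pairs",
                 n_pairs), call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(n_pairs, n_characters))
  g1 <- labels[((idx - 1L) %/% length(labels)) + 1L]
  g2 <- labels[((idx - 1L) %% length(labels)) + 1L]
  tibble::tibble(
    gesture1 = g1,
    gesture2 = g2,
    character_id = sprintf("C%03d", seq_len(n_characters))
  )
}

validate_code_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("gesture1", "gesture2", "character_id") %in% names(table))) {
    stop("code table needs columns gesture1, gesture2, character_id",
         call. = FALSE)
  }
  bad <- !is_valid_gesture_label(table$gesture1) |
    !is_valid_gesture_label(table$gesture2)
  if (any(bad)) {
    stop("code table contains invalid gesture labels", call. = FALSE)
  }
  if (anyDuplicated(paste(table$gesture1, table$gesture2))) {
    stop("code table keys (gesture pairs) must be unique", call. = FALSE)
  }
  invisible(table)
}

#' Decode a gesture pair into a character id
#'
#' Exact ordered-pair lookup in the code table; an unmapped pair yields `NA`
#' (an explicit unknown, counted as an error downstream).
#'
#' @param g1,g2 Gesture labels (first and second execution).
#' @param table A code table as returned by [make_toy_code_table()].
#' @return Character id or `NA_character_` for an unmapped pair.
#' @export
decode_character <- function(g1, g2, table) {
  validate_code_table(table)
  if (length(g1) != length(g2)) {
    stop("`g1` and `g2` must have equal length", call. = FALSE)
  }
  ok <- is_valid_gesture_label(g1) & is_valid_gesture_label(g2)
  if (!all(ok)) {
    stop("invalid gesture label in pair", call. = FALSE)
  }
  key <- paste(g1, g2)
  table$character_id[match(key, paste(table$gesture1, table$gesture2))]
}

#' Gesture-label sequence for a set of characters
#'
#' Expands rows of a code table into the flat sequence of gesture labels a
#' signer would execute (two per character, in order).
#'
#' @param table Code table.
#' @param character_ids Which characters to include (default: all rows).
#' @return Character vector of gesture labels, length `2 * n`.
#' @export
character_gesture_sequence <- function(table, character_ids = NULL) {
  validate_code_table(table)
  if (!is.null(character_ids)) {
    idx <- match(character_ids, table$character_id)
    if (anyNA(idx)) stop("unknown character id", call. = FALSE)
    table <- table[idx, ]
  }
  as.vector(rbind(table$gesture1, table$gesture2))
}
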