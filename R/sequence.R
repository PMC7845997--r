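#' @title Binary sequences over the items A and B
#'
#' @description Sequences are plain character strings over the alphabet
#' `{A, B}`. The labelling of the two items is arbitrary (high vs low tone,
#' red vs green patch), so a sequence and its item-swapped mirror are the same
#' pattern; the canonical representative starts with A.
#' @name binary_sequence
NULL

.check_pattern <- function(pattern) {
  if (!(is.character(pattern) && length(pattern) == 1L && nchar(pattern) >= 1L &&
        grepl("^[AB]+$", pattern)))
    stop("pattern must be a non-empty string over {A,B}", call. = FALSE)
  pattern
}

# string -> integer vector (1 = A, 2 = B)
.seq_int <- function(pattern) {
  match(strsplit(pattern, "")[[1L]], c("A", "B"))
}

.int_seq <- function(x) paste(c("A", "B")[x], collapse = "")

.flip_pattern <- function(pattern) {
  chartr("AB", "BA", pattern)
}

#' Canonicalize a binary sequence
#'
#' Swaps the two item labels globally so that the first item is A. Vectorised.
#'
#' @param pattern Character vector of sequences over `{A,B}`.
#' @return Character vector of canonical sequences.
#' @examples
#' canonicalize_sequence("BABABA")  # "ABABAB"
#' @export
canonicalize_sequence <- function(pattern) {
  vapply(pattern, function(p) {
    .check_pattern(p)
    if (substr(p, 1L, 1L) == "B") .flip_pattern(p) else p
  }, "", USE.NAMES = FALSE)
}

#' Catalog of canonical binary sequences of a given length
#'
#' All sequences of the given length, one representative per A/B-relabelling
#' class (i.e. all sequences starting with A), sorted lexicographically.
#' There are `2^(length-1)` of them, e.g. 32 for length 6. With
#' `balanced_only = TRUE` only sequences with equal numbers of As and Bs are
#' kept (35 for length 8).
#'
#' @param length Sequence length, 1..20.
#' @param balanced_only Keep only sequences with `#A == #B` (requires an even
#'   length).
#' @return Character vector of canonical patterns.
#' @export
sequence_catalog <- function(length, balanced_only = FALSE) {
  stopifnot(length >= 1, length <= 20, length == round(length))
  if (balanced_only && length %% 2 != 0)
    stop("balanced_only requires an even length", call. = FALSE)
  length <- as.integer(length)
  if (length == 1L) return("A")
  tails <- expand.grid(rep(list(c("A", "B")), length - 1L),
                       stringsAsFactors = FALSE)
  pats <- paste0("A", do.call(paste0, rev(tails)))
  if (balanced_only) {
    na <- vapply(pats, function(p) sum(.seq_int(p) == 1L), 0L, USE.NAMES = FALSE)
    pats <- pats[na == length / 2L]
  }
  sort(pats)
}

#' Period of a binary sequence
#'
#' The smallest divisor `p` of the sequence length such that the sequence is
#' its first `p` items repeated; equals the length for aperiodic sequences.
#'
#' @param pattern A sequence over `{A,B}`.
#' @return Integer period.
#' @examples
#' sequence_period("AAAABBBBAAAABBBB")  # 8
#' @export
sequence_period <- function(pattern) {
  x <- .seq_int(.check_pattern(pattern))
  n <- length(x)
  for (p in seq_len(n)) {
    if (n %% p != 0) next
    if (all(x == rep_len(x[seq_len(p)], n))) return(p)
  }
  n
}
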