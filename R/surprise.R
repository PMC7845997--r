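#' @title Transition-probability surprise for deviant items
#'
#' @description In the violation-detection task the standard sequence is
#' fully learned during habituation, so an observer tracking first-order
#' statistics holds *fixed* transition probabilities estimated from one
#' linear presentation of the sequence (no wrap-around between repetitions).
#' The Shannon surprise of an observed item is the negative base-2 log of
#' its predictive probability given the preceding item; zero probabilities
#' are padded to a small constant (default 0.01), capping surprise at
#' `-log2(0.01) ~ 6.64` bits.
#' @name surprise_model
NULL

#' Estimate a fixed transition model from one sequence presentation
#'
#' Maximum-likelihood first-order transition probabilities from the
#' `length - 1` adjacent pairs of a single linear pass, plus marginal item
#' frequencies. Conditionals of an item that never occurs with a successor
#' (e.g. B in the sequence `AB`) are `NA` -- undefined, not zero.
#'
#' @param pattern A sequence over `{A,B}` of length >= 2.
#' @return An object of class `transition_model`: list with `p_given`
#'   (2x2 matrix, rows = previous item, cols = next item), `counts`
#'   (2x2 integer matrix), `item_freq` (named vector).
#' @examples
#' m <- estimate_transitions("AAAAAAAABBBBBBBB")
#' m$p_given["A", "A"]  # 0.875
#' m$p_given["B", "A"]  # 0
#' @export
estimate_transitions <- function(pattern) {
  x <- .seq_int(.check_pattern(pattern))
  if (length(x) < 2L)
    stop("transition estimation needs length >= 2", call. = FALSE)
  counts <- matrix(0L, 2L, 2L, dimnames = list(c("A", "B"), c("A", "B")))
  for (k in seq_len(length(x) - 1L))
    counts[x[k], x[k + 1L]] <- counts[x[k], x[k + 1L]] + 1L
  rs <- rowSums(counts)
  p <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(p_given = p, counts = counts,
                 item_freq = stats::setNames(tabulate(x, 2L) / length(x),
                                             c("A", "B")),
                 pattern = .int_seq(x)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> for", x$pattern, "\n")
  print(round(x$p_given, 4))
  invisible(x)
}

#' Shannon surprise of an observed item
#'
#' `-log2(p(observed | previous))`, with exact-zero probabilities padded to
#' `padding` (no smoothing of non-zero probabilities). An undefined
#' conditional (previous item never seen with a successor) is an error.
#'
#' @param model A [estimate_transitions()] model.
#' @param prev_item,observed_item Items in `{A, B}`.
#' @param padding Replacement for zero probabilities (default 0.01).
#' @return Surprise in bits, in `[0, -log2(padding)]`.
#' @export
shannon_surprise <- function(model, prev_item, observed_item, padding = 0.01) {
  stopifnot(inherits(model, "transition_model"),
            prev_item %in% c("A", "B"), observed_item %in% c("A", "B"),
            padding > 0, padding <= 1)
  p <- model$p_given[prev_item, observed_item]
  if (is.na(p))
    stop(sprintf("no transition defined from item %s", prev_item),
         call. = FALSE)
  if (p == 0) p <- padding
  -log2(p)
}

#' Surprise of a deviant at a given position
#'
#' The context is the item at `position - 1` of the *original* sequence (the
#' learned standard); the observed item is the deviant. Sequence deviants
#' replace the original item by the other one; super-deviants (a third item
#' C) have no transition probability and are not handled here.
#'
#' @param pattern The standard sequence.
#' @param position 1-based deviant position, `>= 2`.
#' @param deviant_item The item heard/seen at `position` (default: the flip
#'   of the original item there).
#' @param padding Zero-probability padding.
#' @return Surprise in bits.
#' @examples
#' deviant_surprise("AAAAAAAABBBBBBBB", 11)  # padded: -log2(0.01) = 6.64
#' @export
deviant_surprise <- function(pattern, position, deviant_item = NULL,
                             padding = 0.01) {
  x <- strsplit(.check_pattern(pattern), "")[[1L]]
  if (position < 2L || position > length(x))
    stop("position must be in 2..length (a predecessor is needed)",
         call. = FALSE)
  if (is.null(deviant_item))
    deviant_item <- if (x[position] == "A") "B" else "A"
  m <- estimate_transitions(pattern)
  shannon_surprise(m, x[position - 1L], deviant_item, padding)
}

#' Mean deviant surprise over a set of positions
#'
#' Arithmetic mean of [deviant_surprise()] over the given positions, each
#' deviant being the flip of the original item. `drop_zero = TRUE`
#' replicates the control analysis that excludes padded zero-probability
#' transitions entirely: such positions are dropped before averaging (the
#' mean is `NA` if nothing remains).
#'
#' @inheritParams deviant_surprise
#' @param positions Integer vector of 1-based positions, all `>= 2`.
#' @param drop_zero Exclude positions whose true transition probability is
#'   exactly zero instead of padding them.
#' @return Mean surprise in bits (possibly `NA` under `drop_zero`).
#' @export
mean_deviant_surprise <- function(pattern, positions, padding = 0.01,
                                  drop_zero = FALSE) {
  x <- strsplit(.check_pattern(pattern), "")[[1L]]
  m <- estimate_transitions(pattern)
  vals <- vapply(positions, function(pos) {
    if (pos < 2L || pos > length(x))
      stop("positions must be in 2..length", call. = FALSE)
    dev <- if (x[pos] == "A") "B" else "A"
    p <- m$p_given[x[pos - 1L], dev]
    if (is.na(p))
      stop(sprintf("no transition defined from item %s", x[pos - 1L]),
           call. = FALSE)
    if (p == 0 && drop_zero) return(NA_real_)
    shannon_surprise(m, x[pos - 1L], dev, padding)
  }, 0)
  if (drop_zero) vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
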