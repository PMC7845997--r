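#' @title Exact minimal description length (LoT complexity)
#'
#' @description [minimal_description()] finds, by exact dynamic programming
#' over all grammar expressions, the cheapest program(s) that emit a given
#' binary sequence when run from state A, under a [lot_cost_scheme()]. The
#' minimum cost is the sequence's LoT complexity. With
#' `chunk_preserving = TRUE` the search is restricted to expressions whose
#' repetition-unit boundaries never split a run of identical items (the
#' "A][A" / "B][B" exclusion), yielding the LoT-chunk complexity, which is
#' always `>=` the unrestricted value.
#'
#' The dynamic program tabulates, for every substring and every pair of
#' (incoming state, outgoing state), the cheapest expression emitting that
#' substring. Repetitions exploit the grammar's complement symmetry: an
#' expression run from the flipped state emits the flipped sequence, so a
#' candidate repetition is valid iff the emitted blocks are all equal
#' (per-repetition state shift "same") or alternately complemented (shift
#' "flip"), with the silent transform chosen to realise the shift.
#' @name lot_minimal
NULL

.edges_ok <- function(x, i, j) {
  n <- length(x)
  (i == 1L || x[i - 1L] != x[i]) && (j == n || x[j] != x[j + 1L])
}

# Valid (block length, count, per-repetition shift) decompositions of x[i..j].
# rho = 0: every block equal; rho = 1: blocks alternately complemented.
# In chunk mode, repeats of multi-item blocks must fall on run boundaries.
.rep_options <- function(x, i, j, chunk) {
  len <- j - i + 1L
  out <- list()
  if (len < 2L) return(out)
  for (L in seq_len(len %/% 2L)) {
    if (len %% L != 0L) next
    nr <- len %/% L
    if (chunk && L >= 2L) {
      bnd <- i + seq_len(nr - 1L) * L
      if (any(x[bnd - 1L] == x[bnd])) next
      if (!.edges_ok(x, i, j)) next
    }
    b1 <- x[i:(i + L - 1L)]
    for (rho in 0:1) {
      ok <- TRUE
      for (k in 2:nr) {
        bk <- x[(i + (k - 1L) * L):(i + k * L - 1L)]
        want <- if (rho == 1L && k %% 2L == 0L) 3L - b1 else b1
        if (!all(bk == want)) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <-
          list(L = L, nr = nr, rho = as.integer(rho))
    }
  }
  out
}

# Cost table: C[i, j, s, e] = min cost of an expression emitting x[i..j]
# when started in state s and ending in state e (1 = A, 2 = B).
.lot_dp <- function(x, w, digit, chunk) {
  n <- length(x)
  C <- array(Inf, dim = c(n, n, 2L, 2L))
  for (i in seq_len(n)) {
    C[i, i, 1L, x[i]] <- w
    C[i, i, 2L, x[i]] <- w
    # [atom]^1<b>: emit one item, end in the other state
    C[i, i, 1L, 3L - x[i]] <- 2 * w
    C[i, i, 2L, 3L - x[i]] <- 2 * w
  }
  if (n == 1L) return(C)
  for (len in 2:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      M <- matrix(Inf, 2L, 2L)
      for (k in i:(j - 1L)) {
        for (s in 1:2) for (m in 1:2) {
          a <- C[i, k, s, m]
          if (!is.finite(a)) next
          for (e in 1:2) {
            v <- a + C[k + 1L, j, m, e]
            if (v < M[s, e]) M[s, e] <- v
          }
        }
      }
      for (opt in .rep_options(x, i, j, chunk)) {
        dcost <- digit(opt$nr)
        for (s in 1:2) for (e1 in 1:2) {
          base <- C[i, i + opt$L - 1L, s, e1]
          if (!is.finite(base)) next
          needs_flip <- xor(opt$rho == 1L, e1 != s)
          efin <- if ((opt$nr * opt$rho) %% 2L == 1L) 3L - s else s
          v <- base + (if (needs_flip) w else 0) + dcost
          if (v < M[s, efin]) M[s, efin] <- v
        }
      }
      # silent state change via [whole]^1<b>
      if (!chunk || .edges_ok(x, i, j)) {
        M0 <- M
        for (s in 1:2) for (e in 1:2) {
          v <- M0[s, 3L - e] + w
          if (v < M[s, e]) M[s, e] <- v
        }
      }
      C[i, j, , ] <- M
    }
  }
  C
}

# Reconstruct every minimal expression from the DP table. Concatenations are
# kept flat (terms are atoms or repeats), so each distinct tree is produced
# exactly once. `cap` bounds the number of part-lists materialised.
.lot_reconstruct <- function(x, C, w, digit, chunk, cap) {
  n <- length(x)
  memo <- new.env(parent = emptyenv())
  truncated <- FALSE
  count <- 0L

  units <- function(i, j, s, e) {
    key <- paste("u", i, j, s, e)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- list()
    cc <- C[i, j, s, e]
    if (is.finite(cc)) {
      if (i == j && e == x[i] && cc == w)
        res <- c(res, list(lot_atom(if (s == e) "stay" else "flip")))
      for (opt in .rep_options(x, i, j, chunk)) {
        dcost <- digit(opt$nr)
        for (e1 in 1:2) {
          base <- C[i, i + opt$L - 1L, s, e1]
          if (!is.finite(base)) next
          needs_flip <- xor(opt$rho == 1L, e1 != s)
          efin <- if ((opt$nr * opt$rho) %% 2L == 1L) 3L - s else s
          if (efin != e) next
          if (base + (if (needs_flip) w else 0) + dcost != cc) next
          for (bl in plists(i, i + opt$L - 1L, s, e1)) {
            body <- if (length(bl) == 1L) bl[[1L]] else lot_concat(bl)
            res <- c(res, list(lot_repeat(body, opt$nr,
                                          if (needs_flip) "flip" else NULL)))
          }
        }
      }
      wrap_ok <- (i == j) || !chunk || .edges_ok(x, i, j)
      if (wrap_ok && is.finite(C[i, j, s, 3L - e]) &&
          C[i, j, s, 3L - e] + w == cc) {
        for (bl in plists(i, j, s, 3L - e)) {
          body <- if (length(bl) == 1L) bl[[1L]] else lot_concat(bl)
          res <- c(res, list(lot_repeat(body, 1L, "flip")))
        }
      }
    }
    memo[[key]] <- res
    res
  }

  plists <- function(i, j, s, e) {
    key <- paste("p", i, j, s, e)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- lapply(units(i, j, s, e), list)
    if (j > i) {
      for (k in i:(j - 1L)) for (m in 1:2) {
        a <- C[i, k, s, m]
        b <- C[k + 1L, j, m, e]
        if (!is.finite(a) || !is.finite(b) || a + b != C[i, j, s, e]) next
        us <- units(i, k, s, m)
        if (!length(us)) next
        rs <- plists(k + 1L, j, m, e)
        for (u in us) for (r in rs) {
          if (count >= cap) { truncated <<- TRUE; break }
          res[[length(res) + 1L]] <- c(list(u), r)
          count <<- count + 1L
        }
      }
    }
    memo[[key]] <- res
    res
  }

  best <- min(C[1L, n, 1L, ])
  exprs <- list()
  for (e in 1:2) {
    if (C[1L, n, 1L, e] == best) {
      for (bl in plists(1L, n, 1L, e)) {
        exprs[[length(exprs) + 1L]] <-
          if (length(bl) == 1L) bl[[1L]] else lot_concat(bl)
      }
    }
  }
  list(exprs = exprs, best = best, truncated = truncated)
}

#' Minimal description of a binary sequence
#'
#' Computes the exact minimum description length over all grammar
#' expressions whose evaluation from state A yields the canonicalized
#' sequence, together with every cost-tied minimal expression (structurally
#' deduplicated, reported in lexicographic order of their notation) and the
#' minimum hierarchical depth among the ties.
#'
#' @param pattern A sequence over `{A,B}`; it is canonicalized (item labels
#'   are arbitrary) before the search.
#' @param scheme A [lot_cost_scheme()].
#' @param chunk_preserving If `TRUE`, restrict the search to expressions
#'   whose multi-item repetition units start and end at run boundaries
#'   (repetitions of a single-item body, which *build* runs, are exempt).
#' @param max_length Guard on the sequence length (default 24).
#' @param max_expressions Cap on the number of tied minimal expressions
#'   materialised; if hit, the result is flagged `truncated`.
#' @return An object of class `lot_encoding`: a list with elements
#'   `sequence` (canonical pattern), `input`, `complexity` (bits),
#'   `minimal_expressions` (list of `lot_expr`), `notation` (their rendered
#'   forms), `depth` (minimum depth among ties), `chunk_preserving`,
#'   `truncated`.
#' @examples
#' minimal_description("ABBAAB")$complexity                            # 5
#' minimal_description("ABBAAB", chunk_preserving = TRUE)$complexity   # 9
#' @export
minimal_description <- function(pattern, scheme = lot_cost_scheme(),
                                chunk_preserving = FALSE,
                                max_length = 24, max_expressions = 256) {
  .check_pattern(pattern)
  if (nchar(pattern) > max_length)
    stop(sprintf("sequence length %d exceeds max_length = %d",
                 nchar(pattern), max_length), call. = FALSE)
  stopifnot(inherits(scheme, "lot_cost_scheme"))
  canon <- canonicalize_sequence(pattern)
  x <- .seq_int(canon)
  w <- scheme$instruction_weight
  C <- .lot_dp(x, w, scheme$digit_cost, chunk_preserving)
  rec <- .lot_reconstruct(x, C, w, scheme$digit_cost, chunk_preserving,
                          max_expressions)
  nt <- vapply(rec$exprs, lot_render, "")
  ord <- order(nt)
  exprs <- rec$exprs[ord]
  structure(list(sequence = canon,
                 input = pattern,
                 complexity = rec$best,
                 minimal_expressions = exprs,
                 notation = nt[ord],
                 depth = if (length(exprs))
                   min(vapply(exprs, lot_expression_depth, 0L)) else NA_integer_,
                 chunk_preserving = chunk_preserving,
                 truncated = rec$truncated),
            class = "lot_encoding")
}

#' @export
print.lot_encoding <- function(x, ...) {
  cat("<lot_encoding> ", x$sequence,
      if (x$chunk_preserving) " (chunk-preserving)" else "", "\n",
      "  complexity: ", x$complexity, " bits | depth: ", x$depth,
      " | ", length(x$minimal_expressions), " minimal expression(s)",
      if (x$truncated) " [truncated]" else "", "\n", sep = "")
  show <- utils::head(x$notation, 5L)
  for (s in show) cat("   ", s, "\n")
  if (length(x$notation) > 5L) cat("    ...\n")
  invisible(x)
}

#' LoT complexity of one or more sequences
#'
#' Vectorised convenience wrapper around [minimal_description()] returning
#' just the minimum description length.
#'
#' @inheritParams minimal_description
#' @param pattern Character vector of sequences over `{A,B}`.
#' @return Numeric vector of complexities (bits).
#' @examples
#' lot_complexity(c("ABAAAB", "AAAAAABBBBBB"))  # 10 6
#' @export
lot_complexity <- function(pattern, chunk_preserving = FALSE,
                           scheme = lot_cost_scheme(), max_length = 24) {
  vapply(pattern, function(p)
    minimal_description(p, scheme = scheme,
                        chunk_preserving = chunk_preserving,
                        max_length = max_length,
                        max_expressions = 1L)$complexity,
    0, USE.NAMES = FALSE)
}
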