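#' @title Brute-force enumeration of grammar expressions
#'
#' @description [enumerate_descriptions()] is the independent oracle for the
#' minimizer: it generates, by structural recursion that never looks at the
#' target sequence (only at its length), every canonical grammar expression
#' with the requested emission length and cost below a bound, evaluates each
#' from state A, and keeps those that emit the target. "Canonical" means
#' concatenations are flat (no concat directly inside a concat), silent
#' `<+0>` transforms are omitted (they cost 2 and do nothing), and a
#' count-1 repetition always carries a `<b>` transform (a bare `[x]^1` is
#' the same program as `x` at the same cost). Every other expression is a
#' zero-gain rewrite of a canonical one, so the minimum cost is unaffected.
#' @name lot_enumerate
NULL

# Expression space: all canonical expressions with emission length exactly L
# and cost <= budget. Records carry the emission from start state A and the
# end state from A; by complement symmetry, from B both are flipped.
.enum_space <- function(L, budget, w, digit, node_budget) {
  cache <- new.env(parent = emptyenv())
  nodes <- 0L
  bump <- function(k) {
    nodes <<- nodes + k
    if (nodes > node_budget)
      stop(sprintf("enumeration budget exceeded (> %d nodes)", node_budget),
           call. = FALSE)
  }
  # cheapest conceivable cost of emitting m items: one instruction plus one
  # digit when a repetition is needed
  lowbound <- function(m) w + (m > 1L) * 1

  units <- function(l, b) {
    key <- paste0("u", l, ":", b)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- list()
    if (l == 1L && b >= w) {
      res <- list(list(expr = lot_atom("stay"), cost = w, out = 1L, end = 1L),
                  list(expr = lot_atom("flip"), cost = w, out = 2L, end = 2L))
    }
    for (nr in seq_len(l)) {
      if (l %% nr != 0L) next
      bl <- l %/% nr
      trs <- if (nr == 1L) "flip" else c("none", "flip")
      for (tr in trs) {
        tc <- if (tr == "flip") w else 0
        bb <- b - tc - digit(nr)
        if (bb < lowbound(bl)) next
        for (bd in exprs(bl, bb)) {
          out <- integer(l)
          s <- 1L
          for (k in seq_len(nr)) {
            idx <- ((k - 1L) * bl + 1L):(k * bl)
            if (s == 1L) {
              out[idx] <- bd$out
              s <- bd$end
            } else {
              out[idx] <- 3L - bd$out
              s <- 3L - bd$end
            }
            if (tr == "flip") s <- 3L - s
          }
          res[[length(res) + 1L]] <- list(
            expr = lot_repeat(bd$expr, nr, if (tr == "flip") "flip" else NULL),
            cost = bd$cost + tc + digit(nr), out = out, end = s)
        }
      }
    }
    bump(length(res))
    cache[[key]] <- res
    res
  }

  exprs <- function(l, b) {
    key <- paste0("e", l, ":", b)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- units(l, b)
    if (l > 1L) {
      for (l1 in seq_len(l - 1L)) {
        for (u in units(l1, b - lowbound(l - l1))) {
          for (rest in exprs(l - l1, b - u$cost)) {
            first_terms <- list(u$expr)
            rest_terms <- if (rest$expr$type == "concat") rest$expr$terms
                          else list(rest$expr)
            if (u$end == 1L) {
              out <- c(u$out, rest$out)
              end <- rest$end
            } else {
              out <- c(u$out, 3L - rest$out)
              end <- 3L - rest$end
            }
            res[[length(res) + 1L]] <- list(
              expr = lot_concat(c(first_terms, rest_terms)),
              cost = u$cost + rest$cost, out = out, end = end)
          }
        }
      }
      bump(length(res))
    }
    cache[[key]] <- res
    res
  }

  exprs(L, budget)
}

# Realized chunk-preservation check: walk the evaluation of `expr` over the
# emitted sequence x and, for every *execution* of every repetition whose
# body emits >= 2 items, require that the boundaries between consecutive
# repetitions and the outer edges of the repeated span separate different
# items. Single-item bodies (run builders) are exempt.
.chunk_ok <- function(expr, x) {
  n <- length(x)
  ok <- TRUE
  walk <- function(e, s, off) {  # returns list(len, end)
    switch(e$type,
      atom = {
        v <- if (e$instr == "stay") s else 3L - s
        list(len = 1L, end = v)
      },
      concat = {
        len <- 0L
        for (tm in e$terms) {
          r <- walk(tm, s, off + len)
          len <- len + r$len
          s <- r$end
        }
        list(len = len, end = s)
      },
      `repeat` = {
        blen <- NULL
        len <- 0L
        for (k in seq_len(e$count)) {
          r <- walk(e$body, s, off + len)
          if (is.null(blen)) blen <- r$len
          len <- len + r$len
          s <- r$end
          if (!is.null(e$transform) && e$transform == "flip") s <- 3L - s
        }
        if (blen >= 2L) {
          if (e$count > 1L) {
            bnd <- off + seq_len(e$count - 1L) * blen
            if (any(x[bnd] == x[bnd + 1L])) ok <<- FALSE
          }
          if (off >= 1L && x[off] == x[off + 1L]) ok <<- FALSE
          if (off + len < n && x[off + len] == x[off + len + 1L]) ok <<- FALSE
        }
        list(len = len, end = s)
      })
  }
  walk(expr, 1L, 0L)
  ok
}

#' Enumerate all grammar descriptions of a sequence up to a cost bound
#'
#' Brute-force oracle for [minimal_description()]: all canonical expressions
#' with cost `<= max_cost` that evaluate from state A to the canonicalized
#' sequence. With `chunk_preserving = TRUE`, expressions whose realized
#' repetition boundaries split a run are filtered out. Practical up to
#' length ~10; the search space grows combinatorially, and the enumeration
#' aborts with an explicit error if more than `node_budget` candidate
#' records are materialised.
#'
#' @inheritParams minimal_description
#' @param max_cost Upper cost bound. `2 * nchar(pattern)` (the cost of the
#'   flat atom-by-atom program) is always sufficient to contain the minimum.
#' @param node_budget Abort threshold on generated candidate records.
#' @return A data.frame with columns `notation`, `cost`, and (as an
#'   attribute `"expressions"`) the corresponding list of `lot_expr`,
#'   ordered by cost then notation.
#' @examples
#' e <- enumerate_descriptions("AAAA", max_cost = 4)
#' e$notation  # includes "[+0]^4" at cost 3
#' @export
enumerate_descriptions <- function(pattern, max_cost,
                                   chunk_preserving = FALSE,
                                   scheme = lot_cost_scheme(),
                                   node_budget = 5e6) {
  .check_pattern(pattern)
  canon <- canonicalize_sequence(pattern)
  x <- .seq_int(canon)
  space <- .enum_space(length(x), max_cost, scheme$instruction_weight,
                       scheme$digit_cost, node_budget)
  keep <- vapply(space, function(r)
    r$cost <= max_cost && all(r$out == x), TRUE)
  space <- space[keep]
  if (chunk_preserving)
    space <- space[vapply(space, function(r) .chunk_ok(r$expr, x), TRUE)]
  nt <- vapply(space, function(r) lot_render(r$expr), "")
  cost <- vapply(space, function(r) r$cost, 0)
  ord <- order(cost, nt)
  out <- data.frame(notation = nt[ord], cost = cost[ord],
                    stringsAsFactors = FALSE)
  attr(out, "expressions") <- lapply(space[ord], function(r) r$expr)
  out
}
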