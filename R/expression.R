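#' @title Expressions of the binary language of thought
#'
#' @description The language has two primitive instructions over the two
#' sequence states A and B: `+0` ("stay", emit the current state) and `b`
#' ("flip", move to the other state and emit it). Expressions are built from
#' atoms by concatenation (written with commas) and repetition
#' `[expr]^n<t>`, where the optional silent transform `t` (`+0` or `b`) is
#' applied to the state after every repetition -- including the last one --
#' without emitting anything. `[+0]^4` therefore produces `AAAA` while
#' `[+0]^4<b>` produces `ABAB`.
#'
#' Constructors validate their arguments; all other functions assume
#' well-formed trees.
#'
#' @name lot_expression
NULL

.lot_instr <- c("stay", "flip")

.check_instr <- function(instr) {
  if (!(is.character(instr) && length(instr) == 1L && instr %in% .lot_instr))
    stop("instruction must be \"stay\" or \"flip\"", call. = FALSE)
  instr
}

#' @param instr `"stay"` (the `+0` primitive) or `"flip"` (the `b` primitive).
#' @return A `lot_expr` tree node.
#' @rdname lot_expression
#' @examples
#' e <- lot_repeat(lot_atom("stay"), 4, transform = "flip")
#' lot_render(e)                 # "[+0]^4<b>"
#' lot_evaluate(e)$emitted       # "ABAB"
#' @export
lot_atom <- function(instr) {
  structure(list(type = "atom", instr = .check_instr(instr)),
            class = "lot_expr")
}

#' @param body A `lot_expr` to repeat.
#' @param count Integer repetition count, `>= 1`.
#' @param transform Optional silent instruction applied after every
#'   repetition: `NULL` (none, the default), `"stay"` or `"flip"`.
#' @rdname lot_expression
#' @export
lot_repeat <- function(body, count, transform = NULL) {
  stopifnot(inherits(body, "lot_expr"))
  if (!(is.numeric(count) && length(count) == 1L && count >= 1 &&
        count == round(count)))
    stop("count must be a single integer >= 1", call. = FALSE)
  if (!is.null(transform)) .check_instr(transform)
  structure(list(type = "repeat", body = body, count = as.integer(count),
                 transform = transform),
            class = "lot_expr")
}

#' @param ... For `lot_concat()`: two or more `lot_expr` terms (or a single
#'   list of them). Nested concatenations are flattened -- concatenation is
#'   associative and the comma notation cannot distinguish groupings -- so
#'   the terms of a concat node are always atoms or repetitions.
#' @rdname lot_expression
#' @export
lot_concat <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1L]]) &&
      !inherits(terms[[1L]], "lot_expr"))
    terms <- terms[[1L]]
  if (length(terms) < 2L)
    stop("a concatenation needs at least two terms", call. = FALSE)
  if (!all(vapply(terms, inherits, TRUE, "lot_expr")))
    stop("all terms must be lot_expr objects", call. = FALSE)
  flat <- list()
  for (tm in terms) {
    if (tm$type == "concat") flat <- c(flat, tm$terms)
    else flat <- c(flat, list(tm))
  }
  structure(list(type = "concat", terms = flat), class = "lot_expr")
}

#' Evaluate an expression to the binary sequence it emits
#'
#' Runs the program from `start_state`. Atoms emit one item (`+0` the current
#' state, `b` the other one); a repetition runs its body `count` times,
#' applying the silent transform after every run; concatenation threads the
#' state left to right. The returned `end_state` reflects trailing silent
#' transforms and is what a following concatenated term would start from.
#'
#' @param expr A `lot_expr`.
#' @param start_state `"A"` or `"B"` (default `"A"`, the canonical start).
#' @return `list(emitted = <string over AB>, end_state = "A"|"B")`.
#' @examples
#' lot_evaluate(lot_parse("[+0,b]^3"))  # ABBAAB, ends in B
#' @export
lot_evaluate <- function(expr, start_state = "A") {
  stopifnot(inherits(expr, "lot_expr"), start_state %in% c("A", "B"))
  s <- if (start_state == "A") 1L else 2L
  res <- .lot_eval(expr, s)
  list(emitted = paste(c("A", "B")[res$out], collapse = ""),
       end_state = c("A", "B")[res$end])
}

# internal evaluator on integer states (1 = A, 2 = B)
.lot_eval <- function(expr, s) {
  switch(expr$type,
    atom = {
      e <- if (expr$instr == "stay") s else 3L - s
      list(out = e, end = e)
    },
    concat = {
      out <- integer(0)
      for (tm in expr$terms) {
        r <- .lot_eval(tm, s)
        out <- c(out, r$out)
        s <- r$end
      }
      list(out = out, end = s)
    },
    `repeat` = {
      out <- integer(0)
      for (k in seq_len(expr$count)) {
        r <- .lot_eval(expr$body, s)
        out <- c(out, r$out)
        s <- r$end
        if (!is.null(expr$transform) && expr$transform == "flip") s <- 3L - s
      }
      list(out = out, end = s)
    },
    stop("malformed expression"))
}

#' Description length of an expression
#'
#' Sum of the instruction weight over every instruction occurrence (emitting
#' atoms and silent transforms alike, each counted once as written) plus the
#' digit cost of every repetition count.
#'
#' @param expr A `lot_expr`.
#' @param scheme A [lot_cost_scheme()].
#' @return Non-negative number (bits).
#' @examples
#' # [[+0]^8]^2<b> -> 2 instructions + 2 digits = 6
#' lot_expression_cost(lot_parse("[[+0]^8]^2<b>"))
#' @export
lot_expression_cost <- function(expr, scheme = lot_cost_scheme()) {
  stopifnot(inherits(expr, "lot_expr"), inherits(scheme, "lot_cost_scheme"))
  w <- scheme$instruction_weight
  rec <- function(e) {
    switch(e$type,
      atom = w,
      concat = sum(vapply(e$terms, rec, 0)),
      `repeat` = rec(e$body) + scheme$digit_cost(e$count) +
        (if (is.null(e$transform)) 0 else w))
  }
  rec(expr)
}

#' Hierarchical depth of an expression
#'
#' The maximum number of repetition nodes on any root-to-leaf path. A flat,
#' repetition-free expression has depth 1 by convention; a single repetition
#' level also counts 1, so one level of embedding (`[[x]^n]^m`) gives 2.
#'
#' @param expr A `lot_expr`.
#' @return Integer `>= 1`.
#' @export
lot_expression_depth <- function(expr) {
  stopifnot(inherits(expr, "lot_expr"))
  rec <- function(e) {
    switch(e$type,
      atom = 0L,
      concat = max(vapply(e$terms, rec, 0L)),
      `repeat` = 1L + rec(e$body))
  }
  max(1L, rec(expr))
}

#' Render an expression in surface notation
#'
#' Atoms are `+0` and `b`, repetition is `[body]^n` with an optional silent
#' transform `<+0>` / `<b>`, concatenation is comma-separated. Brackets around
#' repeated bodies are mandatory, which makes the notation unambiguous:
#' `lot_parse(lot_render(e))` is structurally identical to `e`.
#'
#' @param expr A `lot_expr`.
#' @return A notation string such as `"[[+0]^8]^2<b>"`.
#' @export
lot_render <- function(expr) {
  stopifnot(inherits(expr, "lot_expr"))
  rec <- function(e) {
    switch(e$type,
      atom = if (e$instr == "stay") "+0" else "b",
      concat = paste(vapply(e$terms, rec, ""), collapse = ","),
      `repeat` = {
        tr <- if (is.null(e$transform)) "" else
          paste0("<", if (e$transform == "stay") "+0" else "b", ">")
        paste0("[", rec(e$body), "]^", e$count, tr)
      })
  }
  rec(expr)
}

#' Parse surface notation into an expression
#'
#' Accepts the grammar `expr := term ("," expr)?` with
#' `term := "+0" | "b" | "[" expr "]" "^" int ("<" ("+0"|"b") ">")?`.
#' Whitespace is ignored. Malformed input raises an error reporting the
#' character position at which parsing failed.
#'
#' @param text A notation string.
#' @return A `lot_expr`.
#' @examples
#' lot_parse("[+0]^4<b>")
#' @export
lot_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1L]]
  n <- length(chars)
  pos <- 1L
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg),
                             call. = FALSE)
  peek <- function() if (pos <= n) chars[pos] else ""
  eat <- function(ch) {
    if (peek() != ch) fail(sprintf("expected \"%s\"", ch))
    pos <<- pos + 1L
  }
  parse_instr <- function() {
    if (peek() == "b") { pos <<- pos + 1L; return("flip") }
    if (peek() == "+") {
      eat("+"); eat("0"); return("stay")
    }
    fail("expected \"+0\" or \"b\"")
  }
  parse_int <- function() {
    start <- pos
    while (grepl("[0-9]", peek())) pos <<- pos + 1L
    if (pos == start) fail("expected an integer")
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  parse_term <- function() {
    if (peek() == "[") {
      eat("[")
      body <- parse_expr()
      eat("]")
      eat("^")
      cnt <- parse_int()
      if (cnt < 1L) fail("repetition count must be >= 1")
      tr <- NULL
      if (peek() == "<") {
        eat("<")
        tr <- parse_instr()
        eat(">")
      }
      lot_repeat(body, cnt, tr)
    } else {
      lot_atom(parse_instr())
    }
  }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (peek() == ",") {
      eat(",")
      terms <- c(terms, list(parse_term()))
    }
    if (length(terms) == 1L) terms[[1L]] else lot_concat(terms)
  }
  out <- parse_expr()
  if (pos <= n) fail("trailing input")
  out
}

#' @export
print.lot_expr <- function(x, ...) {
  ev <- lot_evaluate(x)
  cat("<lot_expr> ", lot_render(x), "\n  from A: ", ev$emitted,
      " (ends in ", ev$end_state, ")\n", sep = "")
  invisible(x)
}
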