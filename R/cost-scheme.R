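#' Description-length cost scheme for the binary language of thought
#'
#' The description length of an expression is a weighted sum of its primitive
#' instructions (the emitting atoms `+0` / `b` and the silent `<...>`
#' transforms, each counted once per occurrence in the written expression) plus
#' a digit cost for every repetition count: `ceil(log10(n))` digits, the number
#' of decimal digits needed to write `n`, with `n = 1` costing 0.
#'
#' With the default instruction weight of 2 a single repetition already
#' compresses: `[+0]^2` (cost 2 + 1 = 3) is shorter than `+0,+0` (cost 4).
#'
#' @param instruction_weight Non-negative cost of one instruction occurrence
#'   (default 2).
#' @param digit_cost Function mapping an integer repetition count to its digit
#'   cost. The default is `ceil(log10(n))` with `digit_cost(1) = 0`; note this
#'   literal reading makes `n = 10` cost 1.
#' @return An object of class `lot_cost_scheme`.
#' @examples
#' sc <- lot_cost_scheme()
#' sc$digit_cost(c(1, 2, 9, 10, 16))  # 0 1 1 1 2
#' @export
lot_cost_scheme <- function(instruction_weight = 2,
                            digit_cost = lot_digit_cost) {
  stopifnot(is.numeric(instruction_weight), length(instruction_weight) == 1L,
            instruction_weight >= 0, is.function(digit_cost))
  structure(list(instruction_weight = instruction_weight,
                 digit_cost = digit_cost),
            class = "lot_cost_scheme")
}

#' Default digit cost: decimal digits of the repetition count, rounded up
#'
#' `ceil(log10(n))`, with `n = 1` mapped to 0. Vectorised.
#'
#' @param n Integer repetition count(s), `n >= 1`.
#' @return Numeric vector of digit costs.
#' @export
lot_digit_cost <- function(n) {
  stopifnot(all(n >= 1))
  # round() guards against log10(1000) = 2.9999... artefacts
  ifelse(n <= 1, 0, ceiling(round(log10(n), 12)))
}

#' @export
print.lot_cost_scheme <- function(x, ...) {
  cat("<lot_cost_scheme> instruction weight:", x$instruction_weight,
      "| digit cost: ceil(log10(n)), n=1 -> 0\n")
  invisible(x)
}
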