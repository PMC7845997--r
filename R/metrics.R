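#' @title Rival complexity metrics for binary sequences
#'
#' @description Six previously proposed complexity measures that can be raced
#' against LoT complexity as predictors of sequence memory: run/chunk
#' complexity, pair entropy, LZ78 vocabulary size, subsymmetry counts,
#' change complexity, and an external algorithmic-complexity (ACSS) lookup.
#' @name alt_metrics
NULL

#' Run decomposition of a sequence
#'
#' Maximal runs ("chunks") of consecutive identical items, in order.
#'
#' @param pattern A sequence over `{A,B}`.
#' @return A list with `runs` (data.frame of `item`, `length`) and `K`
#'   (number of runs).
#' @examples
#' run_lengths("AAABAA")$K  # 3
#' @export
run_lengths <- function(pattern) {
  x <- strsplit(.check_pattern(pattern), "")[[1L]]
  r <- rle(x)
  list(runs = data.frame(item = r$values, length = r$lengths,
                         stringsAsFactors = FALSE),
       K = length(r$values))
}

#' Chunk complexity
#'
#' `sum_i log2(1 + L_i)` over the run decomposition, following the digit-span
#' chunking account: each run of length `L` costs `log2(1 + L)` bits.
#'
#' @param pattern A sequence over `{A,B}`.
#' @return Bits.
#' @examples
#' chunk_complexity("AAABAA")  # log2(4) + log2(2) + log2(3)
#' @export
chunk_complexity <- function(pattern) {
  sum(log2(1 + run_lengths(pattern)$runs$length))
}

#' Shannon entropy of item pairs
#'
#' Entropy of the distribution of adjacent pairs (AA, AB, BA, BB), with the
#' pair probability factored as `p(X, Y) = p(X) * p(Y|X)`: marginal item
#' frequencies over the whole sequence, maximum-likelihood first-order
#' transition probabilities from its single linear presentation, and the
#' convention `0 * log2(0) = 0`. Bounded by 2 bits (four outcomes).
#'
#' @param pattern A sequence over `{A,B}` of length >= 2.
#' @return Bits in `[0, 2]`.
#' @export
pair_entropy <- function(pattern) {
  x <- .seq_int(.check_pattern(pattern))
  if (length(x) < 2L) stop("pair entropy needs length >= 2", call. = FALSE)
  p_item <- tabulate(x, 2L) / length(x)
  trans <- matrix(0, 2L, 2L)
  for (k in seq_len(length(x) - 1L))
    trans[x[k], x[k + 1L]] <- trans[x[k], x[k + 1L]] + 1
  rs <- rowSums(trans)
  h <- 0
  for (a in 1:2) for (b in 1:2) {
    if (rs[a] == 0) next
    pc <- trans[a, b] / rs[a]
    joint <- p_item[a] * pc
    if (joint > 0) h <- h - joint * (log2(p_item[a]) + log2(pc))
  }
  h
}

#' LZ78 complexity
#'
#' Number of phrases in the incremental Lempel-Ziv (LZ78) parse: scanning
#' left to right, each phrase is the shortest prefix of the remaining input
#' not yet in the vocabulary, which is then added to it. For
#' `AABBAABBAABBAABB` the first four phrases are A, AB, B, AA and the final
#' vocabulary has 8 entries.
#'
#' @param pattern A sequence over `{A,B}`.
#' @param count_incomplete Count a final phrase left incomplete at the end
#'   of the scan (already in the vocabulary) as one entry (default `TRUE`;
#'   the worked examples in the literature end on complete parses, so either
#'   convention reproduces them).
#' @return Integer phrase count.
#' @examples
#' lz78_complexity("AABBAABBAABBAABB")  # 8
#' @export
lz78_complexity <- function(pattern, count_incomplete = TRUE) {
  length(lz78_phrases(pattern, count_incomplete))
}

#' @return For `lz78_phrases()`: the parsed phrases in scan order; a final
#'   incomplete phrase (if counted) is marked with a trailing `*`.
#' @rdname lz78_complexity
#' @examples
#' lz78_phrases("AABBAABBAABBAABB")[1:4]  # "A" "AB" "B" "AA"
#' @export
lz78_phrases <- function(pattern, count_incomplete = TRUE) {
  x <- strsplit(.check_pattern(pattern), "")[[1L]]
  vocab <- character(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    j <- i
    while (paste(x[i:j], collapse = "") %in% vocab && j < n) {
      j <- j + 1L
    }
    phrase <- paste(x[i:j], collapse = "")
    if (!(phrase %in% vocab)) {
      vocab <- c(vocab, phrase)
    } else if (count_incomplete) {
      # scan ended inside a phrase already in the vocabulary
      vocab <- c(vocab, paste0(phrase, "*"))
    }
    i <- j + 1L
  }
  vocab
}

#' Number of subsymmetries
#'
#' Count of contiguous palindromic substrings of length >= 2 (single items do
#' not count). `AABBAB` has four: AA, BB, BAB and ABBA; the pure alternation
#' `(AB)^8` has 56.
#'
#' @param pattern A sequence over `{A,B}`.
#' @return Integer count.
#' @export
subsymmetries <- function(pattern) {
  x <- .seq_int(.check_pattern(pattern))
  n <- length(x)
  total <- 0L
  # centre expansion, even and odd centres
  for (c in seq_len(n)) {
    # odd length, centre c: count palindromes of length >= 3
    r <- 1L
    while (c - r >= 1L && c + r <= n && x[c - r] == x[c + r]) {
      total <- total + 1L
      r <- r + 1L
    }
    # even length, centre between c and c+1
    r <- 0L
    while (c - r >= 1L && c + r + 1L <= n && x[c - r] == x[c + r + 1L]) {
      total <- total + 1L
      r <- r + 1L
    }
  }
  total
}

#' Change complexity
#'
#' A reconstruction of the change-based complexity measure: complexity lives
#' in the transitions, not the items. The sequence is reduced to its change
#' signal (1 where adjacent items differ), the signal is segmented into
#' maximal change episodes, and each episode of length `L` contributes
#' `log2(1 + L)` bits -- the run-encoding cost of the change signal's active
#' stretches. Constant sequences score 0; a periodic concatenation of `k`
#' copies of a motif whose change episodes do not merge across junctions
#' scores exactly `k` times the motif plus junction terms, reproducing the
#' factor-3 relation between AAABBB and AAABBBAAABBB; pure alternations stay
#' cheap (one long episode) while irregular mixtures of runs and alternations
#' are expensive, with an upper bound near `n/2`. The exact published variant
#' of the measure is not reproduced here; see the package vignette.
#'
#' @param pattern A sequence over `{A,B}` of length >= 2.
#' @return Non-negative number.
#' @examples
#' change_complexity("AAABBBAAABBB") / change_complexity("AAABBB")  # 3
#' @export
change_complexity <- function(pattern) {
  x <- .seq_int(.check_pattern(pattern))
  if (length(x) < 2L) stop("change complexity needs length >= 2", call. = FALSE)
  d <- as.integer(x[-1L] != x[-length(x)])
  r <- rle(d)
  ep <- r$lengths[r$values == 1L]
  if (!length(ep)) return(0)
  sum(log2(1 + ep))
}

#' Load an external algorithmic-complexity (ACSS) table
#'
#' Algorithmic complexity for short strings is approximated elsewhere via the
#' coding theorem (output frequencies of small Turing machines) and published
#' as lookup tables; it is not computed here. The loader reads a CSV with
#' columns `pattern` and `acss`.
#'
#' @param path CSV file with header `pattern,acss`.
#' @return An object of class `acss_table` (named numeric vector).
#' @export
read_acss_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pattern", "acss") %in% names(df)))
    stop("ACSS table must have columns 'pattern' and 'acss'", call. = FALSE)
  bad <- !grepl("^[AB]+$", df$pattern)
  if (any(bad))
    stop(sprintf("ACSS table rows with non-AB patterns: %s",
                 paste(utils::head(which(bad)), collapse = ", ")), call. = FALSE)
  acss_table(stats::setNames(as.numeric(df$acss), df$pattern))
}

#' @param values Named numeric vector mapping patterns to ACSS values.
#' @rdname read_acss_table
#' @export
acss_table <- function(values = numeric(0)) {
  stopifnot(is.numeric(values))
  if (length(values) && is.null(names(values)))
    stop("values must be named by pattern", call. = FALSE)
  structure(values, class = "acss_table")
}

#' Look up the algorithmic complexity of a pattern
#'
#' Exact-string lookup trying both labelings (the table may store either
#' representative of the A/B-relabelling class). Absent patterns return
#' `NA`, never an error.
#'
#' @param pattern Character vector of sequences over `{A,B}`.
#' @param table An [acss_table()].
#' @return Numeric vector, `NA` where no value is available.
#' @export
acss_lookup <- function(pattern, table) {
  stopifnot(inherits(table, "acss_table"))
  vapply(pattern, function(p) {
    .check_pattern(p)
    v <- unclass(table)[p]
    if (is.na(v)) v <- unclass(table)[.flip_pattern(p)]
    unname(v)
  }, 0, USE.NAMES = FALSE)
}

#' Metric table for a set of sequences
#'
#' One row per sequence with every complexity predictor used in the model
#' race: LoT and LoT-chunk complexity, chunk complexity, pair entropy, LZ78,
#' subsymmetries, change complexity, optional ACSS, plus length, period and
#' the minimal expressions' hierarchical depth.
#'
#' @param pattern Character vector of sequences over `{A,B}`.
#' @param acss Optional [acss_table()].
#' @param scheme A [lot_cost_scheme()].
#' @return A data.frame keyed by canonical `pattern`.
#' @export
sequence_metrics <- function(pattern, acss = NULL, scheme = lot_cost_scheme()) {
  canon <- canonicalize_sequence(pattern)
  enc <- lapply(canon, minimal_description, scheme = scheme,
                max_expressions = 64)
  data.frame(
    pattern = canon,
    length = nchar(canon),
    lot = vapply(enc, `[[`, 0, "complexity"),
    lot_chunk = lot_complexity(canon, chunk_preserving = TRUE, scheme = scheme),
    chunk = vapply(canon, chunk_complexity, 0, USE.NAMES = FALSE),
    entropy = vapply(canon, pair_entropy, 0, USE.NAMES = FALSE),
    lz = vapply(canon, lz78_complexity, 0L, USE.NAMES = FALSE),
    subsym = vapply(canon, subsymmetries, 0L, USE.NAMES = FALSE),
    change = vapply(canon, change_complexity, 0, USE.NAMES = FALSE),
    acss = if (is.null(acss)) NA_real_ else acss_lookup(canon, acss),
    period = vapply(canon, sequence_period, 0L, USE.NAMES = FALSE),
    depth = vapply(enc, `[[`, 0L, "depth"),
    stringsAsFactors = FALSE, row.names = NULL)
}
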