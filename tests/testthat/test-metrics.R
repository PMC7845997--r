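# Rival complexity metrics.

test_that("run decomposition and chunk complexity follow the run formula", {
  r <- run_lengths("AAABAA")
  expect_equal(r$K, 3)
  expect_equal(r$runs$item, c("A", "B", "A"))
  expect_equal(r$runs$length, c(3L, 1L, 2L))
  expect_equal(run_lengths("A")$K, 1)
  expect_equal(run_lengths("AAABBBAA")$K, 3)
  expect_equal(chunk_complexity("AAABAA"), log2(4) + log2(2) + log2(3))
  expect_equal(chunk_complexity("A"), 1)
  expect_equal(chunk_complexity("ABABABAB"), 8)
})

test_that("pair entropy matches the four-term formula and its bounds", {
  expect_equal(pair_entropy("AAAAAAAA"), 0)
  expect_equal(pair_entropy("AAAAAAAABBBBBBBB"), 1.271782, tolerance = 1e-6)
  for (p in sequence_catalog(8, balanced_only = TRUE)) {
    h <- pair_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, 2)
    expect_equal(pair_entropy(chartr("AB", "BA", p)), h)
  }
  expect_error(pair_entropy("A"), "length")
})

test_that("LZ78 parses shortest-new-phrase left to right", {
  expect_equal(lz78_phrases("AABBAABBAABBAABB")[1:4], c("A", "AB", "B", "AA"))
  expect_equal(lz78_complexity("AABBAABBAABBAABB"), 8)
  expect_equal(lz78_complexity("A"), 1)
  expect_equal(lz78_complexity("ABABABAB"), 5)
  expect_equal(lz78_complexity("ABABABAB", count_incomplete = FALSE), 4)
  # relabeling invariance and sublinear growth on repeated text
  expect_equal(lz78_complexity("BBAABBAA"), lz78_complexity("AABBAABB"))
  reps <- vapply(c(2, 4, 8, 16), function(k)
    lz78_complexity(strrep("AAB", k)), 0L)
  expect_true(all(diff(reps) / reps[-length(reps)] < 1))
  expect_lt(reps[4], 3 * 16 / 2)
})

test_that("subsymmetries counts palindromic substrings of length >= 2", {
  expect_equal(subsymmetries("AABBAB"), 4)
  expect_equal(subsymmetries("ABABABABABABABAB"), 56)
  expect_equal(subsymmetries("AAAABBBBAAAABBBB"), 32)
  expect_equal(subsymmetries("AB"), 0)
})

test_that("subsymmetries agrees with an O(n^3) brute force up to length 12", {
  brute <- function(p) {
    x <- strsplit(p, "")[[1]]
    n <- length(x)
    total <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- x[i:j]
      if (all(s == rev(s))) total <- total + 1L
    }
    total
  }
  for (L in 2:9) for (p in sequence_catalog(L))
    expect_equal(subsymmetries(p), brute(p), info = p)
  set.seed(3)
  for (L in 10:12) {
    for (p in sample(sequence_catalog(L), 40))
      expect_equal(subsymmetries(p), brute(p), info = p)
  }
})

test_that("change complexity is zero for constants and scales by copies", {
  expect_equal(change_complexity("AAAA"), 0)
  expect_equal(change_complexity("BBBBBBB"), 0)
  expect_equal(change_complexity("AAABBBAAABBB"),
               3 * change_complexity("AAABBB"))
  for (p in sequence_catalog(8, balanced_only = TRUE))
    expect_equal(change_complexity(chartr("AB", "BA", p)),
                 change_complexity(p))
  # alternation stays cheap relative to irregular mixtures of same length
  expect_lt(change_complexity("ABABABAB"), change_complexity("AABBABAB"))
})

test_that("ACSS lookup is an exact-string table with labeling fallback", {
  tab <- read_acss_table(system.file("extdata", "acss_synthetic.csv",
                                     package = "binlot"))
  expect_equal(acss_lookup("AAAAAA", tab), 10.85)
  # stored as BABBAA; looked up under the flipped labeling
  expect_equal(acss_lookup("ABAABB", tab), 15.31)
  expect_true(is.na(acss_lookup("ABABABABABABABAB", tab)))
  empty <- acss_table()
  expect_true(all(is.na(acss_lookup(c("A", "AB"), empty))))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("pattern,acss", "AXB,1"), bad)
  expect_error(read_acss_table(bad), "non-AB")
  writeLines(c("seq,value", "AAB,1"), bad)
  expect_error(read_acss_table(bad), "columns")
})

test_that("sequence_metrics assembles one row per sequence", {
  m <- sequence_metrics(c("BABABA", "AAABBB"),
                        acss = acss_table(c(ABABAB = 12.05)))
  expect_equal(nrow(m), 2)
  expect_equal(m$pattern, c("ABABAB", "AAABBB"))  # canonicalized
  expect_equal(m$lot, c(5, 6))
  expect_equal(m$acss, c(12.05, NA))
  expect_true(all(c("lot_chunk", "chunk", "entropy", "lz", "subsym",
                    "change", "period", "depth") %in% names(m)))
})
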