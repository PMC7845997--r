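# Trial classification, RT trimming, LISAS, exclusion, scoring.

test_that("classification is exhaustive, exclusive and window-based", {
  tb <- rbind(
    toy_block("P1", "S1", "ABBAAB", rts = c(994, 2600, 150), miss = 1,
              fa = 1, ns = 3))
  ct <- classify_trials(tb)
  expect_equal(as.character(ct$outcome[1:4]),
               c("hit", "miss", "miss", "miss"))  # 2600 and 150 outside window
  std <- ct[ct$deviant_type == "none", ]
  expect_equal(sum(std$outcome == "false_alarm"), 1)
  expect_equal(sum(std$outcome == "correct_rejection"), 2)
  expect_false(any(is.na(ct$outcome)))
  # window edges are inclusive
  tb2 <- toy_block("P1", "S1", "ABBAAB", rts = c(200, 2500), ns = 0)
  expect_equal(as.character(classify_trials(tb2)$outcome), c("hit", "hit"))
})

test_that("negative RTs are rejected with a warning", {
  tb <- toy_block("P1", "S1", "ABBAAB", rts = c(500, -20), ns = 0)
  expect_warning(ct <- classify_trials(tb), "negative")
  expect_equal(nrow(ct), 1)
})

test_that("trimming removes RTs beyond 2.5 SD of the cell median", {
  # 2400 ms is a valid hit but far beyond 2.5 leave-one-out SDs of the rest
  tb <- toy_block("P1", "S1", "ABBAAB", rts = c(500, 510, 520, 2400), ns = 0)
  tr <- trim_rts(classify_trials(tb))
  expect_equal(sum(tr$trials$rt_trimmed), 1)
  expect_true(tr$trials$rt_trimmed[tr$trials$rt_ms == 2400])
  expect_equal(tr$fraction, 0.25)
  # constant cell: SD 0, nothing removed
  tb2 <- toy_block("P1", "S1", "ABBAAB", rts = c(600, 600, 600), ns = 0)
  expect_equal(sum(trim_rts(classify_trials(tb2))$trials$rt_trimmed), 0)
  # hits stay hits for miss-rate purposes
  expect_equal(as.character(tr$trials$outcome[tr$trials$rt_trimmed]), "hit")
})

test_that("trimming removes a small share of Gaussian RTs", {
  set.seed(21)
  blocks <- lapply(1:80, function(i)
    toy_block(sprintf("P%02d", i), "S1", "ABBAAB",
              rts = pmax(200, rnorm(12, 800, 150)), ns = 0))
  tr <- trim_rts(classify_trials(do.call(rbind, blocks)))
  expect_gt(tr$fraction, 0.002)
  expect_lt(tr$fraction, 0.04)
})

test_that("LISAS reduces to mean RT at perfect accuracy and scales linearly", {
  expect_equal(lisas(731, 0, 120, 0.2), 731)
  expect_equal(lisas(600, 0.2, 100, 0.1), 800)
  base <- lisas(600, 0.2, 100, 0.1)
  expect_equal(lisas(600, 0.2, 200, 0.1) - 600, 2 * (base - 600))
  expect_gte(lisas(500, 0.5, 80, 0.4), 500)
  expect_error(lisas(600, 0.2, 100, 0), "undefined")
  expect_equal(lisas(600, 0, 100, 0), 600)
})

test_that("participant exclusion flags outliers with reasons, keeps ties", {
  s <- data.frame(participant = sprintf("P%d", 1:10),
                  miss_rate = c(rep(0.1, 9), 0.1),
                  mean_rt = c(rep(700, 9), 700),
                  false_alarms = c(rep(2, 9), 30))
  ex <- exclude_participants(s)
  expect_equal(ex$excluded, "P10")
  expect_equal(ex$reasons$criterion, "false_alarms")
  # homogeneous group: SD = 0, values equal the median -> strict > keeps all
  s2 <- s
  s2$false_alarms <- 2
  ex2 <- exclude_participants(s2)
  expect_length(ex2$excluded, 0)
  expect_length(ex2$kept, 10)
  expect_error(exclude_participants(s[1:2, ]), "3 participants")
})

test_that("sequence scores aggregate hits, misses and false alarms", {
  tb <- rbind(
    toy_block("P1", "S1", "ABBAAB", rts = rep(700, 4), fa = 2, ns = 6),
    toy_block("P1", "S2", "ABABAB", rts = c(650, 700, 750), miss = 1, fa = 0,
              ns = 6),
    toy_block("P2", "S1", "ABBAAB", rts = rep(650, 4), fa = 1, ns = 6),
    toy_block("P2", "S2", "ABABAB", rts = rep(650, 4), fa = 0, ns = 6))
  ct <- classify_trials(tb)
  sc <- sequence_scores(ct)
  # all-hit constant-RT cells: lisas equals the RT
  p2 <- sc[sc$participant == "P2", ]
  expect_equal(p2$lisas, c(650, 650))
  expect_equal(p2$rt_c, c(650, 650))
  expect_equal(p2$miss_rate, c(0, 0))
  # hand-counted false alarms per sequence
  expect_equal(sc$false_alarms[sc$participant == "P1" &
                                 sc$sequence_id == "S1"], 2)
  expect_equal(sc$false_alarms[sc$participant == "P2" &
                                 sc$sequence_id == "S1"], 1)
  # P1/S2 has a miss: lisas > rt_c
  r <- sc[sc$participant == "P1" & sc$sequence_id == "S2", ]
  expect_gt(r$lisas, r$rt_c)
})

test_that("scores join predictors and flag missing ones", {
  tb <- rbind(toy_block("P1", "S1", "ABBAAB", rts = rep(700, 3)),
              toy_block("P1", "S2", "ABABAB", rts = rep(700, 3)),
              toy_block("P2", "S1", "ABBAAB", rts = rep(600, 3)),
              toy_block("P2", "S2", "ABABAB", rts = rep(600, 3)))
  ct <- classify_trials(tb)
  metrics <- sequence_metrics("ABBAAB")  # deliberately incomplete
  expect_warning(sc <- sequence_scores(ct, metrics = metrics), "no metric")
  expect_true(all(sc$predictors_missing[sc$pattern == "ABABAB"]))
  expect_false(any(sc$predictors_missing[sc$pattern == "ABBAAB"]))
  expect_equal(nrow(sc), 4)
})
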