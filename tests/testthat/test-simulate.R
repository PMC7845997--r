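# Synthetic trial generator: determinism, schema, ground truth.

test_that("the same seed reproduces the identical trial table", {
  cfg <- sim_config(n_participants = 4, sequences = sequence_catalog(6)[1:5],
                    deviant_positions = list(4:6), seed = 99)
  a <- simulate_trials(cfg)
  b <- simulate_trials(cfg)
  expect_identical(a$trials, b$trials)
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write.csv(a$trials, fa, row.names = FALSE)
  write.csv(b$trials, fb, row.names = FALSE)
  expect_identical(readLines(fa), readLines(fb))
  # and a different seed does not
  c2 <- simulate_trials(sim_config(n_participants = 4,
                                   sequences = sequence_catalog(6)[1:5],
                                   deviant_positions = list(4:6),
                                   seed = 100))
  expect_false(identical(a$trials$rt_ms, c2$trials$rt_ms))
})

test_that("the trial table conforms to the schema and the design counts", {
  cfg <- sim_config(n_participants = 3, sequences = c("ABBAAB", "AAABBB"),
                    deviant_positions = list(4:6), trials_per_cell = 9,
                    standards_per_cell = 18, seed = 1)
  sim <- simulate_trials(cfg)
  tr <- sim$trials
  expect_true(all(c("participant", "experiment", "modality", "sequence_id",
                    "pattern", "trial", "deviant_type", "deviant_position",
                    "responded", "rt_ms") %in% names(tr)))
  expect_equal(nrow(tr), 3 * 2 * (9 + 18))
  expect_true(all(tr$deviant_position[tr$deviant_type != "none"] %in% 4:6))
  expect_true(all(is.na(tr$rt_ms) == !tr$responded))
  expect_true(all(tr$rt_ms >= 200, na.rm = TRUE))
  # classification accepts it directly
  expect_silent(classify_trials(tr))
})

test_that("degenerate configurations are refused", {
  expect_error(sim_config(sequences = character(0)), "length")
  expect_error(sim_config(trials_per_cell = 0), "trials_per_cell")
  expect_error(sim_config(deviant_positions = list(1:3)), "positions")
  expect_error(sim_config(rt_model = c(beta0 = 1, beta_complexity = 0,
                                       beta_surprise = 0,
                                       sd_participant = 0,
                                       sd_residual = 1)),
               "sd_participant")
})

test_that("null effects yield no complexity-performance correlation", {
  cfg <- sim_config(n_participants = 12,
                    sequences = sequence_catalog(8, balanced_only = TRUE),
                    rt_model = c(beta0 = 700, beta_complexity = 0,
                                 beta_surprise = 0, sd_participant = 120,
                                 sd_residual = 200),
                    miss_model = c(gamma0 = -2.5, gamma_complexity = 0,
                                   gamma_surprise = 0),
                    seed = 55)
  sim <- simulate_trials(cfg)
  tr <- trim_rts(classify_trials(sim$trials))$trials
  sc <- sequence_scores(tr,
                        metrics = data.frame(pattern = cfg$sequences,
                                             lot = lot_complexity(cfg$sequences)),
                        surprise = sim$truth$surprise)
  r <- per_sequence_correlation(sc, "lot")
  expect_lt(abs(r$r), 0.35)
})

test_that("empirical miss rates converge to the logistic model", {
  cfg <- sim_config(n_participants = 40, sequences = c("ABBAAB", "ABABAB"),
                    deviant_positions = list(4:6), trials_per_cell = 60,
                    standards_per_cell = 0,
                    miss_model = c(gamma0 = -2, gamma_complexity = 0.15,
                                   gamma_surprise = -0.2), seed = 7)
  sim <- simulate_trials(cfg)
  tr <- classify_trials(sim$trials)
  for (sq in unique(tr$sequence_id)) {
    d <- tr[tr$sequence_id == sq & tr$deviant_type == "sequence", ]
    # position-averaged expected miss probability
    pat <- d$pattern[1]
    S <- vapply(4:6, function(p) deviant_surprise(pat, p), 0)
    pexp <- mean(plogis(-2 + 0.15 * lot_complexity(pat) - 0.2 * S))
    pobs <- mean(d$outcome == "miss")
    se <- sqrt(pexp * (1 - pexp) / nrow(d))
    expect_lt(abs(pobs - pexp), 4 * se + 0.01)
  }
})

test_that("experiment presets mirror the published designs", {
  designs <- make_experiment_designs(seed = 1)
  expect_named(designs, paste0("exp", 1:5))
  expect_length(designs$exp3$sequences, 35)
  expect_length(designs$exp4$sequences, 32)
  expect_length(designs$exp5$sequences, 15)
  expect_true(all(c("ABABABABABABABAB", "AABBAABBAABBAABB",
                    "AAAABBBBAAAABBBB", "AAAAAAAABBBBBBBB") %in%
                    designs$exp1$sequences))
  expect_equal(designs$exp1$deviant_positions[[1]], c(9, 11, 13, 15))
  expect_length(designs$exp1$sequences, 10)
  expect_true(all(nchar(designs$exp2$sequences) == 12))
  # stand-ins are flagged
  expect_true(length(attr(designs$exp1, "stand_ins")) > 0)
  # super-deviants present only in the long-sequence designs
  s1 <- simulate_trials(sim_config(n_participants = 1,
                                   sequences = designs$exp1$sequences[1:2],
                                   deviant_positions = list(c(9, 11, 13, 15)),
                                   super_deviant_share = 1 / 3,
                                   trials_per_cell = 18, seed = 2))
  expect_true(any(s1$trials$deviant_type == "super"))
})
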