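# Mixed-model fitting, likelihood-ratio tests, Akaike weights, races.

make_mixed_data <- function(seed = 5, n_group = 15, n_per = 20,
                            beta = 50, group_sd = 80, resid_sd = 100) {
  set.seed(seed)
  g <- rep(sprintf("P%02d", seq_len(n_group)), each = n_per)
  x <- rnorm(n_group * n_per)
  u <- rep(rnorm(n_group, 0, group_sd), each = n_per)
  data.frame(participant = g, x = x,
             y = 500 + beta * x + u + rnorm(length(x), 0, resid_sd))
}

test_that("zero group variance degrades to OLS with matching likelihood", {
  # identical data in every group: the ML group variance is exactly zero
  set.seed(2)
  x1 <- rnorm(20)
  y1 <- 500 + 50 * x1 + rnorm(20, 0, 100)
  d <- data.frame(participant = rep(sprintf("P%02d", 1:15), each = 20),
                  x = rep(x1, 15), y = rep(y1, 15))
  f <- fit_lmm(d, "y", "x", "participant")
  expect_true(f$degenerate)
  ols <- lm(y ~ x, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$log_lik, as.numeric(logLik(ols)), tolerance = 1e-6)
  expect_equal(f$variance_components[["group"]], 0)
})

test_that("fit recovers a known slope and satisfies the AIC/BIC identities", {
  d <- make_mixed_data(seed = 6)
  f <- fit_lmm(d, "y", "x", "participant")
  est <- f$coefficients[f$coefficients$term == "x", ]
  expect_lt(abs(est$estimate - 50), 2 * est$std_error)
  expect_equal(f$aic, 2 * f$n_params - 2 * f$log_lik)
  expect_equal(f$bic, f$n_params * log(f$n_obs) - 2 * f$log_lik)
  expect_equal(f$n_params, 2 + 2)  # intercept + slope + 2 variances
})

test_that("adding a predictor never decreases the maximum likelihood", {
  d <- make_mixed_data(seed = 8)
  set.seed(1)
  d$junk <- rnorm(nrow(d))
  f0 <- fit_lmm(d, "y", "x", "participant")
  f1 <- fit_lmm(d, "y", c("x", "junk"), "participant")
  expect_gte(f1$log_lik + 1e-6, f0$log_lik)
})

test_that("likelihood-ratio test computes the chi-square tail", {
  d <- make_mixed_data(seed = 3)
  f0 <- fit_lmm(d, "y", character(0), "participant")
  f1 <- fit_lmm(d, "y", "x", "participant")
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$chi2, 2 * (f1$log_lik - f0$log_lik))
  expect_lt(lrt$p, 0.001)
  # identical models
  same <- likelihood_ratio_test(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # the published headline statistic is far in the tail
  expect_lt(pchisq(130.9, 1, lower.tail = FALSE), 1e-4)
  # non-nested specs refuse
  set.seed(2)
  d$z <- rnorm(nrow(d))
  fz <- fit_lmm(d, "y", "z", "participant")
  expect_error(likelihood_ratio_test(fz, f1), "nested")
})

test_that("the LRT statistic is invariant to affine predictor rescaling", {
  d <- make_mixed_data(seed = 13)
  d$x2 <- 3.7 * d$x - 12
  f0 <- fit_lmm(d, "y", character(0), "participant")
  a <- likelihood_ratio_test(f0, fit_lmm(d, "y", "x", "participant"))
  b <- likelihood_ratio_test(f0, fit_lmm(d, "y", "x2", "participant"))
  expect_equal(a$chi2, b$chi2, tolerance = 1e-4)
})

test_that("Akaike weights normalise exp(-delta/2) stably", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2, 1000))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # an hopeless extra model leaves the others unchanged to machine precision
  w2 <- akaike_weights(c(0, 2))
  expect_equal(w[1:2] / sum(w[1:2]), w2, tolerance = 1e-15)
  expect_equal(w[3], 0, tolerance = 1e-200)
  # huge shared offsets do not overflow
  expect_equal(akaike_weights(c(1e6, 1e6 + 2)),
               akaike_weights(c(0, 2)))
  expect_error(akaike_weights(3), "length")
})

test_that("model race ranks predictors on one common dataset", {
  sim <- simulate_trials(sim_config(
    n_participants = 12, sequences = sequence_catalog(6),
    deviant_positions = list(4:6), seed = 31,
    rt_model = c(beta0 = 600, beta_complexity = 60, beta_surprise = -30,
                 sd_participant = 100, sd_residual = 200)))
  tr <- trim_rts(classify_trials(sim$trials))$trials
  m <- sequence_metrics(unique(tr$pattern))
  sc <- sequence_scores(tr, metrics = m, surprise = sim$truth$surprise)
  race <- model_race(sc, c("lot", "chunk", "entropy"))
  expect_equal(nrow(race), 6)
  expect_equal(sum(race$w_aic), 1, tolerance = 1e-9)
  expect_equal(race$delta_aic[1], 0)
  expect_equal(race$predictor[1], "lot")
  # single-predictor race is trivially its own best
  solo <- model_race(sc, "lot", surprise = "without")
  expect_equal(solo$delta_aic, 0)
  # shuffled response supports no predictor strongly
  set.seed(77)
  sc$lisas <- sample(sc$lisas)
  r <- per_sequence_correlation(sc, "lot")
  expect_lt(abs(r$r), 0.5)
})

test_that("per-sequence correlation behaves on toy data", {
  sc <- data.frame(participant = rep(c("P1", "P2"), each = 6),
                   pattern = rep(sprintf("S%d", 1:6), 2),
                   lisas = rep(c(1, 2, 3, 4, 5, 6), 2))
  sc$self <- sc$lisas
  sc$anti <- -sc$lisas
  sc$flat <- 1
  expect_equal(per_sequence_correlation(sc, "self")$r, 1)
  expect_equal(per_sequence_correlation(sc, "anti")$r, -1)
  expect_error(per_sequence_correlation(sc, "flat"), "zero variance")
  cmp <- per_sequence_correlation(sc, "self", predictor2 = "anti")
  expect_equal(cmp$comparison$mean_diff, 2)
})
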