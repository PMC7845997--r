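#' @title Random-intercept model comparison
#'
#' @description Maximum-likelihood linear mixed models of performance scores
#' on complexity predictors with a per-participant random intercept, and the
#' machinery to race them: likelihood-ratio tests for nested pairs and
#' AIC/BIC/Akaike weights across a candidate set. All fits use ML (not REML)
#' so that likelihoods are comparable across fixed-effect structures;
#' p-values for single coefficients are Wald z statistics (no
#' Kenward-Roger approximation).
#' @name model_comparison
NULL

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' `response ~ fixed effects + (1 | grouping)`, fitted with ML. When the
#' estimated group variance is (numerically) zero, the fit is singular and
#' degrades gracefully to ordinary least squares: estimates equal OLS and
#' the result is flagged `degenerate`. The parameter count `n_params` is
#' always the number of fixed effects + 2 variance components, so AIC/BIC
#' stay comparable across a race.
#'
#' @param data A data.frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param grouping Grouping (participant) column name.
#' @return An object of class `lot_fit`: list with `log_lik`, `aic`, `bic`,
#'   `n_params`, `n_obs`, `coefficients` (data.frame of estimate/se/t),
#'   `variance_components`, `degenerate`, `spec`.
#' @export
fit_lmm <- function(data, response, fixed = character(0), grouping) {
  stopifnot(is.data.frame(data), response %in% names(data),
            grouping %in% names(data), all(fixed %in% names(data)))
  use <- stats::complete.cases(data[, c(response, fixed, grouping),
                                    drop = FALSE])
  data <- data[use, , drop = FALSE]
  if (length(unique(data[[grouping]])) < 2L)
    stop("grouping factor needs at least 2 levels", call. = FALSE)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 | %s)", response, rhs, grouping))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  degenerate <- lme4::isSingular(fit, tol = 1e-6)
  n <- nrow(data)
  if (degenerate) {
    ols <- stats::lm(stats::as.formula(sprintf("%s ~ %s", response, rhs)),
                     data = data)
    ll <- as.numeric(stats::logLik(ols))
    cf <- summary(ols)$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                        std_error = cf[, 2], t = cf[, 3],
                        stringsAsFactors = FALSE, row.names = NULL)
    vc <- c(group = 0, residual = sum(stats::residuals(ols)^2) / n)
  } else {
    ll <- as.numeric(stats::logLik(fit))
    cf <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        std_error = cf[, "Std. Error"], t = cf[, "t value"],
                        stringsAsFactors = FALSE, row.names = NULL)
    vcm <- lme4::VarCorr(fit)
    vc <- c(group = as.numeric(vcm[[grouping]]),
            residual = attr(vcm, "sc")^2)
  }
  k <- nrow(coefs) + 2L
  structure(list(log_lik = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 n_params = k, n_obs = n,
                 coefficients = coefs,
                 variance_components = vc,
                 degenerate = degenerate,
                 spec = list(response = response, fixed = fixed,
                             grouping = grouping)),
            class = "lot_fit")
}

#' @export
print.lot_fit <- function(x, ...) {
  cat(sprintf("<lot_fit> %s ~ %s + (1 | %s)%s\n",
              x$spec$response,
              if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ")
              else "1",
              x$spec$grouping,
              if (x$degenerate) "  [singular: OLS fallback]" else ""))
  cat(sprintf("  logLik %.2f | AIC %.1f | BIC %.1f | k = %d | n = %d\n",
              x$log_lik, x$aic, x$bic, x$n_params, x$n_obs))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between two nested ML fits
#'
#' `chi2 = 2 (logLik_full - logLik_null)` referred to a chi-square with
#' df = parameter difference. The null's fixed effects must be a subset of
#' the full's, on the same response and grouping.
#'
#' @param null,full [fit_lmm()] results, `null` nested in `full`.
#' @return `list(chi2, df, p)`.
#' @export
likelihood_ratio_test <- function(null, full) {
  stopifnot(inherits(null, "lot_fit"), inherits(full, "lot_fit"))
  if (!identical(null$spec$response, full$spec$response) ||
      !identical(null$spec$grouping, full$spec$grouping) ||
      !all(null$spec$fixed %in% full$spec$fixed))
    stop("models are not nested (same response/grouping, null fixed effects a subset of full's)",
         call. = FALSE)
  df <- full$n_params - null$n_params
  chi2 <- max(0, 2 * (full$log_lik - null$log_lik))
  list(chi2 = chi2, df = df,
       p = if (df <= 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; computed on the shifted values so that
#' large AICs cannot underflow the best model. Interpretable as the
#' probability that model i is the best of the set. Accepts raw AICs or
#' already-shifted Delta values (the weights are identical).
#'
#' @param aic Numeric vector of at least two finite AIC (or Delta AIC)
#'   values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  stopifnot(is.numeric(aic), length(aic) >= 2L, all(is.finite(aic)))
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Race predictors as single-fixed-effect mixed models
#'
#' Fits, for each predictor, a model with that predictor as the only fixed
#' effect (plus a participant random intercept) and optionally the same
#' model with mean deviant surprise as a covariate, then ranks the whole
#' set by AIC: Delta(AIC), Delta(BIC) and Akaike weights are relative to
#' the candidate set actually fitted. Rows with a missing value in *any*
#' raced predictor are dropped listwise first, so every model sees the same
#' data. A model that fails to fit is kept as a flagged row, not an error.
#'
#' @param scores A [sequence_scores()] table (or any data.frame).
#' @param predictors Character vector of predictor columns.
#' @param surprise `"both"` (default: with and without the surprise
#'   covariate), `"with"`, or `"without"`.
#' @param response Response column (default `"lisas"`).
#' @param grouping Grouping column (default `"participant"`).
#' @param extra Character vector of covariates included in every model
#'   (e.g. `"modality"`).
#' @return A data.frame, one row per model, ordered by AIC, with attribute
#'   `"fits"` carrying the `lot_fit` objects.
#' @export
model_race <- function(scores, predictors, surprise = c("both", "with",
                                                        "without"),
                       response = "lisas", grouping = "participant",
                       extra = character(0)) {
  surprise <- match.arg(surprise)
  stopifnot(all(predictors %in% names(scores)))
  if (surprise != "without" && !"surprise" %in% names(scores))
    stop("scores table has no 'surprise' column", call. = FALSE)
  need <- c(response, grouping, predictors, extra,
            if (surprise != "without") "surprise")
  scores <- scores[stats::complete.cases(scores[, need, drop = FALSE]), ,
                   drop = FALSE]
  specs <- list()
  for (p in predictors) {
    if (surprise %in% c("both", "without"))
      specs[[paste0(p)]] <- c(p, extra)
    if (surprise %in% c("both", "with"))
      specs[[paste0(p, " + surprise")]] <- c(p, "surprise", extra)
  }
  fits <- lapply(specs, function(fx) {
    tryCatch(fit_lmm(scores, response, fx, grouping),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  tab <- data.frame(
    model = names(specs),
    predictor = rep(predictors,
                    each = if (surprise == "both") 2L else 1L),
    with_surprise = grepl("surprise", names(specs)),
    log_lik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$log_lik, 0),
    aic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic, 0),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 0),
    converged = ok,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!any(ok)) stop("no model could be fitted", call. = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$delta_bic <- tab$bic - min(tab$bic, na.rm = TRUE)
  tab$w_aic <- NA_real_
  tab$w_aic[ok] <- if (sum(ok) == 1L) 1 else akaike_weights(tab$aic[ok])
  tab <- tab[order(tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "n_obs") <- nrow(scores)
  tab
}

#' Per-sequence correlation of a predictor with performance
#'
#' Pearson r between the participant-averaged score per sequence and the
#' predictor, plus the distribution of within-participant correlations.
#' When `predictor2` is given, the two predictors' within-participant
#' correlations are compared with a paired t test.
#'
#' @param scores A [sequence_scores()] table.
#' @param predictor Predictor column name.
#' @param predictor2 Optional second predictor to compare against.
#' @param response Response column (default `"lisas"`).
#' @return `list(r, n_sequences, participant_r, comparison)`; `comparison`
#'   is `NULL` unless `predictor2` is given.
#' @export
per_sequence_correlation <- function(scores, predictor, predictor2 = NULL,
                                     response = "lisas") {
  stopifnot(predictor %in% names(scores), response %in% names(scores))
  use <- stats::complete.cases(scores[, c(response, predictor), drop = FALSE])
  sc <- scores[use, , drop = FALSE]
  agg <- stats::aggregate(sc[, c(response, predictor)],
                          by = list(pattern = sc$pattern), FUN = mean)
  if (nrow(agg) < 3L) stop("need >= 3 sequences", call. = FALSE)
  if (stats::sd(agg[[predictor]]) == 0)
    stop("predictor has zero variance across sequences", call. = FALSE)
  r <- stats::cor(agg[[response]], agg[[predictor]])
  pr <- function(pred) {
    vapply(split(sc, sc$participant), function(d) {
      if (nrow(d) < 3L || stats::sd(d[[pred]]) == 0 ||
          stats::sd(d[[response]]) == 0) return(NA_real_)
      stats::cor(d[[response]], d[[pred]])
    }, 0)
  }
  participant_r <- pr(predictor)
  comparison <- NULL
  if (!is.null(predictor2)) {
    r2 <- pr(predictor2)
    keep <- !is.na(participant_r) & !is.na(r2)
    tt <- tryCatch(stats::t.test(participant_r[keep], r2[keep],
                                 paired = TRUE),
                   error = function(e) NULL)  # e.g. constant differences
    comparison <- list(predictor2 = predictor2, participant_r2 = r2,
                       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                       p = if (is.null(tt)) NA_real_ else tt$p.value,
                       mean_diff = mean(participant_r[keep] - r2[keep]))
  }
  list(r = r, n_sequences = nrow(agg), participant_r = participant_r,
       comparison = comparison)
}

#' Bar chart of a model race
#'
#' Horizontal Delta(AIC) bars, one per raced model, annotated with Akaike
#' weights -- the usual way to display a predictor race.
#'
#' @param race A [model_race()] table.
#' @param file Optional path; when given, a PDF is written there.
#' @return Invisibly, the race table.
#' @export
plot_model_race <- function(race, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 0.6 + 0.35 * nrow(race))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4, 11, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  ord <- rev(seq_len(nrow(race)))
  graphics::barplot(race$delta_aic[ord], names.arg = race$model[ord],
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = expression(Delta * "AIC"),
                    col = ifelse(race$with_surprise[ord], "grey70", "grey30"))
  invisible(race)
}
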