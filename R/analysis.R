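#' Standardize numeric columns
#'
#' Centers and scales the named columns to mean 0, SD 1 (sample-SD
#' convention). Constant columns are an error: a z-score is undefined.
#'
#' @param data Data frame.
#' @param cols Character vector of column names.
#' @return `data` with the named columns replaced by z-scores.
#' @export
standardize <- function(data, cols) {
  for (cl in cols) {
    assert_that(cl %in% names(data), paste("no column", cl))
    x <- data[[cl]]
    s <- stats::sd(x, na.rm = TRUE)
    assert_that(!is.na(s) && s > 0,
                paste("cannot standardize constant column", cl))
    data[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

# tidy coefficient table from an lm fit (aliased terms are dropped by
# summary(); align the CIs by term name)
lm_result_table <- function(fit) {
  co <- summary(fit)$coefficients
  ci <- stats::confint(fit)[rownames(co), , drop = FALSE]
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             statistic = co[, 3], df = fit$df.residual, p = co[, 4],
             ci_low = ci[, 1], ci_high = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress exploration on unpredictability with covariates
#'
#' Ordinary least squares of a participant-level exploration measure on the
#' (standardized) unpredictability score plus standardized covariates.
#' Outlier exclusion is the caller's responsibility
#' ([exclude_outliers()]).
#'
#' @param metrics Participant-level data frame (one row per child).
#' @param outcome Outcome column (default overall exploration rate).
#' @param predictor Unpredictability column.
#' @param covariates Covariate columns (standardized internally).
#' @return List of class `regression_result`: `table` (term, estimate, SE,
#'   t, df, p, CI), `model` (the `lm` fit), `n`.
#' @export
exploration_regression <- function(metrics, outcome = "p_explore_overall",
                                   predictor = "quic_total",
                                   covariates = c("digit_span", "income",
                                                  "anxiety")) {
  dat <- standardize(metrics, c(predictor, covariates))
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = dat)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    warning("dropped rank-deficient terms: ",
            paste(names(aliased)[aliased], collapse = ", "))
  structure(list(table = lm_result_table(fit), model = fit,
                 n = stats::nobs(fit)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> n =", x$n, "\n")
  print(cbind(x$table[1],
              round(x$table[vapply(x$table, is.numeric, logical(1))], 4)))
  invisible(x)
}

#' Trial-level logistic mixed model with an unpredictability interaction
#'
#' Regresses a binary per-game outcome (exploring at the first free choice,
#' or repeating the previous choice) on standardized unpredictability, a
#' binary moderator, their interaction, and standardized covariates, with a
#' participant random intercept (`lme4::glmer`, binomial). Moderators:
#' `horizon` (long vs short), `conflict` (informative option pays less),
#' or `uncertainty` (the previously chosen option was the once-shown one).
#' If the mixed model fails or does not converge, a pooled logistic
#' regression without the random intercept is fitted instead, with a
#' warning and a flag in the result (participant dummies are not an option
#' here: they would absorb the between-person predictors of interest).
#'
#' @param games Game-level table ([first_free_table()]) joined with
#'   participant scores -- must contain the outcome and moderator columns,
#'   `participant_id`, `predictor`, and `covariates`.
#' @param outcome "explore" or "habitual".
#' @param moderator "horizon", "conflict", or "uncertainty".
#' @param predictor Unpredictability column name.
#' @param covariates Covariate column names (participant-level).
#' @return List of class `glmm_result`: `table` (with odds ratios and CIs),
#'   `model`, `moderator`, `predictor`, `fallback` (TRUE when the
#'   fixed-effects approximation was used).
#' @export
trial_glmm <- function(games, outcome = c("explore", "habitual"),
                       moderator = c("horizon", "conflict", "uncertainty"),
                       predictor = "quic_total",
                       covariates = c("digit_span", "income", "anxiety")) {
  outcome <- match.arg(outcome)
  moderator <- match.arg(moderator)
  ycol <- switch(outcome, explore = "explored", habitual = "habitual")
  mcol <- switch(moderator, horizon = "horizon", conflict = "conflict",
                 uncertainty = "prev_was_info")
  assert_that(all(c(ycol, mcol, predictor, covariates, "participant_id")
                  %in% names(games)), "missing columns in games table")
  dat <- games
  dat$.y <- dat[[ycol]]
  dat$.mod <- if (mcol == "horizon")
    factor(dat$horizon, levels = c("short", "long"))
  else factor(dat[[mcol]], levels = c(0, 1),
              labels = switch(mcol,
                              conflict = c("no_conflict", "conflict"),
                              prev_was_info = c("familiar", "uncertain")))
  assert_that(length(unique(dat$.mod)) > 1,
              "moderator is constant; interaction not estimable")
  dat <- standardize(dat, c(predictor, covariates))
  fixed <- paste(".y ~", predictor, "* .mod +",
                 paste(covariates, collapse = " + "))
  fml <- stats::as.formula(paste(fixed, "+ (1 | participant_id)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = dat, family = stats::binomial))),
    error = function(e) NULL)
  # a singular (zero-variance) random intercept is benign; real convergence
  # failures are not
  msgs <- if (is.null(fit)) "error" else fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  fallback <- is.null(fit) || length(msgs) > 0
  if (fallback) {
    # pooled logistic approximation: participant dummies would absorb the
    # between-person predictors, so the intercept-only structure is dropped
    # entirely and the result is flagged
    warning("mixed model did not converge; ",
            "reporting pooled logistic regression instead")
    fit <- stats::glm(stats::as.formula(fixed), data = dat,
                      family = stats::binomial)
  }
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    z = co[, 3], p = co[, 4],
                    ci_low = co[, 1] - 1.96 * co[, 2],
                    ci_high = co[, 1] + 1.96 * co[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$odds_ratio <- exp(tab$estimate)
  tab$or_low <- exp(tab$ci_low)
  tab$or_high <- exp(tab$ci_high)
  structure(list(table = tab, model = fit, moderator = moderator,
                 predictor = predictor, fallback = fallback,
                 n_trials = nrow(dat),
                 n_participants = length(unique(dat$participant_id))),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat("<glmm_result>", x$n_trials, "trials,", x$n_participants,
      "participants; moderator:", x$moderator,
      if (x$fallback) "(fixed-effects fallback)" else "", "\n")
  print(cbind(x$table[1],
              round(x$table[vapply(x$table, is.numeric, logical(1))], 4)))
  invisible(x)
}

#' Estimated marginal effects of the predictor by moderator level
#'
#' Average slope of the predicted outcome probability with respect to the
#' (standardized) unpredictability score, evaluated at each moderator level
#' with covariates at their means (`emmeans::emtrends` on the response
#' scale, delta-method SEs).
#'
#' @param result A [trial_glmm()] result.
#' @param level Confidence level.
#' @return Data frame: moderator `level`, `M` (marginal effect, probability
#'   per SD), `se`, `ci_low`, `ci_high`.
#' @export
marginal_effects <- function(result, level = 0.95) {
  stopifnot(inherits(result, "glmm_result"))
  tr <- emmeans::emtrends(result$model, specs = ".mod",
                          var = result$predictor, regrid = "response",
                          level = level)
  s <- as.data.frame(summary(tr, infer = c(TRUE, FALSE)))
  trend_col <- grep("trend$", names(s), value = TRUE)[1]
  lcl <- grep("lower|LCL", names(s), value = TRUE)[1]
  ucl <- grep("upper|UCL", names(s), value = TRUE)[1]
  data.frame(level = as.character(s$.mod), M = s[[trend_col]], se = s$SE,
             ci_low = s[[lcl]], ci_high = s[[ucl]],
             stringsAsFactors = FALSE)
}

#' Mediation by the product of coefficients with a bootstrap CI
#'
#' Two nested linear regressions estimate the indirect path: the mediator
#' on the predictor (`a`), and the outcome on predictor plus mediator
#' (`b` and direct effect `c'`). The indirect effect is `a*b`; the total
#' effect `c` (outcome on predictor alone) satisfies `c = c' + a*b` exactly
#' for these linear fits. Significance of the indirect effect comes from a
#' percentile bootstrap resampling participants.
#'
#' @param data Participant-level data frame.
#' @param predictor,mediator,outcome Column names (e.g. unpredictability,
#'   habitual-responding rate, exploration rate).
#' @param covariates Covariate column names included in both regressions.
#' @param n_boot Bootstrap resamples (>= 1000).
#' @param seed Bootstrap seed (deterministic result per seed).
#' @param level Confidence level for the percentile interval.
#' @return List of class `mediation_result`: `path_a`, `path_b`,
#'   `indirect`, `direct`, `total`, `ci_indirect`, `boot` (the resampled
#'   indirect effects), `n`, `n_boot`.
#' @export
mediate_boot <- function(data, predictor = "quic_total",
                         mediator = "habitual_rate",
                         outcome = "p_explore_overall",
                         covariates = c("digit_span", "income", "anxiety"),
                         n_boot = 5000, seed = 1L, level = 0.95) {
  assert_that(n_boot >= 1000, "n_boot must be at least 1000")
  dat <- standardize(data, c(predictor, covariates))
  X <- as.matrix(cbind(1, dat[, c(predictor, covariates)]))
  Mv <- dat[[mediator]]
  Yv <- dat[[outcome]]
  paths <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    a <- stats::.lm.fit(Xi, Mv[idx])$coefficients[2]
    fit2 <- stats::.lm.fit(cbind(Xi, Mv[idx]), Yv[idx])$coefficients
    b <- fit2[ncol(Xi) + 1]
    cprime <- fit2[2]
    total <- stats::.lm.fit(Xi, Yv[idx])$coefficients[2]
    c(a = a, b = b, indirect = a * b, direct = cprime, total = total)
  }
  est <- paths(seq_len(nrow(X)))
  boot <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(X), replace = TRUE)
      paths(idx)[["indirect"]]
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(path_a = est[["a"]], path_b = est[["b"]],
                 indirect = est[["indirect"]], direct = est[["direct"]],
                 total = est[["total"]],
                 ci_indirect = c(lower = ci[1], upper = ci[2]),
                 boot = boot, n = nrow(X), n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> n =", x$n, "\n")
  cat(sprintf("  a = %.4f, b = %.4f, indirect ab = %.4f [%.4f, %.4f]\n",
              x$path_a, x$path_b, x$indirect, x$ci_indirect[1],
              x$ci_indirect[2]))
  cat(sprintf("  direct c' = %.4f, total c = %.4f\n", x$direct, x$total))
  invisible(x)
}

#' One-sample optimality tests of foraging thresholds
#'
#' Tests, per environment, whether participants' deviations from the
#' optimal exit threshold differ from zero (one-sample t test). Positive
#' mean deviation means leaving trees earlier than optimal --
#' over-exploration.
#'
#' @param thresholds Participant table from [compute_exit_thresholds()]
#'   with `deviation_rich` and `deviation_poor` columns.
#' @return Data frame: `environment`, `mean_deviation`, `t`, `df`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
optimality_tests <- function(thresholds) {
  one <- function(x, env) {
    x <- x[!is.na(x)]
    assert_that(length(x) >= 2, "need at least 2 participants per test")
    tt <- stats::t.test(x, mu = 0)
    data.frame(environment = env, mean_deviation = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, ci_low = tt$conf.int[1],
               ci_high = tt$conf.int[2], stringsAsFactors = FALSE)
  }
  rbind(one(thresholds$deviation_rich, "rich"),
        one(thresholds$deviation_poor, "poor"))
}

#' Environment effect on tree-level exit thresholds
#'
#' Linear mixed model of per-tree exit thresholds on environment type with
#' a participant random intercept (`lmerTest::lmer`, Satterthwaite df).
#' The reference level is the poor (long-travel) environment, so a positive
#' environment coefficient means higher thresholds -- earlier leaving -- in
#' rich orchards.
#'
#' @param tree_thresholds Tree-level table from
#'   `compute_exit_thresholds(..., per_tree = TRUE)`.
#' @return List of class `regression_result` (coefficient table + model).
#' @export
environment_effect <- function(tree_thresholds) {
  dat <- tree_thresholds
  dat$environment <- factor(dat$environment, levels = c("poor", "rich"))
  assert_that(length(unique(dat$environment)) == 2,
              "need both environments")
  fit <- lmerTest::lmer(exit_threshold ~ environment + (1 | participant_id),
                        data = dat)
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], statistic = co[, "t value"],
                    df = co[, "df"], p = co[, "Pr(>|t|)"],
                    ci_low = co[, "Estimate"] - 1.96 * co[, "Std. Error"],
                    ci_high = co[, "Estimate"] + 1.96 * co[, "Std. Error"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, model = fit, n = nrow(dat)),
            class = "regression_result")
}
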