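#' Effect configuration for the synthetic cohort
#'
#' Collects the generative settings of the synthetic-child generator: the
#' questionnaire (QUIC) total-score moment targets and latent-to-observed
#' reliability, covariate moments, the baseline choice-model parameters of
#' an average child, and the planted paths from latent unpredictability `U`
#' to the agent parameters. The default plants the habit route: higher `U`
#' raises the choice-repetition bonus K (`slope_repeat` points per SD of
#' `U`), which behaviorally lowers exploration; the direct route through
#' the information bonus (`slope_info`) is 0, so any association between
#' unpredictability and exploration is transmitted entirely through
#' habitual responding.
#'
#' Baseline choice parameters were chosen so that a default cohort shows
#' overall exploration near one half, a small positive horizon effect
#' (strategic exploration a few percentage points), and reward maximization
#' around 0.8 -- the aggregate behavior profile typical of late-childhood
#' samples on this task. `slope_repeat` and the individual spread
#' `sd_repeat` are sized so that the habit signal in an 80-game session
#' dominates the binomial measurement noise of the habitual-responding rate
#' (reliability above ~0.85), which is what makes mediation through the
#' *measured* mediator recoverable.
#'
#' @param slope_repeat Points of repeat bonus K per SD of latent `U`.
#' @param slope_info Points of information bonus per SD of latent `U`
#'   (the direct, non-habitual path; default 0 = full mediation).
#' @param quic_reliability Correlation between latent `U` and the common
#'   factor driving questionnaire items, in (0, 1].
#' @param quic_mean,quic_sd Target moments of the questionnaire total.
#' @param base_info_short,base_info_long Baseline information bonus, points.
#' @param base_spatial Baseline spatial bias, points.
#' @param base_noise Baseline decision noise, points.
#' @param base_repeat Baseline repeat bonus, points.
#' @param sd_info,sd_repeat Between-child SDs of the information and repeat
#'   bonuses beyond what `U` explains, points.
#' @param income_mean,income_sd,digit_mean,digit_sd Covariate moments
#'   (ordinal family-income scale; digit-span score).
#' @param threshold_bias Mean over-exploration of foraging thresholds
#'   relative to optimal, apples (children leave trees earlier than
#'   optimal).
#' @param threshold_child_sd Between-child SD of the foraging threshold
#'   offset, apples (shared across environments).
#' @param threshold_noise_sd Decision-level threshold noise, apples.
#' @return List of class `effect_config`.
#' @export
effect_config <- function(slope_repeat = 6, slope_info = 0,
                          quic_reliability = 0.8,
                          quic_mean = 5.63, quic_sd = 5.05,
                          base_info_short = 1.2, base_info_long = 2.6,
                          base_spatial = 0, base_noise = 8, base_repeat = 1,
                          sd_info = 1, sd_repeat = 8,
                          income_mean = 4.29, income_sd = 1.39,
                          digit_mean = 10.85, digit_sd = 3.18,
                          threshold_bias = 1.5, threshold_child_sd = 1,
                          threshold_noise_sd = 1) {
  assert_that(quic_reliability > 0 && quic_reliability <= 1,
              "quic_reliability must be in (0, 1]")
  assert_that(quic_mean > 0 && quic_mean < 38 && quic_sd > 0,
              "infeasible questionnaire moment targets")
  structure(as.list(environment()), class = "effect_config")
}

# QUIC subscale structure: 38 binary items in five groups
quic_subscales <- function() {
  c(parental_involvement = 9, parental_predictability = 12,
    parental_environment = 7, physical_environment = 7,
    safety_security = 3)
}

# Moment-match the item model: items share a common factor with loading
# lambda and threshold tau; solve (lambda, tau) so the 38-item total has the
# target mean and SD. Expectation over the factor taken on a fixed grid.
quic_item_params <- function(target_mean, target_sd, n_items = 38) {
  u <- seq(-6, 6, length.out = 601)
  w <- stats::dnorm(u); w <- w / sum(w)
  moments <- function(lambda, tau) {
    p <- stats::pnorm((lambda * u - tau) / sqrt(1 - lambda^2))
    m <- n_items * sum(w * p)
    v <- n_items * sum(w * p * (1 - p)) +
      n_items^2 * (sum(w * p^2) - sum(w * p)^2)
    c(m, sqrt(v))
  }
  obj <- function(th) {
    lambda <- stats::plogis(th[1])  # in (0,1)
    tau <- th[2]
    mm <- moments(lambda, tau)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  o <- stats::optim(c(stats::qlogis(0.8), 1), obj,
                    control = list(reltol = 1e-12, maxit = 2000))
  if (o$value > 1e-4)
    stop("questionnaire moment targets could not be matched")
  list(lambda = stats::plogis(o$par[1]), tau = o$par[2])
}

#' Score questionnaire items
#'
#' Sums 38 binary unpredictability items into the total score (range 0-38)
#' and the five subscale sums (9, 12, 7, 7, and 3 items).
#'
#' @param items Logical/0-1 vector of length 38, or a matrix with 38
#'   columns (rows = participants), ordered by subscale.
#' @return List with `total` and named `subscales` (vectors, or one row per
#'   participant for matrix input).
#' @export
quic_score <- function(items) {
  if (is.vector(items)) items <- matrix(items, nrow = 1)
  sizes <- quic_subscales()
  assert_that(ncol(items) == sum(sizes), "expected 38 items")
  assert_that(all(items %in% c(0, 1)), "items must be binary")
  idx <- rep(names(sizes), sizes)
  sub <- sapply(names(sizes), function(s)
    rowSums(items[, idx == s, drop = FALSE]))
  if (is.vector(sub)) sub <- matrix(sub, nrow = 1,
                                    dimnames = list(NULL, names(sizes)))
  list(total = rowSums(items), subscales = sub)
}

#' Generate a synthetic cohort of child participants
#'
#' Each child gets a latent unpredictability `U ~ N(0, 1)`; 38 binary
#' questionnaire items generated from a thresholded common-factor model
#' whose loading and threshold are moment-matched to the target total-score
#' mean and SD (right-skewed, many near-zero totals); covariates (ordinal
#' family income, digit span, a distress scalar, and a parent-report scalar
#' unrelated to behavior); and planted agent parameters for both tasks,
#' with the repeat bonus (and optionally the information bonus) depending
#' linearly on `U`.
#'
#' @param n Number of participants (>= 2).
#' @param config An [effect_config()].
#' @param seed RNG seed; the same seed reproduces the same cohort.
#' @return Data frame with one row per child: `participant_id`, `latent_U`,
#'   `quic_total`, the five `quic_*` subscale sums, `income`, `digit_span`,
#'   `anxiety`, `parent_report`, the horizon-task parameters
#'   (`info_bonus_short`, `info_bonus_long`, `spatial_bias`,
#'   `decision_noise`, `repeat_bonus`), and the foraging parameters
#'   (`exit_threshold_rich`, `exit_threshold_poor`, `threshold_noise_sd`,
#'   `block_order`). The 0/1 item matrix is attached as attribute
#'   `quic_items`.
#' @export
generate_cohort <- function(n, config = effect_config(), seed = NULL) {
  assert_that(n >= 2, "need at least 2 participants")
  stopifnot(inherits(config, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  U <- stats::rnorm(n)
  ip <- quic_item_params(config$quic_mean, config$quic_sd)
  r <- config$quic_reliability
  factor_score <- r * U + sqrt(1 - r^2) * stats::rnorm(n)
  n_items <- sum(quic_subscales())
  liab <- ip$lambda * factor_score +
    sqrt(1 - ip$lambda^2) * matrix(stats::rnorm(n * n_items), n, n_items)
  items <- (liab > ip$tau) * 1L
  sc <- quic_score(items)
  optimal <- c(rich = as.numeric(mvt_optimal_threshold(
                 orchard_config(travel_time = 6))),
               poor = as.numeric(mvt_optimal_threshold(
                 orchard_config(travel_time = 12))))
  info_dev <- config$slope_info * U + stats::rnorm(n, 0, config$sd_info)
  repeat_bonus <- config$base_repeat + config$slope_repeat * U +
    stats::rnorm(n, 0, config$sd_repeat)
  thr_off <- config$threshold_bias +
    stats::rnorm(n, 0, config$threshold_child_sd)
  out <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    latent_U = U,
    quic_total = sc$total,
    income = pmin(pmax(round_half_away(
      stats::rnorm(n, config$income_mean, config$income_sd)), 1), 7),
    digit_span = pmax(round_half_away(
      stats::rnorm(n, config$digit_mean, config$digit_sd)), 0),
    anxiety = stats::rnorm(n),
    parent_report = stats::rnorm(n),
    info_bonus_short = config$base_info_short + info_dev,
    info_bonus_long = config$base_info_long + info_dev,
    spatial_bias = config$base_spatial,
    decision_noise = config$base_noise,
    repeat_bonus = repeat_bonus,
    exit_threshold_rich = pmax(optimal[["rich"]] + thr_off, 0.5),
    exit_threshold_poor = pmax(optimal[["poor"]] + thr_off, 0.5),
    threshold_noise_sd = config$threshold_noise_sd,
    block_order = rep(c("ABAB", "BABA"), length.out = n),
    stringsAsFactors = FALSE)
  sub <- as.data.frame(sc$subscales)
  names(sub) <- paste0("quic_", names(sub))
  out <- cbind(out, sub)
  attr(out, "quic_items") <- items
  out
}

# build the horizon agent implied by one cohort row
cohort_agent <- function(row) {
  horizon_agent(
    info_bonus = row$info_bonus_short, spatial_bias = row$spatial_bias,
    decision_noise = row$decision_noise, repeat_bonus = row$repeat_bonus,
    horizon_specific = list(long = list(info_bonus = row$info_bonus_long)))
}

#' Simulate the full study for a cohort
#'
#' Every child plays the 80-game bandit schedule (a fresh randomized order
#' per child) and a four-orchard foraging session with their planted
#' parameters, yielding the two trial-log tables the metrics and analysis
#' stages consume.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param seed RNG seed for all task-level randomness.
#' @param environments Orchard environment pair ([orchard_environments()]).
#' @return List with `horizon` (trial records) and `foraging` (event
#'   records).
#' @export
simulate_study <- function(cohort, seed = NULL,
                           environments = orchard_environments()) {
  if (!is.null(seed)) set.seed(seed)
  horizon <- vector("list", nrow(cohort))
  foraging <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    sched <- horizon_schedule(seed = NULL)
    horizon[[i]] <- play_schedule(sched, cohort_agent(row),
                                  participant_id = row$participant_id)
    foraging[[i]] <- simulate_foraging_env_thresholds(
      row, environments, participant_id = row$participant_id)
  }
  list(horizon = do.call(rbind, horizon),
       foraging = do.call(rbind, foraging))
}

# session with environment-specific thresholds (rich blocks use the child's
# rich threshold, poor blocks the poor one)
simulate_foraging_env_thresholds <- function(row, environments,
                                             participant_id) {
  envs <- if (row$block_order == "ABAB") c("rich", "poor", "rich", "poor")
          else c("poor", "rich", "poor", "rich")
  blocks <- lapply(seq_along(envs), function(b) {
    thr <- if (envs[b] == "rich") row$exit_threshold_rich
           else row$exit_threshold_poor
    ag <- foraging_agent(thr, row$threshold_noise_sd)
    one <- simulate_foraging_block(ag, environments[[envs[b]]])
    one$orchard_id <- b
    one$environment <- envs[b]
    one
  })
  out <- do.call(rbind, blocks)
  out$participant_id <- participant_id
  out[, c("participant_id", "orchard_id", "environment", "tree_index",
          "action", "yield", "elapsed_s")]
}

#' Simulate only first free choices for a cohort
#'
#' Fast path used by calibration and power studies: generates the
#' first-free-choice record table ([simulate_first_free()]) for every child
#' on a common schedule, skipping later free trials and the foraging task.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param schedule Optional shared schedule; by default a fresh
#'   [horizon_schedule()] is drawn from the current RNG stream.
#' @param seed Optional seed.
#' @return Game-level records for all children, in the
#'   [first_free_table()] schema.
#' @export
cohort_first_free <- function(cohort, schedule = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- horizon_schedule(seed = NULL)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    simulate_first_free(schedule, cohort_agent(row),
                        participant_id = row$participant_id)
  })
  do.call(rbind, out)
}
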