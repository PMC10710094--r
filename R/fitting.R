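#' Negative log-likelihood of first free choices
#'
#' Likelihood of observed first free choices under the logistic
#' information-bonus model. The probability is computed by the same code
#' path used for simulation ([horizon_choice_prob()]'s core), so fitted and
#' generative models cannot drift apart.
#'
#' @param params Named numeric vector with `info_bonus`, `spatial_bias`,
#'   `decision_noise`, `repeat_bonus` (a subset of names is allowed;
#'   missing entries default to 0, noise to 8).
#' @param records Data frame with columns `delta_reward`, `delta_info`,
#'   `repeat_ind`, `side_ind`, `chose_left` (as from [first_free_table()]).
#' @return Negative log-likelihood in nats.
#' @export
horizon_nll <- function(params, records) {
  p <- c(info_bonus = 0, spatial_bias = 0, decision_noise = 8,
         repeat_bonus = 0)
  p[names(params)] <- params
  assert_that(p[["decision_noise"]] > 0,
              "decision_noise must be positive for a likelihood")
  pl <- choice_prob_core(records$delta_reward, records$delta_info,
                         records$repeat_ind, records$side_ind,
                         p[["info_bonus"]], p[["spatial_bias"]],
                         p[["decision_noise"]], p[["repeat_bonus"]])
  pr <- ifelse(records$chose_left == 1, pl, 1 - pl)
  -sum(log(pmax(pr, .Machine$double.xmin)))
}

# parameter box used by the fitter and the grid-search oracle
fit_bounds <- function() {
  list(lower = c(info_bonus = -30, spatial_bias = -30, decision_noise = 0.1,
                 repeat_bonus = -30),
       upper = c(info_bonus = 30, spatial_bias = 30, decision_noise = 50,
                 repeat_bonus = 30))
}

#' Fit the choice model by maximum likelihood
#'
#' Multi-start bounded quasi-Newton (L-BFGS-B) minimization of
#' [horizon_nll()] over the box A, B, K in \[-30, 30\] points and
#' sigma in \[0.1, 50\] points. With `per_horizon = TRUE` the information
#' bonus and decision noise are estimated separately for short- and
#' long-horizon games while the spatial bias and repeat bonus are shared.
#' Start points are drawn deterministically from `seed`, so refitting the
#' same records reproduces the same result.
#'
#' @param records First-free-choice records ([first_free_table()]); must
#'   include a `horizon` column when `per_horizon = TRUE`.
#' @param per_horizon Estimate horizon-specific information bonus and noise?
#' @param n_starts Number of optimizer starts (first start is a fixed
#'   neutral point, the rest random within the box).
#' @param seed Seed for the start points.
#' @param min_trials Minimum records required per fitted condition.
#' @return List of class `horizon_fit`: `params` (a [horizon_agent()]),
#'   `negative_log_likelihood`, `n_trials_used`, `converged`, `per_horizon`,
#'   and the raw `estimates` vector.
#' @export
fit_horizon_model <- function(records, per_horizon = FALSE, n_starts = 10,
                              seed = 1L, min_trials = 20) {
  assert_that(nrow(records) >= min_trials,
              sprintf("need at least %d first-free-choice records",
                      min_trials))
  b <- fit_bounds()
  if (!per_horizon) {
    nm <- c("info_bonus", "spatial_bias", "decision_noise", "repeat_bonus")
    lower <- b$lower[nm]; upper <- b$upper[nm]
    fn <- function(th) horizon_nll(stats::setNames(th, nm), records)
    neutral <- c(0, 0, 8, 0)
  } else {
    assert_that("horizon" %in% names(records),
                "per-horizon fit needs a horizon column")
    is_short <- records$horizon == "short"
    assert_that(min(sum(is_short), sum(!is_short)) >= min_trials,
                "too few records in one horizon condition")
    nm <- c("info_short", "info_long", "noise_short", "noise_long",
            "spatial_bias", "repeat_bonus")
    lower <- c(b$lower[["info_bonus"]], b$lower[["info_bonus"]],
               b$lower[["decision_noise"]], b$lower[["decision_noise"]],
               b$lower[["spatial_bias"]], b$lower[["repeat_bonus"]])
    upper <- c(b$upper[["info_bonus"]], b$upper[["info_bonus"]],
               b$upper[["decision_noise"]], b$upper[["decision_noise"]],
               b$upper[["spatial_bias"]], b$upper[["repeat_bonus"]])
    names(lower) <- names(upper) <- nm
    fn <- function(th) {
      horizon_nll(c(info_bonus = th[1], decision_noise = th[3],
                    spatial_bias = th[5], repeat_bonus = th[6]),
                  records[is_short, ]) +
        horizon_nll(c(info_bonus = th[2], decision_noise = th[4],
                      spatial_bias = th[5], repeat_bonus = th[6]),
                    records[!is_short, ])
    }
    neutral <- c(0, 0, 8, 8, 0, 0)
  }
  starts <- with_preserved_seed(seed, {
    rand <- matrix(stats::runif((n_starts - 1) * length(lower), lower, upper),
                   ncol = length(lower), byrow = TRUE)
    rbind(neutral, rand)
  })
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_ok)
    return(structure(list(params = NULL, estimates = NULL,
                          negative_log_likelihood = NA_real_,
                          n_trials_used = nrow(records), converged = FALSE,
                          per_horizon = per_horizon),
                     class = "horizon_fit"))
  est <- stats::setNames(best$par, nm)
  agent <- if (!per_horizon) {
    horizon_agent(info_bonus = est[["info_bonus"]],
                  spatial_bias = est[["spatial_bias"]],
                  decision_noise = est[["decision_noise"]],
                  repeat_bonus = est[["repeat_bonus"]])
  } else {
    horizon_agent(
      info_bonus = est[["info_short"]], spatial_bias = est[["spatial_bias"]],
      decision_noise = est[["noise_short"]],
      repeat_bonus = est[["repeat_bonus"]],
      horizon_specific = list(long = list(info_bonus = est[["info_long"]],
                                          decision_noise = est[["noise_long"]])))
  }
  structure(list(params = agent, estimates = est,
                 negative_log_likelihood = best$value,
                 n_trials_used = nrow(records),
                 converged = best$convergence == 0,
                 per_horizon = per_horizon),
            class = "horizon_fit")
}

#' @export
print.horizon_fit <- function(x, ...) {
  cat("<horizon_fit> NLL =", round(x$negative_log_likelihood, 3),
      "on", x$n_trials_used, "trials; converged:", x$converged, "\n")
  print(round(x$estimates, 3))
  invisible(x)
}

#' Exhaustive grid-search fit (oracle)
#'
#' Minimizes [horizon_nll()] over the Cartesian product of the supplied
#' parameter grids. Intended as an independent check on
#' [fit_horizon_model()] on small problems, not as a practical fitter.
#'
#' @param records First-free-choice records.
#' @param grids Named list of numeric grids for `info_bonus`,
#'   `spatial_bias`, `decision_noise`, `repeat_bonus`.
#' @return List with `estimates` (best grid point) and
#'   `negative_log_likelihood`.
#' @export
grid_search_fit <- function(records,
                            grids = list(
                              info_bonus = seq(-10, 10, by = 2.5),
                              spatial_bias = seq(-5, 5, by = 2.5),
                              decision_noise = c(2, 4, 6, 8, 12, 20),
                              repeat_bonus = seq(-10, 10, by = 2.5))) {
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  nll <- vapply(seq_len(nrow(g)), function(i) {
    pl <- choice_prob_core(records$delta_reward, records$delta_info,
                           records$repeat_ind, records$side_ind,
                           g$info_bonus[i], g$spatial_bias[i],
                           g$decision_noise[i], g$repeat_bonus[i])
    pr <- ifelse(records$chose_left == 1, pl, 1 - pl)
    -sum(log(pmax(pr, .Machine$double.xmin)))
  }, numeric(1))
  best <- which.min(nll)
  list(estimates = unlist(g[best, ]), negative_log_likelihood = nll[best])
}

#' Parameter-recovery study
#'
#' Simulates agents with known parameters on a fixed game schedule, refits
#' each one, and reports per-parameter recovery quality (correlation, bias,
#' RMSE between true and recovered values).
#'
#' @param true_params Data frame with one row per simulated agent and
#'   columns among `info_bonus`, `spatial_bias`, `decision_noise`,
#'   `repeat_bonus` (missing columns default to the [horizon_agent()]
#'   defaults).
#' @param n_games Games simulated per agent (two 80-game schedules give
#'   160).
#' @param seed Master seed for schedules, payouts, choices, and fits.
#' @param n_starts Optimizer starts per fit.
#' @return List with `fits` (true and recovered values per agent) and
#'   `summary` (one row per recovered parameter: correlation, bias, RMSE).
#' @export
parameter_recovery <- function(true_params, n_games = 160, seed = 1L,
                               n_starts = 10) {
  assert_that(nrow(true_params) >= 1, "true_params must be non-empty")
  set.seed(seed)
  n_sched <- ceiling(n_games / 80)
  schedule <- do.call(rbind, lapply(seq_len(n_sched), function(i)
    horizon_schedule(seed = seed + i)))
  schedule <- schedule[seq_len(n_games), ]
  schedule$game_id <- seq_len(n_games)
  defaults <- list(info_bonus = 0, spatial_bias = 0, decision_noise = 8,
                   repeat_bonus = 0)
  fits <- lapply(seq_len(nrow(true_params)), function(i) {
    pars <- defaults
    known <- intersect(names(true_params), names(defaults))
    pars[known] <- as.list(true_params[i, known, drop = FALSE])
    agent <- do.call(horizon_agent, pars)
    ff <- simulate_first_free(schedule, agent)
    fit <- fit_horizon_model(ff, per_horizon = FALSE, n_starts = n_starts,
                             seed = seed + i)
    est <- fit$estimates
    data.frame(agent = i,
               true_info_bonus = pars$info_bonus,
               true_repeat_bonus = pars$repeat_bonus,
               true_decision_noise = pars$decision_noise,
               true_spatial_bias = pars$spatial_bias,
               fit_info_bonus = est[["info_bonus"]],
               fit_repeat_bonus = est[["repeat_bonus"]],
               fit_decision_noise = est[["decision_noise"]],
               fit_spatial_bias = est[["spatial_bias"]],
               converged = fit$converged)
  })
  fits <- do.call(rbind, fits)
  summ <- do.call(rbind, lapply(
    c("info_bonus", "repeat_bonus", "decision_noise", "spatial_bias"),
    function(p) {
      tr <- fits[[paste0("true_", p)]]
      ft <- fits[[paste0("fit_", p)]]
      data.frame(parameter = p,
                 correlation = if (stats::sd(tr) > 0)
                   stats::cor(tr, ft) else NA_real_,
                 bias = mean(ft - tr),
                 rmse = sqrt(mean((ft - tr)^2)),
                 stringsAsFactors = FALSE)
    }))
  list(fits = fits, summary = summ)
}

#' Simulate first-free-choice records directly
#'
#' Fast vectorized generator of the game-level records that the exploration
#' analyses and the model likelihood consume: forced-phase payouts are drawn
#' for each game (three for the thrice-shown bandit, one for the once-shown
#' bandit), the first free choice is sampled from the agent's policy, and
#' the derived indicators are returned in the same schema as
#' [first_free_table()]. Equivalent in distribution to playing full games
#' with [play_game()] and reducing the log, but orders of magnitude faster;
#' later free choices (needed only for reward-maximization metrics) are not
#' generated.
#'
#' @param schedule Game schedule ([horizon_schedule()]).
#' @param agent A [horizon_agent()].
#' @param participant_id Identifier attached to the records.
#' @param payout_sd Payout SD in points.
#' @return Data frame in the [first_free_table()] schema.
#' @export
simulate_first_free <- function(schedule, agent, participant_id = "sim",
                                payout_sd = 8) {
  n <- nrow(schedule)
  mu_info <- ifelse(schedule$info_bandit == "left", schedule$mu_left,
                    schedule$mu_right)
  mu_other <- ifelse(schedule$info_bandit == "left", schedule$mu_right,
                     schedule$mu_left)
  m_info <- sample_payout(mu_info, payout_sd, n = n)
  m_other <- (sample_payout(mu_other, payout_sd, n = n) +
                sample_payout(mu_other, payout_sd, n = n) +
                sample_payout(mu_other, payout_sd, n = n)) / 3
  info_left <- schedule$info_bandit == "left"
  m_left <- ifelse(info_left, m_info, m_other)
  m_right <- ifelse(info_left, m_other, m_info)
  t4 <- substr(schedule$forced_seq, 4, 4)
  delta_info <- ifelse(info_left, 1, -1)
  repeat_ind <- ifelse(t4 == "L", 1, -1)
  p_left <- numeric(n)
  for (h in unique(schedule$horizon)) {
    sel <- schedule$horizon == h
    pp <- agent_params_for(agent, h)
    p_left[sel] <- choice_prob_core(
      (m_left - m_right)[sel], delta_info[sel], repeat_ind[sel], 1,
      pp$info_bonus, pp$spatial_bias, pp$decision_noise, pp$repeat_bonus)
  }
  chose_left <- as.integer(stats::runif(n) < p_left)
  t5 <- ifelse(chose_left == 1, "left", "right")
  t4_side <- ifelse(t4 == "L", "left", "right")
  data.frame(
    participant_id = participant_id, game_id = schedule$game_id,
    horizon = schedule$horizon, info_bandit = schedule$info_bandit,
    mean_info = m_info, mean_other = m_other,
    explored = as.integer(t5 == schedule$info_bandit),
    habitual = as.integer(t5 == t4_side),
    prev_was_info = as.integer(t4_side == schedule$info_bandit),
    conflict = as.integer(m_info < m_other),
    delta_reward = m_left - m_right,
    delta_info = delta_info, repeat_ind = repeat_ind, side_ind = 1,
    chose_left = chose_left, stringsAsFactors = FALSE)
}
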