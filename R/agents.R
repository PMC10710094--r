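#' Parameterized bandit agent for the horizon task
#'
#' Bundles the parameters of the logistic choice model used both to simulate
#' and to fit behavior in the two-armed bandit task: an information bonus
#' `A` (points added to the less-sampled option), a spatial bias `B`
#' (points added to the left option), decision noise `sigma` (the logistic
#' temperature, in points), and a repetition ("habit") bonus `K` (points
#' added to the option chosen on the previous trial). Any parameter can be
#' overridden per horizon condition via `horizon_specific`, e.g. to let the
#' information bonus grow when more free choices remain.
#'
#' @param info_bonus Information bonus A, in points.
#' @param spatial_bias Left-side bias B, in points.
#' @param decision_noise Logistic temperature sigma, in points; must be
#'   non-negative. Zero gives the greedy (deterministic) limit with ties
#'   broken by a fair coin.
#' @param repeat_bonus Choice-repetition bonus K, in points.
#' @param horizon_specific Optional named list, e.g.
#'   `list(long = list(info_bonus = 8))`, overriding parameters in one
#'   horizon condition ("short" or "long").
#' @return An object of class `horizon_agent`.
#' @examples
#' ag <- horizon_agent(info_bonus = 5, decision_noise = 8)
#' horizon_choice_prob(ag, delta_reward = -5, delta_info = 1)
#' @export
horizon_agent <- function(info_bonus = 0, spatial_bias = 0,
                          decision_noise = 8, repeat_bonus = 0,
                          horizon_specific = NULL) {
  pars <- c(info_bonus = info_bonus, spatial_bias = spatial_bias,
            decision_noise = decision_noise, repeat_bonus = repeat_bonus)
  assert_that(all(is.finite(pars)), "agent parameters must be finite")
  assert_that(decision_noise >= 0, "decision_noise must be >= 0")
  if (!is.null(horizon_specific)) {
    assert_that(all(names(horizon_specific) %in% c("short", "long")),
                "horizon_specific names must be 'short' and/or 'long'")
    ok <- vapply(horizon_specific, function(x)
      all(names(x) %in% names(pars)), logical(1))
    assert_that(all(ok), "unknown parameter in horizon_specific override")
  }
  structure(list(info_bonus = info_bonus, spatial_bias = spatial_bias,
                 decision_noise = decision_noise, repeat_bonus = repeat_bonus,
                 horizon_specific = horizon_specific),
            class = "horizon_agent")
}

#' @export
print.horizon_agent <- function(x, ...) {
  cat("<horizon_agent> A =", x$info_bonus, " B =", x$spatial_bias,
      " sigma =", x$decision_noise, " K =", x$repeat_bonus, "\n")
  if (!is.null(x$horizon_specific))
    cat("  horizon-specific overrides:",
        paste(names(x$horizon_specific), collapse = ", "), "\n")
  invisible(x)
}

# resolve effective (A, B, sigma, K) for a horizon condition
agent_params_for <- function(agent, horizon = NULL) {
  p <- agent[c("info_bonus", "spatial_bias", "decision_noise", "repeat_bonus")]
  if (!is.null(horizon) && !is.null(agent$horizon_specific[[horizon]])) {
    ov <- agent$horizon_specific[[horizon]]
    p[names(ov)] <- ov
  }
  p
}

# Core choice rule shared by simulation and likelihood code. All arguments
# vectorized; returns P(choose option 1).
choice_prob_core <- function(delta_reward, delta_info, repeat_ind, side_ind,
                             info_bonus, spatial_bias, decision_noise,
                             repeat_bonus) {
  dv <- delta_reward + info_bonus * delta_info + spatial_bias * side_ind +
    repeat_bonus * repeat_ind
  if (all(decision_noise > 0)) return(stats::plogis(dv / decision_noise))
  # greedy limit: step function with fair-coin ties
  p <- ifelse(decision_noise > 0, stats::plogis(dv / decision_noise),
              ifelse(dv > 0, 1, ifelse(dv < 0, 0, 0.5)))
  p
}

#' Choice probability under the logistic information-bonus model
#'
#' Probability that option 1 is chosen given the observed payout-mean
#' difference and signed indicators for information, repetition, and side:
#' `P = logistic((dR + A*dI + B*side + K*rep) / sigma)`.
#'
#' Indicators are coded +1 when the property favors option 1, -1 when it
#' favors option 2, and 0 when neither (e.g. equal observation counts). With
#' this coding the model is antisymmetric: swapping the two options maps
#' `P` to `1 - P`.
#'
#' @param agent A [horizon_agent()].
#' @param delta_reward Observed payout-mean difference, option 1 minus
#'   option 2, in points.
#' @param delta_info +1 if option 1 is the less-sampled (high-information)
#'   option, -1 if option 2 is, 0 if tied.
#' @param repeat_ind +1 if option 1 was chosen on the previous trial, -1 if
#'   option 2 was.
#' @param side_ind +1 if option 1 is the left option, -1 otherwise.
#' @param horizon Optional horizon condition ("short"/"long") used to apply
#'   `horizon_specific` parameter overrides.
#' @return Probability in `[0, 1]` (strictly inside for positive noise).
#' @export
horizon_choice_prob <- function(agent, delta_reward, delta_info = 0,
                                repeat_ind = 0, side_ind = 1,
                                horizon = NULL) {
  stopifnot(inherits(agent, "horizon_agent"))
  p <- agent_params_for(agent, horizon)
  choice_prob_core(delta_reward, delta_info, repeat_ind, side_ind,
                   p$info_bonus, p$spatial_bias, p$decision_noise,
                   p$repeat_bonus)
}

#' Sample a free choice from the agent's policy
#'
#' Computes observed payout means from the history visible to the agent (its
#' own choices' payouts only), derives the information and repetition
#' indicators, and draws a Bernoulli choice from [horizon_choice_prob()].
#' The option observed fewer times is the high-information option; with
#' equal counts the information indicator is 0.
#'
#' @param agent A [horizon_agent()].
#' @param history Data frame with columns `choice` ("left"/"right") and
#'   `payout` for all previous trials of the game, in order.
#' @param horizon Optional horizon label for parameter overrides.
#' @return "left" or "right".
#' @export
act_horizon <- function(agent, history, horizon = NULL) {
  assert_that(nrow(history) >= 1, "history must contain at least one trial")
  left <- history$payout[history$choice == "left"]
  right <- history$payout[history$choice == "right"]
  d_reward <- mean_or_zero(left) - mean_or_zero(right)
  d_info <- sign(length(right) - length(left))  # fewer obs -> +1 for left
  rep_ind <- if (history$choice[nrow(history)] == "left") 1 else -1
  p_left <- horizon_choice_prob(agent, d_reward, d_info, rep_ind,
                                side_ind = 1, horizon = horizon)
  if (stats::runif(1) < p_left) "left" else "right"
}

mean_or_zero <- function(x) if (length(x)) mean(x) else 0

#' Threshold-based foraging agent
#'
#' Leaves the current tree when the expected next harvest falls below
#' `exit_threshold` plus (optionally) trial-level Gaussian noise on the
#' threshold; always harvests at least once at a new tree.
#'
#' @param exit_threshold Leaving threshold, in apples; must be positive.
#' @param threshold_noise_sd SD of per-decision Gaussian noise added to the
#'   threshold, in apples.
#' @return An object of class `foraging_agent`.
#' @export
foraging_agent <- function(exit_threshold, threshold_noise_sd = 0) {
  assert_that(is.finite(exit_threshold) && exit_threshold > 0,
              "exit_threshold must be positive")
  assert_that(threshold_noise_sd >= 0, "threshold_noise_sd must be >= 0")
  structure(list(exit_threshold = exit_threshold,
                 threshold_noise_sd = threshold_noise_sd),
            class = "foraging_agent")
}

#' Harvest-or-leave decision
#'
#' @param agent A [foraging_agent()].
#' @param expected_next_yield Expected yield of the next harvest at the
#'   current tree, in apples.
#' @return "harvest" or "leave".
#' @export
act_foraging <- function(agent, expected_next_yield) {
  stopifnot(inherits(agent, "foraging_agent"))
  thr <- agent$exit_threshold +
    if (agent$threshold_noise_sd > 0)
      stats::rnorm(1, 0, agent$threshold_noise_sd) else 0
  if (expected_next_yield < thr) "leave" else "harvest"
}
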