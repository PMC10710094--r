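#' Per-game first-free-choice summary
#'
#' Reduces a trial log to one row per game with everything the trial-level
#' analyses need: the observed forced-phase payout means of the
#' high-information (once-shown) and low-information (thrice-shown) bandits,
#' whether the first free choice was exploratory (the high-information
#' bandit), whether it repeated the trial-4 choice (habitual responding),
#' whether the repeated option was the uncertain one, and whether the game
#' poses a reward-information conflict (the informative option's observed
#' mean is strictly lower; ties count as no conflict).
#'
#' @param trials Trial-record data frame as produced by [play_game()] /
#'   [play_schedule()] (any number of participants).
#' @return Data frame with one row per participant x game: `participant_id`,
#'   `game_id`, `horizon`, `info_bandit`, `mean_info`, `mean_other`,
#'   `explored` (0/1), `habitual` (0/1), `prev_was_info` (0/1; trial-4
#'   choice was the once-shown option), `conflict` (0/1), and the model
#'   regressors `delta_reward` (left minus right observed mean),
#'   `delta_info`, `repeat_ind`, `side_ind`, `chose_left`.
#' @export
first_free_table <- function(trials) {
  need <- c("participant_id", "game_id", "horizon", "trial_index", "phase",
            "choice", "payout", "info_bandit")
  assert_that(all(need %in% names(trials)),
              "trial log is missing required columns")
  key <- interaction(trials$participant_id, trials$game_id, drop = TRUE)
  parts <- split(trials, key)
  rows <- lapply(parts, function(g) {
    g <- g[order(g$trial_index), ]
    assert_that(nrow(g) >= 5, "each game needs at least 5 trials")
    forced <- g[g$trial_index <= 4, ]
    t4 <- g$choice[g$trial_index == 4]
    t5 <- g$choice[g$trial_index == 5]
    info <- g$info_bandit[1]
    m_left <- mean(forced$payout[forced$choice == "left"])
    m_right <- mean(forced$payout[forced$choice == "right"])
    m_info <- if (info == "left") m_left else m_right
    m_other <- if (info == "left") m_right else m_left
    data.frame(
      participant_id = g$participant_id[1], game_id = g$game_id[1],
      horizon = g$horizon[1], info_bandit = info,
      mean_info = m_info, mean_other = m_other,
      explored = as.integer(t5 == info),
      habitual = as.integer(t5 == t4),
      prev_was_info = as.integer(t4 == info),
      conflict = as.integer(m_info < m_other),
      delta_reward = m_left - m_right,
      delta_info = ifelse(info == "left", 1, -1),
      repeat_ind = ifelse(t4 == "left", 1, -1),
      side_ind = 1,
      chose_left = as.integer(t5 == "left"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$game_id), ]
}

#' Exploration rates at the first free choice
#'
#' Exploration is choosing the high-information (once-shown) bandit at the
#' first free choice (trial 5). Returns per-participant proportions split by
#' horizon, plus the overall rate and strategic exploration (long minus
#' short).
#'
#' @param trials Trial log, or a precomputed [first_free_table()].
#' @return Data frame: `participant_id`, `p_explore_short`,
#'   `p_explore_long`, `p_explore_overall`, `strategic_exploration`.
#' @export
compute_exploration <- function(trials) {
  ff <- as_first_free(trials)
  agg <- function(sub) mean(sub$explored)
  ids <- unique(ff$participant_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    f <- ff[ff$participant_id == id, ]
    ps <- agg(f[f$horizon == "short", ])
    pl <- agg(f[f$horizon == "long", ])
    data.frame(participant_id = id, p_explore_short = ps,
               p_explore_long = pl, p_explore_overall = agg(f),
               strategic_exploration = compute_strategic(ps, pl),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

as_first_free <- function(trials) {
  if (all(c("explored", "habitual", "conflict") %in% names(trials))) trials
  else first_free_table(trials)
}

#' Strategic exploration index
#'
#' Horizon adaptation of exploration: the long-horizon exploration rate
#' minus the short-horizon rate.
#'
#' @param p_explore_short,p_explore_long Proportions in `[0, 1]`.
#' @return Difference in `[-1, 1]`.
#' @export
compute_strategic <- function(p_explore_short, p_explore_long) {
  assert_that(all(p_explore_short >= 0 & p_explore_short <= 1 &
                    p_explore_long >= 0 & p_explore_long <= 1,
                  na.rm = TRUE),
              "exploration rates must lie in [0, 1]")
  p_explore_long - p_explore_short
}

#' Classify a game's reward-information conflict
#'
#' A game presents a conflict when the more informative (once-shown) option
#' has the strictly lower observed forced-phase payout mean, pitting
#' information against reward. Ties are classified as no conflict.
#'
#' @param info_payouts Forced-phase payouts of the once-shown bandit
#'   (length 1).
#' @param other_payouts Forced-phase payouts of the thrice-shown bandit
#'   (length 3).
#' @return "conflict" or "no_conflict".
#' @export
classify_conflict <- function(info_payouts, other_payouts) {
  if (mean(info_payouts) < mean(other_payouts)) "conflict" else "no_conflict"
}

#' Habitual-responding indicator for one game
#'
#' Whether the first free choice (trial 5) repeated the trial-4 choice, and
#' whether that previous option was the uncertain (once-shown) or familiar
#' (thrice-shown) bandit.
#'
#' @param game Trial records of a single game (>= 5 trials).
#' @return List with `habitual` (0/1) and `previous_option` ("more_info" if
#'   trial 4 chose the once-shown bandit, "less_info" otherwise).
#' @export
is_habitual_response <- function(game) {
  game <- game[order(game$trial_index), ]
  assert_that(nrow(game) >= 5, "game must contain trials 4 and 5")
  t4 <- game$choice[game$trial_index == 4]
  t5 <- game$choice[game$trial_index == 5]
  list(habitual = as.integer(t5 == t4),
       previous_option = if (t4 == game$info_bandit[1]) "more_info"
                         else "less_info")
}

#' Reward maximization rate
#'
#' Proportion of free choices after the first (trial 6 onward) that selected
#' the bandit with the higher observed payout mean at choice time, using
#' only payouts the participant had seen. Trials where the observed means
#' tie are excluded.
#'
#' @param trials Trial log for one or more participants.
#' @return Data frame: `participant_id`, `reward_maximization`,
#'   `mean_reward` (average free-choice payout), `n_eligible`.
#' @export
compute_reward_maximization <- function(trials) {
  key <- interaction(trials$participant_id, trials$game_id, drop = TRUE)
  per_game <- lapply(split(trials, key), function(g) {
    g <- g[order(g$trial_index), ]
    free <- g$trial_index[g$phase == "free"]
    if (!length(free)) return(NULL)
    hits <- integer(0)
    for (t in free[free > 5]) {
      before <- g[g$trial_index < t, ]
      ml <- mean(before$payout[before$choice == "left"])
      mr <- mean(before$payout[before$choice == "right"])
      if (isTRUE(all.equal(ml, mr))) next
      best <- if (ml > mr) "left" else "right"
      hits <- c(hits, as.integer(g$choice[g$trial_index == t] == best))
    }
    data.frame(participant_id = g$participant_id[1],
               n_hit = sum(hits), n_eligible = length(hits),
               reward_sum = sum(g$payout[g$phase == "free"]),
               n_free = length(free), stringsAsFactors = FALSE)
  })
  per_game <- do.call(rbind, per_game)
  out <- do.call(rbind, lapply(split(per_game, per_game$participant_id),
    function(p) data.frame(
      participant_id = p$participant_id[1],
      reward_maximization = sum(p$n_hit) / max(sum(p$n_eligible), 1),
      mean_reward = sum(p$reward_sum) / sum(p$n_free),
      n_eligible = sum(p$n_eligible), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Participant-level horizon-task metrics
#'
#' Convenience wrapper combining exploration rates, habitual-responding
#' rate, reward maximization, and mean reward into one table, one row per
#' participant.
#'
#' @param trials Trial log from [play_schedule()] or
#'   [simulate_study()].
#' @return Data frame of participant metrics.
#' @export
horizon_metrics <- function(trials) {
  ff <- first_free_table(trials)
  ex <- compute_exploration(ff)
  hab <- stats::aggregate(habitual ~ participant_id, ff, mean)
  names(hab)[2] <- "habitual_rate"
  rm_ <- compute_reward_maximization(trials)
  out <- merge(ex, hab, by = "participant_id")
  merge(out, rm_[, c("participant_id", "reward_maximization", "mean_reward")],
        by = "participant_id")
}

#' Exit thresholds and deviation from optimal
#'
#' For every completed tree visit (one followed by a leave event) the exit
#' threshold is the mean of the last two harvests at that tree; if the tree
#' was harvested only once, that single yield is used. The first exit of
#' every orchard block is excluded (the environment's travel time is unknown
#' until the first move). Thresholds are averaged per environment and,
#' when optimal values are supplied, reported as deviations
#' (observed minus optimal; positive = left earlier than optimal, i.e.
#' over-exploration).
#'
#' @param foraging Event log from [simulate_foraging_session()].
#' @param optimal Optional named vector `c(rich = ..., poor = ...)` of
#'   optimal thresholds from [mvt_optimal_threshold()].
#' @param per_tree Return the tree-level table instead of participant
#'   averages (used by the trial-level environment analysis).
#' @return Participant-level data frame (`exit_threshold_rich`,
#'   `exit_threshold_poor`, `deviation_rich`, `deviation_poor`) or, with
#'   `per_tree = TRUE`, one row per retained tree exit with columns
#'   `participant_id`, `orchard_id`, `environment`, `tree_index`,
#'   `exit_threshold`.
#' @export
compute_exit_thresholds <- function(foraging, optimal = NULL,
                                    per_tree = FALSE) {
  harv <- foraging[foraging$action == "harvest", ]
  key <- interaction(foraging$participant_id, foraging$orchard_id,
                     drop = TRUE)
  per_block <- lapply(split(foraging, key), function(b) {
    b <- b[order(b$elapsed_s, b$tree_index), ]
    left_trees <- unique(b$tree_index[b$action == "leave"])
    if (!length(left_trees)) return(NULL)
    th <- vapply(left_trees, function(tr) {
      y <- b$yield[b$action == "harvest" & b$tree_index == tr]
      if (length(y) >= 2) mean(utils::tail(y, 2)) else y[length(y)]
    }, numeric(1))
    out <- data.frame(participant_id = b$participant_id[1],
                      orchard_id = b$orchard_id[1],
                      environment = b$environment[1],
                      tree_index = left_trees, exit_threshold = th,
                      stringsAsFactors = FALSE)
    out[-1, , drop = FALSE]  # drop the first exit of the block
  })
  tree_tab <- do.call(rbind, per_block)
  rownames(tree_tab) <- NULL
  if (per_tree) return(tree_tab)
  ids <- unique(foraging$participant_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tt <- tree_tab[tree_tab$participant_id == id, ]
    thr <- function(env) {
      v <- tt$exit_threshold[tt$environment == env]
      if (length(v)) mean(v) else NA_real_
    }
    data.frame(participant_id = id,
               exit_threshold_rich = thr("rich"),
               exit_threshold_poor = thr("poor"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(optimal)) {
    out$deviation_rich <- out$exit_threshold_rich - optimal[["rich"]]
    out$deviation_poor <- out$exit_threshold_poor - optimal[["poor"]]
  }
  rownames(out) <- NULL
  out
}

#' Exclude statistically extreme participants
#'
#' Removes participants whose value on `metric` lies more than `sd_limit`
#' standard deviations from the sample mean (both computed once, on the full
#' sample -- a single pass, not iterated). With zero variance nothing is
#' excluded. Exclusion on one task's metric is independent of any other
#' metric.
#'
#' @param metrics Participant-level data frame.
#' @param metric Column name to screen on.
#' @param sd_limit Cutoff in SD units (default 2).
#' @return List with `kept` and `excluded` data frames and the numeric
#'   `bounds` used.
#' @export
exclude_outliers <- function(metrics, metric, sd_limit = 2) {
  assert_that(metric %in% names(metrics), "unknown metric column")
  assert_that(nrow(metrics) >= 3, "need at least 3 participants")
  x <- metrics[[metric]]
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    keep <- rep(TRUE, nrow(metrics))
  } else {
    keep <- !is.na(x) & abs(x - m) <= sd_limit * s
  }
  list(kept = metrics[keep, , drop = FALSE],
       excluded = metrics[!keep, , drop = FALSE],
       bounds = c(lower = m - sd_limit * s, upper = m + sd_limit * s))
}
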