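#' Generate the counterbalanced 80-game bandit schedule
#'
#' Builds the full factorial design of the horizon task: 5 payout-mean gaps
#' (4, 8, 12, 20, 30 points) x 2 high-mean sides (left/right) x 2 horizons
#' (short = 5 trials, long = 10 trials) x 2 placements of the
#' high-information option (on the higher- or lower-mean bandit), with each
#' cell appearing twice for 80 games. The anchor bandit (left) has mean 40
#' in one replicate and 60 in the other; the right bandit differs by the
#' gap, above or below depending on the high-mean side. Within the four
#' forced trials one bandit is shown three times and the other once; the
#' once-shown bandit is the high-information option. Game order and the
#' internal order of the forced sequence are randomized by `seed`.
#'
#' @param seed Integer seed controlling game order and forced-sequence
#'   orders. `NULL` uses the current RNG state.
#' @return Data frame with one row per game: `game_id`, `horizon`
#'   ("short"/"long"), `total_trials` (5/10), `mu_left`, `mu_right`,
#'   `info_bandit` ("left"/"right"), and `forced_seq` (4-character string of
#'   "L"/"R", e.g. "LRLL").
#' @examples
#' sched <- horizon_schedule(seed = 1)
#' table(sched$horizon)
#' @export
horizon_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- c(4, 8, 12, 20, 30)
  cells <- expand.grid(gap = gaps,
                       high_side = c("left", "right"),
                       horizon = c("short", "long"),
                       info_on_high = c(TRUE, FALSE),
                       replicate = 1:2,
                       stringsAsFactors = FALSE)
  anchor <- ifelse(cells$replicate == 1, 40, 60)  # left-bandit mean
  mu_left <- anchor
  mu_right <- ifelse(cells$high_side == "left", anchor - cells$gap,
                     anchor + cells$gap)
  low_side <- ifelse(cells$high_side == "left", "right", "left")
  info_bandit <- ifelse(cells$info_on_high, cells$high_side, low_side)
  forced_seq <- vapply(info_bandit, function(info) {
    other <- if (info == "left") "R" else "L"
    me <- if (info == "left") "L" else "R"
    paste(sample(c(me, other, other, other)), collapse = "")
  }, character(1))
  out <- data.frame(
    horizon = cells$horizon,
    total_trials = ifelse(cells$horizon == "short", 5L, 10L),
    mu_left = mu_left, mu_right = mu_right,
    info_bandit = info_bandit, forced_seq = forced_seq,
    stringsAsFactors = FALSE)
  out <- out[sample(nrow(out)), , drop = FALSE]
  out$game_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("game_id", "horizon", "total_trials", "mu_left", "mu_right",
          "info_bandit", "forced_seq")]
}

#' Sample a bandit payout
#'
#' Gaussian payout with SD 8 points by default, rounded to the nearest
#' integer (halves away from zero). No floor is applied; negative draws are
#' possible but vanishingly rare at the means used in the task.
#'
#' @param mu Bandit mean, in points.
#' @param sd Payout SD, in points (default 8).
#' @param n Number of draws.
#' @param round Round to integers? Set `FALSE` to obtain the raw Gaussian
#'   draws (e.g. for calibration checks of the generator itself).
#' @return Numeric vector of payouts.
#' @export
sample_payout <- function(mu, sd = 8, n = 1, round = TRUE) {
  assert_that(all(sd >= 0), "payout sd must be non-negative")
  x <- stats::rnorm(n, mu, sd)
  if (round) round_half_away(x) else x
}

#' Play one bandit game against an agent
#'
#' The four forced trials follow the game's forced sequence; the agent then
#' makes the remaining free choices. Only payouts of chosen bandits enter
#' the history the agent sees (the unchosen bandit's payout is never drawn,
#' so it cannot leak). A custom policy can be supplied via `choose_fun`,
#' which receives the visible history and must return "left" or "right" --
#' useful for instrumented or scripted agents.
#'
#' @param spec One-row data frame (a row of [horizon_schedule()]).
#' @param agent A [horizon_agent()]; ignored when `choose_fun` is given.
#' @param participant_id Identifier recorded on each trial.
#' @param payout_sd Payout SD in points.
#' @param choose_fun Optional function `(history, spec)` returning
#'   "left"/"right" for each free trial.
#' @return Data frame of trial records: `participant_id`, `game_id`,
#'   `horizon`, `trial_index`, `phase` ("forced"/"free"), `choice`,
#'   `payout`, `mu_left`, `mu_right`, `info_bandit`.
#' @export
play_game <- function(spec, agent = horizon_agent(), participant_id = "sim",
                      payout_sd = 8, choose_fun = NULL) {
  stopifnot(nrow(spec) == 1)
  n <- spec$total_trials
  forced <- strsplit(spec$forced_seq, "")[[1]]
  assert_that(length(forced) == 4, "forced_seq must have four entries")
  choice <- character(n)
  payout <- numeric(n)
  mu <- c(left = spec$mu_left, right = spec$mu_right)
  for (t in seq_len(n)) {
    if (t <= 4) {
      choice[t] <- if (forced[t] == "L") "left" else "right"
    } else {
      hist <- data.frame(choice = choice[seq_len(t - 1)],
                         payout = payout[seq_len(t - 1)],
                         stringsAsFactors = FALSE)
      ch <- if (is.null(choose_fun)) {
        act_horizon(agent, hist, horizon = spec$horizon)
      } else {
        choose_fun(hist, spec)
      }
      assert_that(is.character(ch) && length(ch) == 1 &&
                    ch %in% c("left", "right"),
                  "agent returned an invalid choice")
      choice[t] <- ch
    }
    payout[t] <- sample_payout(mu[[choice[t]]], payout_sd)
  }
  data.frame(participant_id = participant_id, game_id = spec$game_id,
             horizon = spec$horizon,
             trial_index = seq_len(n),
             phase = c(rep("forced", 4), rep("free", n - 4)),
             choice = choice, payout = payout,
             mu_left = spec$mu_left, mu_right = spec$mu_right,
             info_bandit = spec$info_bandit,
             stringsAsFactors = FALSE)
}

#' Export or import a game schedule as JSON
#'
#' Round-trippable structured representation of a schedule, so the exact
#' game list of a run can be archived next to its trial logs.
#'
#' @param schedule Data frame from [horizon_schedule()].
#' @param path File path.
#' @return `write_schedule` invisibly returns `path`; `read_schedule`
#'   returns the schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(schedule, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  need <- c("game_id", "horizon", "total_trials", "mu_left", "mu_right",
            "info_bandit", "forced_seq")
  assert_that(all(need %in% names(out)), "not a schedule file")
  out[, need]
}

#' Play a full schedule of games
#'
#' @param schedule Data frame from [horizon_schedule()].
#' @param agent A [horizon_agent()].
#' @param participant_id Identifier recorded on each trial.
#' @param payout_sd Payout SD in points.
#' @return Row-bound trial records for all games.
#' @export
play_schedule <- function(schedule, agent = horizon_agent(),
                          participant_id = "sim", payout_sd = 8) {
  out <- lapply(seq_len(nrow(schedule)), function(i)
    play_game(schedule[i, , drop = FALSE], agent, participant_id, payout_sd))
  do.call(rbind, out)
}
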