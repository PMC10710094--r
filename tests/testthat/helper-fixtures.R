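# Shared fixtures built in code.

# deterministic two-game trial log with known payouts, for metric arithmetic
toy_trials <- function() {
  g1 <- data.frame(
    participant_id = "p1", game_id = 1L, horizon = "short",
    trial_index = 1:5,
    phase = c(rep("forced", 4), "free"),
    choice = c("left", "left", "right", "left", "right"),
    payout = c(50, 52, 40, 48, 41),
    mu_left = 50, mu_right = 42, info_bandit = "right",
    stringsAsFactors = FALSE)
  g2 <- data.frame(
    participant_id = "p1", game_id = 2L, horizon = "long",
    trial_index = 1:10,
    phase = c(rep("forced", 4), rep("free", 6)),
    choice = c("right", "right", "left", "right",
               "left", "left", "left", "left", "right", "left"),
    payout = c(60, 58, 40, 62, 39, 41, 40, 38, 61, 42),
    mu_left = 40, mu_right = 60, info_bandit = "left",
    stringsAsFactors = FALSE)
  rbind(g1, g2)
}

# small deterministic foraging log: two blocks, known harvests
toy_foraging <- function() {
  mk <- function(orchard, env, trees) {
    out <- list()
    t_el <- 0
    for (i in seq_along(trees)) {
      y <- trees[[i]]
      t_el <- t_el + 3 * length(y)
      out[[length(out) + 1]] <- data.frame(
        participant_id = "p1", orchard_id = orchard, environment = env,
        tree_index = i, action = "harvest", yield = y,
        elapsed_s = seq(t_el - 3 * (length(y) - 1), t_el, by = 3),
        stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- data.frame(
        participant_id = "p1", orchard_id = orchard, environment = env,
        tree_index = i, action = "leave", yield = NA_real_,
        elapsed_s = t_el, stringsAsFactors = FALSE)
      t_el <- t_el + 6
    }
    do.call(rbind, out)
  }
  rbind(
    mk(1, "rich", list(c(10, 8.8, 7.7, 6.8), c(12, 10), c(9, 8))),
    mk(2, "poor", list(c(10, 9), c(10), c(8, 7, 6))))
}

quick_cohort_games <- function(n, config = effect_config(), seed = 1) {
  co <- generate_cohort(n, config, seed = seed)
  ff <- cohort_first_free(co, seed = seed + 1)
  merge(ff, co[, c("participant_id", "quic_total", "income", "digit_span",
                   "anxiety", "latent_U")],
        by = "participant_id")
}

# trees visited and harvests made in one block under a fixed threshold
simulate_foraging_block_stats <- function(threshold, travel_time) {
  blk <- simulate_foraging_block(foraging_agent(threshold),
                                 orchard_config(travel_time = travel_time))
  c(trees = length(unique(blk$tree_index)),
    harvests = sum(blk$action == "harvest"))
}
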