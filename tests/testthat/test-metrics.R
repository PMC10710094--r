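test_that("first-free-choice reduction computes the defined quantities", {
  ff <- first_free_table(toy_trials())
  expect_equal(nrow(ff), 2)
  g1 <- ff[ff$game_id == 1, ]
  # info bandit right observed once (40); left thrice (50, 52, 48)
  expect_equal(g1$mean_info, 40)
  expect_equal(g1$mean_other, 50)
  expect_equal(g1$explored, 1L)       # chose right = info
  expect_equal(g1$habitual, 0L)       # trial 4 left, trial 5 right
  expect_equal(g1$conflict, 1L)       # info mean 40 < 50
  expect_equal(g1$delta_reward, 10)
  g2 <- ff[ff$game_id == 2, ]
  expect_equal(g2$mean_info, 40)      # left shown once
  expect_equal(g2$mean_other, 60)
  expect_equal(g2$explored, 1L)       # chose left = info
  expect_equal(g2$habitual, 0L)       # trial 4 right, trial 5 left
})

test_that("exploration proportions and the strategic index are arithmetic", {
  ff <- first_free_table(toy_trials())
  ex <- compute_exploration(ff)
  expect_equal(ex$p_explore_short, 1)
  expect_equal(ex$p_explore_long, 1)
  expect_equal(ex$p_explore_overall, 1)
  expect_equal(compute_strategic(0.4, 0.6), 0.2)
  expect_equal(compute_strategic(0.5, 0.5), 0)
  expect_error(compute_strategic(-0.1, 0.5), "\\[0, 1\\]")
  # exploration + exploitation sum to one by construction
  expect_equal(mean(ff$explored) + mean(1 - ff$explored), 1)
})

test_that("conflict classification uses observed means with a tie rule", {
  expect_equal(classify_conflict(50, c(42, 44, 40)), "no_conflict")
  expect_equal(classify_conflict(40, c(50, 52, 48)), "conflict")
  expect_equal(classify_conflict(44, c(44, 44, 44)), "no_conflict")
})

test_that("habitual responses are repeats of the trial-4 choice", {
  tt <- toy_trials()
  g1 <- tt[tt$game_id == 1, ]
  h <- is_habitual_response(g1)
  expect_equal(h$habitual, 0L)
  expect_equal(h$previous_option, "less_info")  # trial 4 = left, thrice shown
  g1$choice[5] <- "left"
  h2 <- is_habitual_response(g1)
  expect_equal(h2$habitual, 1L)
})

test_that("a habit-heavy agent repeats almost always", {
  s <- horizon_schedule(7)
  set.seed(10)
  ff <- simulate_first_free(s, horizon_agent(repeat_bonus = 500,
                                             decision_noise = 1))
  expect_gt(mean(ff$habitual), 0.99)
})

test_that("reward maximization is 1 for a greedy noiseless agent and ~0.5 at random", {
  s <- horizon_schedule(8)
  long <- s[s$horizon == "long", ]
  set.seed(11)
  greedy <- play_schedule(long, horizon_agent(decision_noise = 0), "g")
  expect_equal(compute_reward_maximization(greedy)$reward_maximization, 1)
  set.seed(12)
  rnd <- play_schedule(long, horizon_agent(decision_noise = 1e9), "r")
  rm_ <- compute_reward_maximization(rnd)
  expect_gt(rm_$reward_maximization, 0.4)
  expect_lt(rm_$reward_maximization, 0.6)
  # a realistic noisy-greedy agent sits strictly between
  set.seed(13)
  mid <- play_schedule(long, horizon_agent(decision_noise = 8), "m")
  v <- compute_reward_maximization(mid)$reward_maximization
  expect_gt(v, 0.6)
  expect_lt(v, 1)
})

test_that("exit thresholds average the last two harvests and drop first exits", {
  thr <- compute_exit_thresholds(toy_foraging())
  # rich block trees (first exit dropped): (12,10) -> 11; (9,8) -> 8.5
  expect_equal(thr$exit_threshold_rich, mean(c(11, 8.5)))
  # poor block: single-harvest tree counts as its one yield (10);
  # then (8,7,6) -> 6.5
  expect_equal(thr$exit_threshold_poor, mean(c(10, 6.5)))
  # worked example: 10, 8.8, 7.7, 6.8 then leave -> 7.25 (first exit of the
  # rich block, visible in the per-tree table before exclusion applies)
  harv <- toy_foraging()
  tree1 <- harv$yield[harv$orchard_id == 1 & harv$tree_index == 1 &
                        harv$action == "harvest"]
  expect_equal(mean(utils::tail(tree1, 2)), 7.25)
})

test_that("exit thresholds ignore redundant post-leave records", {
  f <- toy_foraging()
  # a duplicated leave event after the tree was already left is inert
  dup <- f[f$action == "leave", ][1, ]
  dup$elapsed_s <- dup$elapsed_s + 1
  f2 <- rbind(f, dup)
  expect_equal(compute_exit_thresholds(f2)$exit_threshold_rich,
               compute_exit_thresholds(f)$exit_threshold_rich)
  thr <- compute_exit_thresholds(f, optimal = c(rich = 6.5, poor = 5.3))
  expect_equal(thr$deviation_rich, thr$exit_threshold_rich - 6.5)
  expect_equal(thr$deviation_poor, thr$exit_threshold_poor - 5.3)
})

test_that("outlier screening removes >2 SD cases in a single pass", {
  tab <- data.frame(participant_id = paste0("p", 1:6),
                    p_explore_overall = c(0.50, 0.52, 0.48, 0.51, 0.49, 0.99))
  x <- tab$p_explore_overall
  expect_true(abs(x[6] - mean(x)) > 2 * sd(x))  # fixture sanity
  res <- exclude_outliers(tab, "p_explore_overall")
  expect_equal(res$excluded$participant_id, "p6")
  expect_equal(nrow(res$kept), 5)
  # all-identical metric: nothing excluded
  same <- data.frame(participant_id = paste0("p", 1:4),
                     p_explore_overall = rep(0.5, 4))
  expect_equal(nrow(exclude_outliers(same, "p_explore_overall")$kept), 4)
  expect_error(exclude_outliers(tab[1:2, ], "p_explore_overall"), "at least 3")
  expect_error(exclude_outliers(tab, "nope"), "unknown metric")
})

test_that("participant metrics combine into one row per child", {
  s <- horizon_schedule(4)
  set.seed(14)
  tr <- rbind(play_schedule(s, horizon_agent(info_bonus = 8), "a"),
              play_schedule(s, horizon_agent(info_bonus = -8), "b"))
  m <- horizon_metrics(tr)
  expect_equal(nrow(m), 2)
  expect_true(all(c("p_explore_short", "p_explore_long", "habitual_rate",
                    "reward_maximization", "mean_reward") %in% names(m)))
  expect_true(all(m$p_explore_overall >= 0 & m$p_explore_overall <= 1))
  expect_gt(m$p_explore_overall[m$participant_id == "a"],
            m$p_explore_overall[m$participant_id == "b"])
})
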