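test_that("schedule has 80 games, balanced horizons, and exact counterbalance", {
  for (seed in c(1, 23)) {
    s <- horizon_schedule(seed)
    expect_equal(nrow(s), 80)
    expect_equal(unname(table(s$horizon)[c("short", "long")]),
                 c(40L, 40L), ignore_attr = TRUE)
    expect_equal(s$total_trials, ifelse(s$horizon == "short", 5L, 10L))
    gap <- abs(s$mu_left - s$mu_right)
    expect_true(all(gap %in% c(4, 8, 12, 20, 30)))
    expect_equal(unname(table(gap)), rep(16L, 5), ignore_attr = TRUE)
    high <- ifelse(s$mu_left > s$mu_right, "left", "right")
    cell <- table(gap, high, s$horizon, s$info_bandit == high)
    expect_true(all(cell == 2))
    # left bandit anchored at 40 or 60
    expect_true(all(s$mu_left %in% c(40, 60)))
    # forced sequence: once-shown bandit is the information option
    n_l <- nchar(gsub("R", "", s$forced_seq))
    expect_true(all(n_l %in% c(1, 3)))
    expect_equal(ifelse(n_l == 1, "left", "right"), s$info_bandit)
  }
})

test_that("schedule generation is deterministic under a fixed seed", {
  expect_identical(horizon_schedule(5), horizon_schedule(5))
  expect_false(identical(horizon_schedule(5), horizon_schedule(6)))
})

test_that("payouts are integer draws with the configured moments", {
  expect_equal(sample_payout(60, sd = 0), 60)
  expect_error(sample_payout(60, sd = -1), "non-negative")
  set.seed(1)
  x <- sample_payout(40, sd = 8, n = 100000)
  expect_true(all(x == round(x)))
  expect_lt(abs(mean(x) - 40), 3 * 8 / sqrt(100000))
  expect_gt(sd(x), 7.8)
  expect_lt(sd(x), 8.2)
  raw <- sample_payout(40, sd = 8, n = 1000, round = FALSE)
  expect_false(all(raw == round(raw)))
})

test_that("games follow the forced sequence and horizon length", {
  s <- horizon_schedule(3)
  set.seed(2)
  short <- s[s$horizon == "short", ][1, ]
  g <- play_game(short, horizon_agent())
  expect_equal(nrow(g), 5)
  expect_equal(sum(g$phase == "free"), 1)
  expect_equal(g$choice[1:4],
               ifelse(strsplit(short$forced_seq, "")[[1]] == "L",
                      "left", "right"))
  long <- s[s$horizon == "long", ][1, ]
  gl <- play_game(long, horizon_agent())
  expect_equal(nrow(gl), 10)
  expect_equal(sum(gl$phase == "free"), 6)
  # information asymmetry after forced trials: 3 vs 1 observations
  counts <- table(gl$choice[1:4])
  expect_setequal(as.integer(counts), c(1, 3))
})

test_that("a greedy noiseless agent picks the higher observed mean", {
  spec <- data.frame(game_id = 1L, horizon = "short", total_trials = 5L,
                     mu_left = 50, mu_right = 42, info_bandit = "left",
                     forced_seq = "RRLR", stringsAsFactors = FALSE)
  set.seed(4)
  g <- play_game(spec, horizon_agent(decision_noise = 0), payout_sd = 0)
  # observed means are exactly the generative means: left 50 > right 42
  expect_equal(g$choice[5], "left")
})

test_that("the agent never sees the unchosen bandit's payout", {
  s <- horizon_schedule(9)
  seen <- NULL
  spy <- function(history, spec) {
    seen <<- history
    "left"
  }
  set.seed(5)
  g <- play_game(s[s$horizon == "long", ][1, ], choose_fun = spy)
  # at the last free choice the spy saw exactly one payout per prior trial
  expect_equal(nrow(seen), 9)
  expect_equal(seen$payout, g$payout[1:9])
  expect_equal(seen$choice, g$choice[1:9])
})

test_that("a symmetric random agent explores at chance", {
  s <- horizon_schedule(11)
  set.seed(6)
  # 10,000 games via the vectorized path with a neutral agent
  ff <- do.call(rbind, lapply(1:125, function(i)
    simulate_first_free(s, horizon_agent(decision_noise = 1e9))))
  expect_equal(nrow(ff), 10000)
  expect_lt(abs(mean(ff$explored) - 0.5), 0.015)
})

test_that("invalid agent choices are rejected", {
  s <- horizon_schedule(2)
  set.seed(1)
  expect_error(play_game(s[1, ], choose_fun = function(h, sp) "up"),
               "invalid choice")
})

test_that("schedules round-trip through JSON", {
  s <- horizon_schedule(42)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule(s, path)
  s2 <- read_schedule(path)
  expect_equal(s2$mu_left, s$mu_left)
  expect_equal(s2$forced_seq, s$forced_seq)
  expect_equal(s2$total_trials, s$total_trials)
  expect_error(read_schedule(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "not a schedule")
})
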