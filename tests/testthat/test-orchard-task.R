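test_that("harvest yields deplete geometrically", {
  det <- orchard_config(depletion_sd = 0)
  expect_equal(harvest_yield(10, det), 8.8)
  expect_equal(harvest_yield(0, det), 0)
  expect_error(harvest_yield(-1, det), ">= 0")
  set.seed(1)
  cfg <- orchard_config()
  r <- harvest_yield(10, cfg, n = 100000) / 10
  expect_gt(mean(r), 0.875)
  expect_lt(mean(r), 0.885)
  expect_true(all(r > 0 & r <= 1))
})

test_that("config validation rejects impossible environments", {
  expect_error(orchard_config(depletion_mean = 1.2), "\\(0, 1\\)")
  expect_error(orchard_config(depletion_sd = -0.1), ">= 0")
  expect_error(orchard_config(orchard_duration = 5), "exceed")
})

test_that("a never-leaving agent harvests one tree for the whole block", {
  ag <- foraging_agent(1e-9)  # threshold below any expected yield
  set.seed(2)
  f <- simulate_foraging_session(ag)
  for (b in 1:4) {
    blk <- f[f$orchard_id == b, ]
    expect_equal(unique(blk$tree_index), 1L)
    expect_equal(sum(blk$action == "harvest"), floor(210 / 3))
  }
})

test_that("session time accounting respects the block budget", {
  set.seed(3)
  f <- simulate_foraging_session(foraging_agent(6, 1))
  for (b in 1:4) {
    blk <- f[f$orchard_id == b, ]
    cfg_travel <- if (blk$environment[1] == "rich") 6 else 12
    used <- sum(blk$action == "harvest") * 3 +
      sum(blk$action == "leave") * cfg_travel
    expect_lte(used, 210 + cfg_travel)  # final leave may go unused
    expect_true(all(blk$elapsed_s <= 210))
    # first action at every tree is a harvest
    first <- blk[!duplicated(blk$tree_index), ]
    expect_true(all(first$action == "harvest"))
  }
  # ABAB vs BABA ordering
  expect_equal(unique(f$environment[f$orchard_id == 1]), "rich")
  set.seed(3)
  g <- simulate_foraging_session(foraging_agent(6, 1),
                                 block_order = "BABA")
  expect_equal(unique(g$environment[g$orchard_id == 1]), "poor")
})

test_that("yield sequences decline in expectation at the depletion rate", {
  set.seed(4)
  f <- simulate_foraging_session(foraging_agent(3))
  harv <- f[f$action == "harvest", ]
  key <- paste(harv$orchard_id, harv$tree_index)
  ratios <- unlist(lapply(split(harv$yield, key), function(y)
    if (length(y) > 1) y[-1] / y[-length(y)] else NULL))
  expect_gt(mean(ratios), 0.85)
  expect_lt(mean(ratios), 0.91)
})

test_that("MVT thresholds fall as travel time rises", {
  th6 <- mvt_optimal_threshold(orchard_config(travel_time = 6))
  th12 <- mvt_optimal_threshold(orchard_config(travel_time = 12))
  th30 <- mvt_optimal_threshold(orchard_config(travel_time = 30))
  expect_gt(th6, th12)
  expect_gt(th12, th30)
})

test_that("the MVT solver is deterministic and leaves the RNG alone", {
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  a <- mvt_optimal_threshold(orchard_config(travel_time = 6), n_trees = 5000,
                             seed = 99)
  after <- runif(1)
  expect_equal(before, after)
  b <- mvt_optimal_threshold(orchard_config(travel_time = 6), n_trees = 5000,
                             seed = 99)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("brute-force policy search agrees with the analytic solver", {
  for (tt in c(6, 12)) {
    cfg <- orchard_config(travel_time = tt)
    mvt <- mvt_optimal_threshold(cfg, n_trees = 20000)
    bf <- brute_force_optimal_threshold(cfg, grid = seq(2, 9, by = 0.25),
                                        n_trees = 20000, seed = 3)
    expect_lt(abs(as.numeric(mvt) - as.numeric(bf)), 0.25)
  }
  expect_error(brute_force_optimal_threshold(orchard_config(),
                                             grid = numeric(0)),
               "non-empty")
  one <- brute_force_optimal_threshold(orchard_config(), grid = 5,
                                       n_trees = 2000)
  expect_equal(attr(one, "best_rule"), 5)
})

test_that("brute-force argmax is stable when the sample size doubles", {
  cfg <- orchard_config(travel_time = 6)
  g <- seq(3, 8, by = 0.5)
  a <- brute_force_optimal_threshold(cfg, grid = g, n_trees = 5000, seed = 11)
  b <- brute_force_optimal_threshold(cfg, grid = g, n_trees = 10000, seed = 12)
  expect_lte(abs(attr(a, "best_rule") - attr(b, "best_rule")), 0.5)
})

test_that("near-optimal agents see task-typical tree and harvest counts", {
  rich_opt <- as.numeric(mvt_optimal_threshold(orchard_config(travel_time = 6)))
  poor_opt <- as.numeric(mvt_optimal_threshold(orchard_config(travel_time = 12)))
  set.seed(31)
  stats <- t(replicate(15, {
    f <- rbind(
      simulate_foraging_block_stats(rich_opt, 6),
      simulate_foraging_block_stats(poor_opt, 12))
    c(f[1, ], f[2, ])
  }))
  # two rich blocks: around 20 trees and ~90 harvests; two poor blocks:
  # around 14 trees and ~80 harvests (children in the task were a bit less
  # efficient than the optimal policy; this is an order-of-magnitude check)
  expect_gt(mean(stats[, 1]) * 2, 14); expect_lt(mean(stats[, 1]) * 2, 28)
  expect_gt(mean(stats[, 2]) * 2, 70); expect_lt(mean(stats[, 2]) * 2, 110)
  expect_gt(mean(stats[, 3]) * 2, 9);  expect_lt(mean(stats[, 3]) * 2, 20)
  expect_gt(mean(stats[, 4]) * 2, 55); expect_lt(mean(stats[, 4]) * 2, 95)
})
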