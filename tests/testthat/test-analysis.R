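test_that("standardization is exact, strict, and idempotent", {
  d <- data.frame(x = c(1, 2, 3))
  z <- standardize(d, "x")$x
  expect_equal(z, c(-1, 0, 1))  # sample-SD convention: sd({1,2,3}) = 1
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(data.frame(x = z), "x")$x, z)
  expect_error(standardize(data.frame(x = rep(2, 5)), "x"), "constant")
})

test_that("the exploration regression recovers a planted negative slope", {
  d <- quick_cohort_games(400, seed = 21)
  ex <- compute_exploration(d)
  tab <- merge(ex, unique(d[, c("participant_id", "quic_total", "income",
                                "digit_span", "anxiety")]),
               by = "participant_id")
  r <- exploration_regression(tab)
  row <- r$table[r$table$term == "quic_total", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.001)
  expect_true(row$ci_low <= row$estimate && row$estimate <= row$ci_high)
  expect_equal(row$df, r$n - 5)
})

test_that("rank-deficient covariates are flagged", {
  d <- quick_cohort_games(80, seed = 22)
  ex <- compute_exploration(d)
  tab <- merge(ex, unique(d[, c("participant_id", "quic_total", "income",
                                "digit_span", "anxiety")]),
               by = "participant_id")
  tab$dup <- tab$digit_span
  expect_warning(
    exploration_regression(tab, covariates = c("digit_span", "dup")),
    "rank-deficient")
})

test_that("trial-level mixed models estimate planted interactions", {
  d <- quick_cohort_games(150, seed = 23)
  g <- trial_glmm(d, "habitual", "uncertainty")
  expect_false(g$fallback)
  main <- g$table[g$table$term == "quic_total", ]
  expect_gt(main$estimate, 0)  # unpredictability raises repetition
  expect_equal(g$table$odds_ratio, exp(g$table$estimate))
  me <- marginal_effects(g)
  expect_equal(nrow(me), 2)
  expect_true(all(me$ci_low <= me$M & me$M <= me$ci_high))
  expect_error(trial_glmm(d[d$horizon == "short", ], "explore", "horizon"),
               "constant")
})

test_that("with no participant heterogeneity the GLMM matches plain logistic", {
  set.seed(24)
  n_part <- 60
  sched <- horizon_schedule(31)
  ag <- horizon_agent(info_bonus = 2, decision_noise = 8, repeat_bonus = 1)
  games <- do.call(rbind, lapply(seq_len(n_part), function(i)
    simulate_first_free(sched, ag, participant_id = paste0("p", i))))
  games$quic_total <- rep(rnorm(n_part), each = nrow(sched))
  games$income <- rep(rnorm(n_part), each = nrow(sched))
  games$digit_span <- rep(rnorm(n_part), each = nrow(sched))
  games$anxiety <- rep(rnorm(n_part), each = nrow(sched))
  g <- trial_glmm(games, "explore", "horizon")
  dat <- standardize(games, c("quic_total", "income", "digit_span",
                              "anxiety"))
  dat$.mod <- factor(dat$horizon, levels = c("short", "long"))
  plain <- glm(explored ~ quic_total * .mod + digit_span + income + anxiety,
               data = dat, family = binomial)
  pc <- coef(plain)
  gc <- g$table$estimate[match(names(pc), g$table$term)]
  expect_lt(max(abs(gc - pc)), 0.05)
})

test_that("mediation algebra holds exactly and recovers planted structure", {
  d <- quick_cohort_games(500, seed = 25)
  ex <- compute_exploration(d)
  hab <- aggregate(habitual ~ participant_id, d, mean)
  names(hab)[2] <- "habitual_rate"
  tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(ex, hab, unique(d[, c("participant_id", "quic_total",
                                           "income", "digit_span",
                                           "anxiety")])))
  med <- mediate_boot(tab, n_boot = 1000, seed = 3)
  expect_equal(med$total, med$direct + med$indirect, tolerance = 1e-8)
  expect_gt(med$path_a, 0)       # U -> habit
  expect_lt(med$path_b, 0)       # habit -> less exploration
  expect_lt(med$ci_indirect[["upper"]], 0)
  # determinism per seed
  med2 <- mediate_boot(tab, n_boot = 1000, seed = 3)
  expect_identical(med$ci_indirect, med2$ci_indirect)
  expect_error(mediate_boot(tab, n_boot = 10), "at least 1000")
})

test_that("null mediation yields an interval covering zero", {
  cfg <- effect_config(slope_repeat = 0, slope_info = 0)
  d <- quick_cohort_games(300, cfg, seed = 26)
  ex <- compute_exploration(d)
  hab <- aggregate(habitual ~ participant_id, d, mean)
  names(hab)[2] <- "habitual_rate"
  tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(ex, hab, unique(d[, c("participant_id", "quic_total",
                                           "income", "digit_span",
                                           "anxiety")])))
  med <- mediate_boot(tab, n_boot = 1000, seed = 4)
  expect_lt(med$ci_indirect[["lower"]], 0)
  expect_gt(med$ci_indirect[["upper"]], 0)
})

test_that("optimality tests detect planted over-exploration", {
  set.seed(27)
  thr <- data.frame(participant_id = paste0("p", 1:76),
                    deviation_rich = rnorm(76, 1.5, 2),
                    deviation_poor = rnorm(76, 1.5, 2))
  res <- optimality_tests(thr)
  expect_equal(res$environment, c("rich", "poor"))
  expect_true(all(res$df == 75))
  expect_true(all(res$t > 2))
  expect_true(all(res$mean_deviation > 0))
  zero <- data.frame(participant_id = c("a", "b", "c"),
                     deviation_rich = c(0, 1e-12, -1e-12),
                     deviation_poor = c(0, 1e-12, -1e-12))
  rz <- optimality_tests(zero)
  expect_lt(abs(rz$t[1]), 1)
  expect_error(optimality_tests(thr[1, ]), "at least 2")
})

test_that("the environment effect has the rich-minus-poor sign and null behavior", {
  set.seed(28)
  n <- 40
  mk <- function(env, mu) do.call(rbind, lapply(1:n, function(i)
    data.frame(participant_id = paste0("p", i), orchard_id = 1,
               environment = env, tree_index = 1:8,
               exit_threshold = rnorm(8, mu + rnorm(1, 0, 0.3), 0.8),
               stringsAsFactors = FALSE)))
  tt <- rbind(mk("rich", 6.5), mk("poor", 5.3))
  r <- environment_effect(tt)
  row <- r$table[r$table$term == "environmentrich", ]
  expect_gt(row$estimate, 0.9)
  expect_lt(row$estimate, 1.5)
  expect_lt(row$p, 0.001)
  # permuting labels kills the effect
  tt$environment <- sample(tt$environment)
  r0 <- environment_effect(tt)
  expect_gt(r0$table$p[2], 0.01)
})
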