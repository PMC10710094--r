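#' Orchard (patch-foraging) environment configuration
#'
#' Environment parameters for the foraging task: harvesting takes 3 s and
#' yields, on average, 88% of the previous harvest at the same tree;
#' traveling to a fresh tree takes 6 s ("rich" orchards) or 12 s ("poor"
#' orchards), during which no harvesting occurs; each orchard block lasts
#' 210 s (four blocks = 14 min).
#'
#' The depletion factor of each harvest is drawn from a normal distribution
#' truncated *symmetrically* around its mean (to `(2*mean - 1, 1]` for means
#' above 0.5), so the realized mean depletion equals `depletion_mean`
#' exactly. Initial tree yields are normal truncated at zero; their default
#' mean and SD were calibrated once so that the Marginal Value Theorem
#' solver reproduces the published optimal exit thresholds (6.52 apples for
#' 6 s travel, 5.31 for 12 s travel).
#'
#' @param travel_time Travel time between trees, seconds (6 or 12).
#' @param harvest_time Time per harvest, seconds.
#' @param depletion_mean Mean multiplicative depletion per harvest, in (0,1).
#' @param depletion_sd SD of the depletion factor; 0 gives deterministic
#'   geometric depletion.
#' @param initial_yield_mean,initial_yield_sd Mean/SD of a fresh tree's
#'   first harvest, in apples (normal truncated at 0).
#' @param orchard_duration Duration of one orchard block, in seconds.
#' @return An object of class `orchard_config` (a list).
#' @examples
#' cfg <- orchard_config(travel_time = 6)
#' mvt_optimal_threshold(cfg)
#' @export
orchard_config <- function(travel_time = 6, harvest_time = 3,
                           depletion_mean = 0.88, depletion_sd = 0.07,
                           initial_yield_mean = 9.78,
                           initial_yield_sd = 5.10,
                           orchard_duration = 210) {
  assert_that(depletion_mean > 0 && depletion_mean < 1,
              "depletion_mean must be in (0, 1)")
  assert_that(depletion_sd >= 0, "depletion_sd must be >= 0")
  assert_that(travel_time > 0 && harvest_time > 0,
              "travel_time and harvest_time must be positive")
  assert_that(orchard_duration > travel_time + harvest_time,
              "orchard_duration must exceed one travel plus one harvest")
  assert_that(initial_yield_mean > 0 && initial_yield_sd >= 0,
              "initial yield moments invalid")
  structure(list(travel_time = travel_time, harvest_time = harvest_time,
                 depletion_mean = depletion_mean, depletion_sd = depletion_sd,
                 initial_yield_mean = initial_yield_mean,
                 initial_yield_sd = initial_yield_sd,
                 orchard_duration = orchard_duration),
            class = "orchard_config")
}

#' The rich/poor environment pair
#'
#' @param ... Overrides passed to both [orchard_config()] calls.
#' @return Named list with elements `rich` (6 s travel) and `poor` (12 s).
#' @export
orchard_environments <- function(...) {
  list(rich = orchard_config(travel_time = 6, ...),
       poor = orchard_config(travel_time = 12, ...))
}

# depletion factor draws with mean exactly depletion_mean: the parent normal
# is truncated symmetrically around the mean (and never above 1)
rdepletion <- function(n, config) {
  m <- config$depletion_mean
  s <- config$depletion_sd
  if (s == 0) return(rep(m, n))
  hi <- min(1, m + (1 - m))
  lo <- m - (hi - m)
  rtruncnorm(n, m, s, lo, hi)
}

rinitial_yield <- function(n, config) {
  rtruncnorm(n, config$initial_yield_mean, config$initial_yield_sd, lower = 0)
}

#' Yield of the next harvest at a tree
#'
#' Multiplies the previous harvest by a stochastic depletion factor with
#' mean `depletion_mean` (0.88 by default: each harvest yields 88% of the
#' previous one on average). With `depletion_sd = 0` the product is exact.
#'
#' @param previous_yield Previous harvest at this tree, in apples (>= 0).
#' @param config An [orchard_config()].
#' @param n Number of draws (each an independent depletion factor applied
#'   to `previous_yield`).
#' @return Numeric vector of next-harvest yields.
#' @export
harvest_yield <- function(previous_yield, config = orchard_config(), n = 1) {
  assert_that(all(previous_yield >= 0), "previous_yield must be >= 0")
  previous_yield * rdepletion(n, config)
}

#' Simulate a four-block foraging session
#'
#' Plays the ABAB/BABA block structure against a threshold agent. Within a
#' block, the first action at every tree is a harvest; afterwards the agent
#' leaves when the expected next harvest (`depletion_mean` times the last
#' yield) falls below its threshold. Each harvest consumes
#' `harvest_time` seconds and each move `travel_time` seconds; an action
#' that does not fit in the remaining block time is discarded and the block
#' ends.
#'
#' @param agent A [foraging_agent()].
#' @param environments Named list with `rich` and `poor`
#'   [orchard_config()]s, as from [orchard_environments()].
#' @param block_order "ABAB" (rich first) or "BABA" (poor first).
#' @param participant_id Identifier recorded on each event.
#' @return Data frame of foraging events: `participant_id`, `orchard_id`
#'   (1-4), `environment` ("rich"/"poor"), `tree_index` (within block),
#'   `action` ("harvest"/"leave"), `yield` (apples; `NA` for leave events),
#'   `elapsed_s` (time within block when the action completed).
#' @export
simulate_foraging_session <- function(agent,
                                      environments = orchard_environments(),
                                      block_order = "ABAB",
                                      participant_id = "sim") {
  stopifnot(inherits(agent, "foraging_agent"))
  assert_that(block_order %in% c("ABAB", "BABA"),
              "block_order must be 'ABAB' or 'BABA'")
  envs <- if (block_order == "ABAB") c("rich", "poor", "rich", "poor")
          else c("poor", "rich", "poor", "rich")
  rows <- lapply(1:4, function(b) {
    m <- simulate_foraging_block(agent, environments[[envs[b]]])
    if (is.null(m)) return(NULL)
    m$orchard_id <- b
    m$environment <- envs[b]
    m
  })
  out <- do.call(rbind, rows)
  out$participant_id <- participant_id
  out[, c("participant_id", "orchard_id", "environment", "tree_index",
          "action", "yield", "elapsed_s")]
}

#' Simulate one orchard block
#'
#' Workhorse behind [simulate_foraging_session()]; also usable directly
#' when blocks need different agents (e.g. environment-specific
#' thresholds).
#'
#' @param agent A [foraging_agent()].
#' @param cfg An [orchard_config()].
#' @return Data frame with `tree_index`, `action`, `yield`, `elapsed_s`, or
#'   `NULL` if nothing fit in the block.
#' @export
simulate_foraging_block <- function(agent, cfg) {
  t_now <- 0
  tree <- 0L
  recs <- list()
  last_yield <- NA_real_
  at_tree <- FALSE
  repeat {
    if (!at_tree) {
      # arriving at the very first tree of a block costs no travel
      cost <- if (tree == 0L) 0 else cfg$travel_time
      if (t_now + cost + cfg$harvest_time > cfg$orchard_duration) break
      t_now <- t_now + cost
      tree <- tree + 1L
      last_yield <- rinitial_yield(1, cfg)  # forced first harvest
      t_now <- t_now + cfg$harvest_time
      recs[[length(recs) + 1]] <- list(tree, "harvest", last_yield, t_now)
      at_tree <- TRUE
      next
    }
    expected_next <- cfg$depletion_mean * last_yield
    act <- act_foraging(agent, expected_next)
    if (act == "harvest") {
      if (t_now + cfg$harvest_time > cfg$orchard_duration) break
      last_yield <- harvest_yield(last_yield, cfg)
      t_now <- t_now + cfg$harvest_time
      recs[[length(recs) + 1]] <- list(tree, "harvest", last_yield, t_now)
    } else {
      recs[[length(recs) + 1]] <- list(tree, "leave", NA_real_, t_now)
      at_tree <- FALSE
    }
  }
  if (!length(recs)) return(NULL)
  data.frame(
    tree_index = vapply(recs, function(r) r[[1]], integer(1)),
    action = vapply(recs, function(r) r[[2]], character(1)),
    yield = vapply(recs, function(r) r[[3]], numeric(1)),
    elapsed_s = vapply(recs, function(r) r[[4]], numeric(1)),
    stringsAsFactors = FALSE)
}

# Simulate a matrix of per-tree harvest sequences (rows = trees, cols =
# successive harvests, unbounded by any leave rule). Shared by the MVT
# solver and the brute-force oracle.
simulate_tree_matrix <- function(config, n_trees, max_harvests = 60) {
  s0 <- rinitial_yield(n_trees, config)
  Y <- matrix(0, n_trees, max_harvests)
  Y[, 1] <- s0
  for (k in 2:max_harvests)
    Y[, k] <- Y[, k - 1] * rdepletion(n_trees, config)
  Y
}

# Evaluate a fixed leave rule "leave once expected next harvest < rule_c" on
# a pre-simulated tree matrix: long-run reward rate, mean exit threshold
# (mean of the last two harvests; a single harvest counts as itself), and
# mean harvests per tree.
eval_leave_rule <- function(Y, config, rule_c) {
  n_trees <- nrow(Y)
  maxk <- ncol(Y)
  cont <- config$depletion_mean * Y[, -maxk, drop = FALSE] >= rule_c
  for (k in 2:ncol(cont)) cont[, k] <- cont[, k] & cont[, k - 1]
  n <- 1 + rowSums(cont)  # forced first harvest
  idx <- cbind(seq_len(n_trees), n)
  csum <- Y
  for (k in 2:maxk) csum[, k] <- csum[, k] + csum[, k - 1]
  total_reward <- csum[idx]
  total_time <- n * config$harvest_time + config$travel_time
  last <- Y[idx]
  prev <- Y[cbind(seq_len(n_trees), pmax(n - 1, 1))]
  theta <- ifelse(n >= 2, (last + prev) / 2, last)
  list(rate = sum(total_reward) / sum(total_time),
       exit_threshold = mean(theta),
       mean_harvests = mean(n))
}

#' Optimal exit threshold by the Marginal Value Theorem
#'
#' Solves for the reward-rate-maximizing leave rule: leave a tree as soon as
#' the expected next harvest falls below `rho * harvest_time`, where `rho`
#' is the long-run reward per second induced by that same rule (including
#' travel). The fixed point is found by iterating the rate map over a large
#' fixed set of simulated trees (common random numbers, internal seed), and
#' the returned value is expressed in the behavioral operationalization of
#' the exit threshold -- the expected mean of the last two harvests before
#' leaving -- so that optimal and observed thresholds are directly
#' comparable.
#'
#' @param config An [orchard_config()].
#' @param n_trees Number of simulated trees used in the expectation.
#' @param max_harvests Per-tree harvest cap (far beyond the optimal rule's
#'   reach at default settings).
#' @param seed Internal seed for the tree sample; the caller's RNG state is
#'   left untouched.
#' @param tol,max_iter Fixed-point convergence tolerance and iteration cap.
#' @return The optimal exit threshold, in apples, with attributes
#'   `rate` (apples/s at the optimum), `rule_threshold` (the expected-yield
#'   cutoff `rho * harvest_time`), and `mean_harvests`.
#' @export
mvt_optimal_threshold <- function(config = orchard_config(),
                                  n_trees = 40000, max_harvests = 60,
                                  seed = 1L, tol = 1e-9, max_iter = 200) {
  stopifnot(inherits(config, "orchard_config"))
  key <- paste(c(unlist(config), n_trees, max_harvests, seed, tol),
               collapse = "|")
  hit <- .mvt_cache[[key]]
  if (!is.null(hit)) return(hit)
  Y <- with_preserved_seed(seed, simulate_tree_matrix(config, n_trees,
                                                      max_harvests))
  rule_c <- config$depletion_mean * config$initial_yield_mean / 2
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    new_c <- eval_leave_rule(Y, config, rule_c)$rate * config$harvest_time
    if (abs(new_c - rule_c) < tol) { rule_c <- new_c; converged <- TRUE; break }
    rule_c <- new_c
  }
  if (!converged)
    stop(sprintf(
      "MVT fixed point did not converge in %d iterations (last rule = %.4f)",
      max_iter, rule_c))
  res <- eval_leave_rule(Y, config, rule_c)
  out <- structure(res$exit_threshold, rate = res$rate,
                   rule_threshold = rule_c,
                   mean_harvests = res$mean_harvests)
  .mvt_cache[[key]] <- out
  out
}

# deterministic-result cache (the solver is a pure function of its
# arguments, seed included), so repeated cohort generation is cheap
.mvt_cache <- new.env(parent = emptyenv())

#' Brute-force optimal threshold by policy simulation
#'
#' Independent oracle for [mvt_optimal_threshold()]: evaluates a grid of
#' candidate leave rules by direct simulation, picks the rule maximizing
#' apples per second, and returns the mean exit threshold (last-two-harvest
#' average) realized under that rule.
#'
#' @param config An [orchard_config()].
#' @param grid Numeric vector of candidate rule cutoffs (expected-next-yield
#'   units, apples).
#' @param n_trees Trees simulated per candidate (shared across candidates
#'   via common random numbers).
#' @param max_harvests Per-tree harvest cap.
#' @param seed Internal seed; caller's RNG state preserved.
#' @return Best candidate's exit threshold (apples), with attributes
#'   `best_rule` and `rate`.
#' @export
brute_force_optimal_threshold <- function(config = orchard_config(),
                                          grid = seq(1, 12, by = 0.25),
                                          n_trees = 20000,
                                          max_harvests = 60, seed = 1L) {
  assert_that(length(grid) >= 1, "candidate grid must be non-empty")
  Y <- with_preserved_seed(seed, simulate_tree_matrix(config, n_trees,
                                                      max_harvests))
  evals <- lapply(grid, function(g) eval_leave_rule(Y, config, g))
  rates <- vapply(evals, `[[`, numeric(1), "rate")
  best <- which.max(rates)
  structure(evals[[best]]$exit_threshold, best_rule = grid[best],
            rate = rates[best])
}
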