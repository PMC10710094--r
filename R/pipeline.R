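#' Run the simulation stage and write trial logs
#'
#' Generates a synthetic cohort, simulates the full bandit schedule and
#' foraging session for every child, and writes tidy CSVs plus a JSON run
#' manifest recording every seed, so a run can be reproduced exactly.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Cohort size.
#' @param config An [effect_config()].
#' @param seeds Named list with `cohort` and `simulation` integer seeds.
#' @return Invisibly, the list of written file paths.
#' @export
run_simulation <- function(out_dir, n = 84, config = effect_config(),
                           seeds = list(cohort = 1L, simulation = 2L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n, config, seed = seeds$cohort)
  study <- simulate_study(cohort, seed = seeds$simulation)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    horizon = file.path(out_dir, "horizon_trials.csv"),
    foraging = file.path(out_dir, "foraging_trials.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  utils::write.csv(study$horizon, paths$horizon, row.names = FALSE)
  utils::write.csv(study$foraging, paths$foraging, row.names = FALSE)
  manifest <- list(
    package = "horizonforage",
    version = as.character(utils::packageVersion("horizonforage")),
    n_participants = n, seeds = seeds,
    config = config[!vapply(config, is.null, logical(1))],
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Run the analysis stage over written trial logs
#'
#' Reads the CSVs produced by [run_simulation()], applies the outlier
#' screen, and runs the full statistical pipeline: the covariate-adjusted
#' exploration regression, the three trial-level interaction models with
#' marginal effects, bootstrap mediation through habitual responding, the
#' environment manipulation check, and the optimality t tests. Results are
#' written as a participant-metrics CSV and a JSON report.
#'
#' @param in_dir Directory containing `cohort.csv`, `horizon_trials.csv`,
#'   `foraging_trials.csv`.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param n_boot Bootstrap resamples for mediation.
#' @param seed Seed for the bootstrap.
#' @return Invisibly, the assembled results list.
#' @export
run_analysis <- function(in_dir, out_dir = in_dir, n_boot = 5000,
                         seed = 1L) {
  need <- file.path(in_dir, c("cohort.csv", "horizon_trials.csv",
                              "foraging_trials.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing input files: ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- utils::read.csv(file.path(in_dir, "cohort.csv"))
  horizon <- utils::read.csv(file.path(in_dir, "horizon_trials.csv"))
  foraging <- utils::read.csv(file.path(in_dir, "foraging_trials.csv"))

  metrics <- horizon_metrics(horizon)
  metrics <- merge(metrics, cohort[, c("participant_id", "quic_total",
                                       "income", "digit_span", "anxiety")],
                   by = "participant_id")
  screened <- exclude_outliers(metrics, "p_explore_overall")
  kept <- screened$kept

  optimal <- c(rich = as.numeric(mvt_optimal_threshold(
                 orchard_config(travel_time = 6))),
               poor = as.numeric(mvt_optimal_threshold(
                 orchard_config(travel_time = 12))))
  thresholds <- compute_exit_thresholds(foraging, optimal = optimal)
  thr_screen <- exclude_outliers(
    merge(thresholds, cohort[, c("participant_id", "quic_total")],
          by = "participant_id"),
    "exit_threshold_rich")
  tree_thr <- compute_exit_thresholds(foraging, per_tree = TRUE)
  tree_thr <- tree_thr[tree_thr$participant_id %in%
                         thr_screen$kept$participant_id, ]

  games <- first_free_table(horizon)
  games <- merge(games, cohort[, c("participant_id", "quic_total", "income",
                                   "digit_span", "anxiety")],
                 by = "participant_id")
  games <- games[games$participant_id %in% kept$participant_id, ]

  reg <- exploration_regression(kept)
  g_horizon <- trial_glmm(games, "explore", "horizon")
  g_conflict <- trial_glmm(games, "explore", "conflict")
  g_uncert <- trial_glmm(games, "habitual", "uncertainty")
  med <- mediate_boot(kept, n_boot = n_boot, seed = seed)
  env_eff <- environment_effect(tree_thr)
  opt <- optimality_tests(thr_screen$kept)

  results <- list(
    n_analyzed = nrow(kept),
    horizon_outliers = screened$excluded$participant_id,
    foraging_outliers = thr_screen$excluded$participant_id,
    exploration_regression = reg$table,
    glmm_horizon = g_horizon$table,
    glmm_horizon_marginal = try_me(g_horizon),
    glmm_conflict = g_conflict$table,
    glmm_uncertainty = g_uncert$table,
    mediation = list(a = med$path_a, b = med$path_b,
                     indirect = med$indirect, direct = med$direct,
                     total = med$total, ci = unname(med$ci_indirect)),
    environment_effect = env_eff$table,
    optimality = opt,
    optimal_thresholds = as.list(optimal))
  utils::write.csv(metrics, file.path(out_dir, "participant_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}

try_me <- function(g) {
  tryCatch(marginal_effects(g), error = function(e) NULL)
}
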