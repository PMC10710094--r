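# horizonforage

Simulation and analysis of explore–exploit behavior in two developmental
decision-making paradigms, built for studying how individual differences —
in particular a child's perceived environmental unpredictability — relate to
exploration.

## What it models

**Horizon (bandit) task.** Each of 80 games presents two one-armed bandits
with Gaussian payouts (SD 8 points, rounded to integers). Four forced
choices show one bandit three times and the other once, creating an
information imbalance; the once-shown bandit is the *high-information
option*, and choosing it at the first free choice operationalizes
exploration. Games have either one (short horizon) or six (long horizon)
free choices; exploring more in long-horizon games is *strategic
exploration*. Choices are modeled with a logistic rule over the decision
variable

```
ΔR + A·ΔI + B·side + K·rep
```

where ΔR is the observed payout-mean difference, A is the information bonus
(points), B a spatial bias, K a choice-repetition ("habit") bonus, and the
logistic temperature σ is the decision noise. The same likelihood is used to
simulate agents and to fit them by multi-start maximum likelihood.

**Orchard (patch-foraging) task.** Trees yield, on average, 88% of the
previous harvest on each further harvest (3 s per harvest); moving to a
fresh tree costs 6 s (rich orchards) or 12 s (poor orchards). The optimal
policy, by the Marginal Value Theorem, leaves a tree when the expected next
harvest falls below ρ*·(harvest time), where ρ* is the long-run reward rate
that this same rule induces. `mvt_optimal_threshold()` solves that fixed
point and reports it as the behavioral *exit threshold* (mean of the last
two harvests before leaving): ≈ 6.52 apples for 6 s travel and ≈ 5.31 for
12 s travel under the calibrated default environment.

**Synthetic cohort and statistics.** `generate_cohort()` draws children
with a latent unpredictability factor, a 38-item questionnaire total
(five subscales: 9, 12, 7, 7, 3 items; totals right-skewed, mean ≈ 5.6,
SD ≈ 5.1), covariates, and planted agent parameters — by default
unpredictability raises the habit bonus K, which lowers exploration, so the
unpredictability→exploration association is fully mediated by habitual
responding. The analysis stage mirrors a typical study pipeline:
covariate-adjusted OLS, trial-level logistic mixed models with interactions
(lme4), estimated marginal effects (emmeans), percentile-bootstrap
mediation, and one-sample optimality tests.

## Worked example

```r
library(horizonforage)

rich <- mvt_optimal_threshold(orchard_config(travel_time = 6))
poor <- mvt_optimal_threshold(orchard_config(travel_time = 12))
round(c(rich = as.numeric(rich), poor = as.numeric(poor)), 2)
#>  rich  poor
#>  6.54  5.28

cohort <- generate_cohort(200, seed = 1)
games  <- cohort_first_free(cohort, seed = 2)
tab <- merge(compute_exploration(games),
             cohort[, c("participant_id", "quic_total", "income",
                        "digit_span", "anxiety")],
             by = "participant_id")
res <- exploration_regression(tab)
subset(res$table, term == "quic_total")[, c("estimate", "se", "p")]
#>      estimate          se            p
#> 2 -0.03176187 0.006857756 6.621899e-06
```

The regression slope is the change in the exploration rate (proportion of
first free choices to the high-information option) per SD of the
questionnaire score: children one SD higher in reported unpredictability
explore about 3 percentage points less, which is the planted habit-mediated
effect attenuated by questionnaire noise.

```r
hab <- aggregate(habitual ~ participant_id, games, mean)
names(hab)[2] <- "habitual_rate"
med <- mediate_boot(merge(tab, hab, by = "participant_id"),
                    n_boot = 2000, seed = 3)
med
#> <mediation_result> n = 200
#>   a = 0.0524, b = -0.5868, indirect ab = -0.0307 [-0.0438, -0.0175]
#>   direct c' = -0.0010, total c = -0.0318
```

The indirect path (unpredictability → habitual responding → less
exploration) carries essentially the whole association; the direct path is
near zero, as planted.

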