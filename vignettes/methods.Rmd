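---
title: "Models and methods behind horizonforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind horizonforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the generative models, the numerical choices, and
the design decisions in `horizonforage`, in the spirit of a methods
appendix: what each component assumes, which knobs matter, and what the
package's own validation does and does not establish.

```{r setup}
library(horizonforage)
```

## The bandit task and its choice model

Each game presents two bandits with Gaussian payouts (SD 8 points, rounded
half-away-from-zero to integers; no floor — negative draws are possible in
principle but vanishingly rare at the means used). The 80-game schedule is
a complete factorial: payout-mean gap (4, 8, 12, 20, 30 points) × high-mean
side (left/right) × horizon (5 vs 10 trials) × placement of the
high-information option (on the higher- or lower-mean bandit), each cell
twice. The left bandit anchors the payout scale at 40 in one replicate and
60 in the other; the right bandit sits a gap above or below it depending on
the high-mean side. The four forced trials show one bandit three times and
the other once, in uniformly random order per game (the internal order is
not analyzed downstream, so per-seed randomization is harmless; whether the
original task fixed it per game across participants is unknown).

Free choices follow a logistic rule on the decision variable
$\Delta R + A\,\Delta I + B\cdot\mathrm{side} + K\cdot\mathrm{rep}$, with
temperature $\sigma$ (decision noise, points). Conventions that matter for
interpreting fitted values:

* $\Delta R$ is the difference in *observed* payout means (the agent never
  sees the unchosen bandit's payout).
* $\Delta I \in \{-1, 0, +1\}$ marks the less-sampled option (0 when the
  observation counts tie, as can happen late in long games). With this ±1
  coding the model is exactly antisymmetric under swapping the options, and
  $A$ is the premium, in points, attached to the information imbalance.
* The repetition indicator points at the previously chosen option — at the
  first free choice, the trial-4 (forced) choice. This matches the
  behavioral habitual-responding measure, which asks whether trial 5
  repeats trial 4.
* $\sigma = 0$ is the greedy limit; exact ties are broken by a fair coin
  rather than raising an error, so degenerate test configurations stay
  well-defined.

Simulation and likelihood share one implementation of this rule; the
fitter cannot drift from the generator.

### Fitting

`fit_horizon_model()` minimizes the first-free-choice negative
log-likelihood with L-BFGS-B inside the box $A, B, K \in [-30, 30]$,
$\sigma \in [0.1, 50]$, from 10 starts (one neutral, the rest uniform in
the box, drawn deterministically from the seed). Only first free choices
enter the likelihood: after trial 5 information and reward confound each
other by design, so later trials identify the parameters poorly and are
used for behavioral metrics only. The per-horizon variant shares $B$ and
$K$ across conditions and frees $A$ and $\sigma$, the convention when
baseline information seeking is reported per horizon. `grid_search_fit()`
is an exhaustive oracle over a coarse 4-D grid used in the tests to confirm
the optimizer lands on the global optimum of small problems, and
`parameter_recovery()` runs the standard simulate–refit validation; with
160 games per agent the true-vs-recovered correlations clear the 0.8
(information bonus) and 0.7 (repeat bonus) validation thresholds with a
wide margin.

## The foraging task and the optimal threshold

Trees deplete multiplicatively: each harvest yields the previous harvest
times a depletion factor with mean 0.88. Two numerical choices here are
deliberate:

* **Depletion noise.** The factor is drawn from a normal with SD 0.07
  truncated *symmetrically* around its mean, to (0.76, 1]. One-sided
  truncation at 1 would drag the realized mean below the configured 0.88;
  symmetric truncation preserves it exactly, which keeps the simulator's
  realized depletion rate equal to the task's stated rate.
* **Initial yields.** Fresh trees draw their first harvest from a normal
  truncated at zero. The published task description does not state this
  distribution; its mean and SD (9.78 and 5.10 apples) were calibrated
  once, by least squares, so that the optimality solver reproduces the two
  published optimal exit thresholds (6.52 and 5.31 apples). With that
  single calibration the solver returns ≈ 6.54 and ≈ 5.28 — both within
  0.05 of the targets, with a rich–poor gap of ≈ 1.26 against the printed
  1.21; no (mean, SD, depletion-SD) combination we searched closes that
  last gap, suggesting a minor structural difference from the original
  implementation (e.g. the exact initial-yield law). These defaults are
  calibrated stand-ins, flagged as such.

Sessions respect the task's time accounting: 3 s per harvest, 6 or 12 s
per move, four 210-s blocks in ABAB/BABA order, a forced first harvest at
every tree, and block truncation that discards any action that does not
fit the remaining time. A threshold agent with the optimal rule visits
roughly 21 trees and harvests roughly 95 times across the two rich blocks,
and roughly 14 trees / 82 harvests across the poor blocks — the right
order of magnitude for child participants, who are somewhat less efficient.

`mvt_optimal_threshold()` solves the Marginal Value Theorem fixed point:
leave when the expected next harvest drops below $\rho^* h$, where
$\rho^*$ is the long-run reward per second (travel included) induced by
that same rule. The expectation runs over 40,000 pre-simulated trees with
common random numbers and an internal seed, so the solver is a pure
function of its arguments and leaves the caller's RNG untouched; the
result is reported as the expected mean of the last two harvests before
leaving, the same operationalization as the behavioral exit threshold, so
observed and optimal values are directly comparable (Monte-Carlo SE at the
default size ≈ 0.01 apples). `brute_force_optimal_threshold()` is the
independent oracle: it scores a grid of candidate rules by simulated
reward rate and returns the best rule's realized threshold; solver and
oracle agree within the grid resolution.

Behavioral exit thresholds average the last two harvests before each
leave, dropping the first exit of every block (the participant cannot yet
know the travel time). A tree harvested only once contributes its single
yield — the task forces at least one harvest, so this is the natural
degenerate value and preserves sample size; the original's handling is not
stated.

## The synthetic cohort

`generate_cohort()` emulates a sample of 10–13-year-olds well enough to
exercise every downstream stage:

* **Questionnaire.** 38 binary items in subscales of 9, 12, 7, 7, and 3.
  Items share one latent factor (thresholded common-factor model); the
  loading and threshold are moment-matched numerically so the total score
  has mean ≈ 5.63 and SD ≈ 5.05 — strongly right-skewed, most children
  near zero, exactly the regime where SD ≈ mean. The factor correlates
  with latent unpredictability $U$ at the configured reliability (0.8),
  so questionnaire noise attenuates effects as in real instruments. Item
  response formats and reverse-scoring of the real instrument are not
  modeled; the total-score moments are the emulation target.
* **Covariates.** Ordinal family income (rounded normal, 1–7, mean 4.29,
  SD 1.39), digit span (rounded normal, mean 10.85, SD 3.18), a standard
  normal "distress" scalar standing in for anxiety/perceived stress, and a
  parent-report scalar unrelated to behavior (for specificity analyses).
* **Planted effects.** Repeat bonus $K = 1 + 6U + \varepsilon$,
  $\varepsilon \sim N(0, 8^2)$; information bonuses 1.2 (short) / 2.6
  (long) plus an optional direct path `slope_info`·$U$ (0 by default) and
  $N(0,1)$ individual spread; noise $\sigma = 8$; foraging thresholds sit
  1.5 apples above optimal (children over-explore) with 1-apple
  between-child spread shared across environments.

Two kinds of consideration fixed the planted magnitudes, both decided by
design simulation before any validation was written. First, the baselines
reproduce the aggregate behavior profile reported for this age group:
exploration ≈ 0.52, strategic exploration ≈ +0.02, habitual responding
≈ 0.47, reward maximization ≈ 0.8. Second, mediation through a *measured*
mediator is only recoverable if the mediator is reliable: the habitual
rate is estimated from 80 games (binomial SE ≈ 0.056), so the
between-child spread of $K$ (slope 6, residual SD 8) is sized to push the
mediator's reliability near 0.9. With weaker habit variation the indirect
path would be attenuated and a spurious direct path would appear — a
measurement-error fact about mediation, not a property of the tasks.

What the generator does *not* emulate: item-level psychometrics,
reaction times, age/demographic structure, task-order effects, learning or
fatigue across games, and any nonlinearity in the $U$→parameter maps.
Passing pipeline tests on these cohorts shows the estimators are correct
and calibrated under the stated generative model, not that the effects
exist in children.

## The analysis stage

All continuous predictors are standardized (sample SD; constant columns
are an error). The participant-level exploration regression is OLS with
Wald CIs. Trial-level models are logistic mixed models with a participant
random intercept (`lme4::glmer`); a singular (zero-variance) random intercept is accepted
as a valid boundary fit, while a genuine convergence failure triggers a
pooled logistic fallback, flagged in the result (`fallback = TRUE`) —
participant dummies are not used because they would absorb the
between-person predictors of interest. Richer random structures (per-condition
intercepts) are intentionally not the default: at 80 trials per child they
are frequently singular, and the simplification is documented rather than
silent. Marginal effects come from `emmeans::emtrends` on the response
scale: the average change in predicted outcome probability per SD of the
predictor at each moderator level, delta-method SEs. Mediation is the
product-of-coefficients estimator from two nested linear regressions, so
total = direct + indirect holds exactly; uncertainty comes from a
percentile bootstrap over participants (default 5000 resamples, seeded).
No multiple-testing correction is applied anywhere, matching the reporting
style the pipeline mirrors. Outlier screening removes participants more
than 2 SD from the sample mean of a metric in a single pass — deliberately
not iterated, and deliberately per-task (exclusion in one task does not
propagate to the other).

One known ambiguity: published "baseline exploration" tables of this
paradigm sometimes report model-parameter tests and sometimes proportion
tests, without stating units. The package exposes both (fitted information
bonus vs 0; exploration proportion vs 0.5) and asserts neither mapping.

## Problem sizes used in validation

The package's own test suite runs the solver–oracle comparison at 20,000
trees; parameter recovery with 100 agents × 160 games; regression
calibration and power on 100 null and 100 planted cohorts of n = 84;
mediation recovery at n = 1000 (2000 bootstrap resamples) plus 30 null
cohorts of n = 300; and the generator calibration checks at 100,000
draws. These sizes keep every Monte-Carlo standard error comfortably
below the tolerance it is checked against while the whole suite stays in
the minutes range.
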