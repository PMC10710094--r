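Package: horizonforage
Title: Simulation and Analysis of Explore-Exploit Behavior in the
    Horizon and Orchard Foraging Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative simulators for two developmental explore-exploit
    paradigms: a two-armed bandit task with forced-choice information
    manipulation and horizon (game length) manipulation, and a patch-foraging
    task in which trees deplete geometrically and travel time sets the
    opportunity cost of leaving. Includes a logistic choice model with an
    information bonus, spatial bias, decision noise, and a choice-repetition
    (habit) bonus; maximum-likelihood fitting with parameter-recovery
    validation; a Marginal Value Theorem solver for optimal patch-leaving
    thresholds with a brute-force simulation oracle; behavioral metrics
    (exploration rate, strategic exploration, habitual responding, reward
    maximization, exit thresholds and deviation from optimal); a synthetic
    cohort generator with questionnaire-based unpredictability scores and
    planted effects on agent parameters; and the statistical pipeline used to
    analyze such studies (covariate-adjusted regressions, trial-level logistic
    mixed models with interactions, estimated marginal effects, bootstrap
    mediation, and optimality t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
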