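Package: actisleep
Title: Actigraphy Sleep Scoring, Sleep-Health Scores and Cognition Association Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for wrist-actigraphy sleep studies
    of cognitive function. Generates epoch-level activity-count cohorts with
    known ground truth, detects nightly rest intervals from activity counts and
    sleep diaries, scores 60-s epochs sleep/wake with the Cole-Kripke weighted
    sum, derives eleven nightly sleep measures with weekly means and
    within-person standard deviations, scores the six RU SATED sleep-health
    dimensions and their 0-12 total, builds cognitive T-scores from normative
    tables, and links sleep summaries to global cognition through five
    association analyses: covariate-adjusted rank (partial Spearman)
    regression, one-component partial least squares with variable importance
    in projection, random-forest variable importance, median regression on
    sleep-health dimensions, and latent-class grouping by finite Gaussian
    mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mclust,
    randomForest,
    quantreg,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
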