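---
title: "Methods: from wrist actigraphy to sleep-health and cognition"
author: "actisleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist actigraphy to sleep-health and cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`actisleep` implements a complete analysis chain for studies that relate
wrist-actigraphy sleep measures to cognitive function, of the kind run in
cohorts of people with HIV (PWH) and demographically similar HIV-negative
controls. The chain is:

1. **Epoch counts** — activity counts accumulated over 15-s epochs on the
   non-dominant wrist, aggregated to 60-s epochs for analysis.
2. **Rest intervals** — one in-bed period per night, anchored on the sleep
   diary and refined by the activity signal.
3. **Sleep/wake scoring** — the Cole–Kripke weighted sum over each 60-s
   epoch of the rest interval.
4. **Nightly measures and weekly summaries** — eleven measures per night;
   per subject, the mean and within-person SD of each over the valid
   nights (22 variables).
5. **Sleep-health construct** — the six RU SATED dimensions
   (satisfaction, alertness, timing, efficiency, duration, regularity),
   each scored 0/1/2 and summed to 0–12.
6. **Cognition** — raw test scores standardized to T-scores
   (mean 50, SD 10) against a normative table, averaged test → domain →
   global.
7. **Association analyses** — five approaches that differ in how they
   treat the correlated 22-variable summary matrix: adjusted rank
   regression, one-component PLS with VIP, random-forest VIM, median
   regression on the dimension scores, and Gaussian-mixture latent
   classes.

Because cohorts of this kind are rarely shareable, the package also ships a
first-class synthetic-cohort generator with known ground truth, which every
downstream stage is tested against.

# Sleep scoring

## Rest-interval detection

For each night the diary bed and wake times anchor a deterministic search:
the in-bed time is the start of the maximal run of at least 5 consecutive
minutes with per-minute counts below 1,000 whose start lies nearest the
diary bed time (within a ±120-min window, configurable); the out-of-bed
time is the nearest run of minutes at or above 1,000. When no qualifying
run exists the diary time is used and the night is flagged
`diary`-anchored. The 1,000 counts/min threshold and the 5-min run rule
are the conventional "abrupt decrease/increase" criteria used when rest
periods are annotated from ActiGraph-style wrist counts; in practice such
annotation is partly manual, so the automated rule here is a deterministic
stand-in and its provenance is recorded per night in the output.

## Cole–Kripke labels

Each 60-s epoch *t* of the rest interval receives

$$D(t) = s \sum_{k=-4}^{+2} w_k\, c(t+k), \qquad
\text{asleep} \iff D(t) < \theta,$$

with defaults $w_{-4..+2} = (404, 598, 326, 441, 408, 508, 350)$,
$s = 10^{-5}$, $\theta = 1$, applied to 60-s aggregated counts and
zero-padded at the series edges. Devices and sites recalibrate these
constants, so all of them are arguments of `coleKripke()`. The five
Webster rescoring rules (short sleep bouts adjacent to long wake rescored
as wake) are implemented but **off** by default. The weighted window makes
the scorer smear state transitions by a few minutes in both directions;
this bias is shared across subjects and does not disturb between-subject
ordering, which is what the association analyses consume.

## Naps

A diary-reported nap is scored only when a ≥5-min run of sub-threshold
activity starts within 30 min of the reported start; the scored bounds are
taken from the activity run. Unaccompanied reports are dropped (and
returned for logging). Naps feed only the alertness dimension; the eleven
nightly measures are computed within the nocturnal rest interval.

# Nightly measures and summaries

Within one scored night: onset is the first sleep epoch, offset the end of
the last; latency = onset − in-bed; duration = total sleep between onset
and offset (h); WASO = wake strictly between onset and offset (min);
maintenance efficiency = 100 × sleep/(offset − onset); awakenings are
maximal wake runs strictly inside the sleep period, summarized by their
count and mean length; the movement index is the percentage of in-bed
epochs with counts above a threshold (default: any count), divided by
hours in bed. Clock times (onset, midpoint, out-of-bed) are carried on a
continuous *hours-since-previous-noon* scale (23:30 → 11.5, 02:00 → 14.0),
which makes means and SDs of bed-time variables well defined without
midnight wrap-around.

Two deliberate conventions:

* **Fragmentation index.** The printed definition in this literature —
  "% of 60-s sleep epochs out of the total number of epochs in the sleep
  period" — is implemented literally by default and then coincides with
  maintenance efficiency. An ActiGraph-style alternative (the proportion
  of immobility bouts lasting one minute) is available via
  `fragmentation = "bouts"`. The package does not take a position on which
  a given study used.
* **Mean awakening length with zero awakenings is 0**, not missing, so the
  22-column summary matrix stays complete for PLS, random forest and the
  mixtures, none of which admit missing cells.

Weekly summaries are the arithmetic mean and the sample (n−1) SD over
valid nights (a population-SD switch exists); SDs are missing below two
valid nights, and a subject enters the analyses only with at least five
valid nights. A night is invalid when its rest interval cannot be
resolved, contains more than 10% device-off time, or has no sleep epoch.

# Sleep health and cognition

The five actigraphy dimensions are scored per night (alertness: no nap
that day; timing: onset strictly before 02:00 **and** out-of-bed strictly
after 04:00; efficiency: maintenance efficiency ≥ 85%; duration: 6–8 h
inclusive; regularity: onset within 30 min of the subject's mean onset)
and banded by the proportion of good nights: ≥ 70% → 2, < 30% → 0,
otherwise 1. The band at exactly 30% scores 1: the printed rule makes
"poor" strictly below 30% and leaves 30% itself ambiguous, which we
resolve in favor of the explicit "less than 30%". Satisfaction combines
the two questionnaire items exactly as printed (both favorable → 2, both
unfavorable → 0, else 1). The total is the sum of the six dimensions,
0–12.

T-scores are affine: $T = 50 + 10\,d\,(x - \mu)/\sigma$ against the
matching normative entry with direction $d = \pm 1$; tests average into
domains and domains into the global score, so an oversampled domain cannot
dominate. The normative table is an input file — the package ships only a
synthetic default (used by the generator) because real norms are
proprietary; the test-to-domain map is likewise a required input.

# Association analyses

All five methods consume the same analysis frame: 22 summaries, dimension
scores and total, global T-score, covariates (age, gender, ethnicity,
education, sleep-medication use, HIV status), complete cases only, with
exclusions recorded.

* **Rank regression** is operationalized as a partial Spearman
  correlation: outcome and predictor are mid-rank transformed and
  residualized on the confounder design (continuous confounders ranked,
  categorical ones as treatment contrasts with the most frequent level as
  reference); the adjusted rho is the correlation of the residuals, with
  Fisher-z confidence intervals using $\mathrm{SE} = 1/\sqrt{n-k-3}$. The
  literature names "rank regression" without fixing an estimator; this
  choice is transparent and testable against a precision-matrix oracle.
  For sleep duration a U-shaped association is accommodated by
  `centeredDuration()`, the absolute deviation from the 7-h median.
* **PLS** fits the standardized outcome on the standardized 22-variable
  block by the NIPALS recursion, one component by default (consistent with
  a single extracted component being the common outcome at these sample
  sizes). VIP is
  $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{aj}/\|w_a\|)^2 /
  \sum_a \mathrm{SSY}_a}$, which obeys $\sum_j \mathrm{VIP}_j^2 = p$ for
  one component — an identity the tests pin at 1e-8.
* **Random forest** (via `randomForest`) uses 27 inputs (22 summaries + 5
  covariates). VIM is the split-wise decrease in residual sum of squares
  averaged over trees — the impurity importance, matching the stated
  definition rather than permutation importance; its known bias toward
  correlated predictor groups is the reason the relative VIM (percent of
  the maximum) is reported alongside, and an out-of-bag
  leave-one-variable-out ΔR² is available (`deltaR2 = TRUE`). The R² used
  is out-of-bag, avoiding refit-on-train optimism.
* **Median regression** (via `quantreg`) contrasts the global T-score
  across good/fair/poor of each dimension, good as reference, dropping
  categories with fewer than five subjects, with xy-bootstrap standard
  errors.
* **Latent classes** are parameterized finite Gaussian mixtures (via
  `mclust`) on the standardized 22-variable block over six covariance
  families (EII, VII, EEI, VVI, EEE, VVV — spherical/diagonal/full,
  equal/varying), selected by BIC, optionally confirmed by the parametric
  bootstrap likelihood-ratio test (999 replicates conventionally; the
  count is an argument). Grouping never sees the outcome; cognition is
  compared across groups afterwards by adjusted median regression.

No multiple-testing correction is applied anywhere, matching the analysis
style this package reproduces; every p-value is reported raw, and users
performing many screens should adjust downstream.

# The synthetic cohort

`simulateCohort()` emulates a 7-day/night wrist-actigraphy study:

* **Nights.** In-bed time is Normal per subject; sleep starts after an
  exponential latency; the sleep period spans a Normal draw; awakenings
  are a Poisson number of exponential-length wake intervals placed by
  stick-breaking; a short exponential terminal wake precedes out-of-bed.
  True measure values are computed from these intervals in continuous
  time, so conservation (latency + sleep + WASO + terminal wake = rest
  interval) holds exactly in the ground truth.
* **Counts.** Negative binomial (dispersion 8) at three levels — asleep 2,
  awake-in-bed 60, daytime 400 per 15-s epoch — chosen so that per-minute
  counts sit far below 1,000 in bed and far above out of bed, making the
  rest-detection contrast realizable, while awake-in-bed minutes score
  wake under the Cole–Kripke weights.
* **Awakening structure.** Three *independent* subject traits: the
  nightly WASO budget (log-normal, median 45 min, bounded 20–150 min),
  the mean awakening length (log-normal, median 4.5 min), and a
  night-to-night variability trait for awakening length. Each night draws
  its mean awakening length from the trait and the awakening count
  compensates (rate ∝ 1/length, bounded 3–60), so nights with longer
  awakenings have proportionally fewer and each night's expected total
  wake time is the subject's budget. This "few long vs many short"
  trade-off is a recognized fragmentation phenotype, and it makes average
  duration, WASO and efficiency population-independent of awakening
  length — the property that lets an effect be planted on awakening
  length *alone*.
* **Cognition.** The global T-score is built as
  $50 + \sum_j \beta_j z(\text{true summary}_j) + \text{covariate
  effects} + \varepsilon$, with the planted coefficient vector a
  configuration item validated against the 22 summary names. Raw test
  scores are back-generated through the synthetic normative table so the
  T-score pipeline reproduces the generated outcome exactly (optional
  per-test scatter exists). Defaults plant −3 T-points per SD on the
  average and the SD of mean awakening length with residual SD 7.
* **Diary.** Bed/wake times are the true ones plus truncated Gaussian
  reporting noise (SD 10 min); naps (afternoon, 20–60 min, probability
  Beta-distributed across subjects) are reported with probability 1.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: circadian phase and its drift, first-night
and weekend effects, non-wear and compliance failure beyond explicit
device-off intervals, device-specific count calibration, daytime activity
structure beyond a single stationary level, and any non-linear or
interaction structure in the sleep-cognition relationship. Recovery results
(e.g. rank correlations above 0.9 between pipeline estimates and truth for
WASO and efficiency at 200 subjects) are statements about this generative
model, not about any particular device or cohort.

# Numerical and design choices

* All stochastic procedures take explicit integer seeds and are exactly
  reproducible; cohort simulation derives independent per-subject seeds
  from the master seed.
* Infeasible night draws (spilling past the next noon, WASO above half
  the sleep span) are resampled up to 25 times before an explicit
  "infeasible profile" error.
* Times are handled timezone-free (UTC) at 15-s/60-s resolution;
  daylight-saving transitions are out of scope.
* The test suite sizes its simulations for a single CPU: 200 subjects for
  pipeline recovery, 20 replicate cohorts of 344 subjects (truth-level,
  without epoch counts) for the method-contrast property, 500-tree
  forests, and 20 replicate mixtures of 300 subjects; these sizes are the
  package's choices for routine verification, and all scale up through
  arguments.
* At n = 344 the Fisher sampling error of a null adjusted rho is about
  0.055, so requiring several near-null estimates to stay within ±0.1
  simultaneously is a statistically tight band; the method-contrast test
  reports how many replicate cohorts satisfy the full conjunction.

# Limitations

The rest-interval heuristic is an automated stand-in for what is, in
practice, partly manual annotation; the Cole–Kripke constants are the
cited 1-min parameterization, not a device-specific recalibration; the
literal fragmentation index duplicates maintenance efficiency (see above);
the "rank regression" estimator is one defensible reading of an
underspecified method name, with the residual-rank construction chosen for
testability; and the mixture family is a superset approximation of
whatever family a given study's software searched. Each of these is
config-exposed precisely so that a study's exact settings can be swapped
in.
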