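#' Cohort simulation configuration
#'
#' Collects everything [simulateCohort()] needs: cohort size, recording
#' length, population distributions of the subject profiles, and the planted
#' sleep-cognition association (which of the 22 true summary variables drive
#' the global cognitive T-score, with what coefficients on the standardized
#' scale).
#'
#' Population model (subject traits, drawn independently unless noted):
#' in-bed time Normal; its night-to-night SD log-normal; sleep-period span
#' Normal with log-normal nightly SD; onset latency mean log-normal; the
#' nightly WASO budget (min), the mean awakening length (min), and the
#' night-to-night awakening-length variability are three independent
#' log-normal traits, with the awakening rate derived as budget / length.
#' The independence of the WASO budget from awakening length reflects the
#' few-long vs many-short awakening trade-off and keeps average duration,
#' WASO and efficiency population-independent of awakening length, so a
#' planted effect on awakening length alone is a well-posed condition.
#'
#' @param nSubjects Number of subjects.
#' @param nDays Recording days per subject (default 7; must be >= 5 so the
#'   5-valid-night inclusion filter is satisfiable).
#' @param epochSeconds Raw epoch length, default 15 s.
#' @param seed Integer seed.
#' @param planted Named numeric vector of planted coefficients (T-score
#'   points per SD) over [summaryVariables()] names.
#' @param noiseSD Residual SD of the global T-score (T points).
#' @param pHIV Probability a subject is a person with HIV.
#' @param population Named list of population hyper-parameters (see source
#'   for the full set; any element supplied overrides the default).
#' @param covariateEffects Named list: additive covariate effects on the
#'   global T-score (`age` per year above 59, `sleep_med`,
#'   `education_college`, `education_university`).
#' @param diaryNoiseMin Diary reporting noise SD (min).
#' @param testNoiseSD SD of per-test T-score scatter around the global
#'   score; 0 (default) makes the two-stage T-score pipeline reproduce the
#'   generated global score exactly.
#' @param start `POSIXct` recording start (noon of day 1).
#' @return A `cohortConfig` list.
#' @export
cohortConfig <- function(nSubjects = 100L,
                         nDays = 7L,
                         epochSeconds = 15L,
                         seed = 1L,
                         planted = c(avg_mean_awakening_length = -3,
                                     sd_mean_awakening_length = -3),
                         noiseSD = 7,
                         pHIV = 344 / 463,
                         population = list(),
                         covariateEffects = list(age = -0.15, sleep_med = -2,
                                                 education_college = 1,
                                                 education_university = 2),
                         diaryNoiseMin = 10,
                         testNoiseSD = 0,
                         start = as.POSIXct("2024-01-01 12:00:00", tz = "UTC")) {
  if (nDays < 5) stop("nDays must be >= 5 so the 5-night inclusion filter is satisfiable")
  if (86400L %% as.integer(epochSeconds) != 0L || 60L %% as.integer(epochSeconds) != 0L) {
    stop("epochSeconds must divide 60")
  }
  bad <- setdiff(names(planted), summaryVariables())
  if (length(bad)) {
    stop("unknown planted summary variable(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(summaryVariables(), collapse = ", "))
  }
  pop <- list(
    mean_onset = c(mean = 11.5, sd = 0.75),
    sd_onset = c(meanlog = log(0.5), sdlog = 0.35),
    mean_sleep_duration = c(mean = 7.3, sd = 0.35),
    sd_duration = c(meanlog = log(0.5), sdlog = 0.35),
    onset_latency_mean = c(meanlog = log(12), sdlog = 0.4),
    waso_budget = c(meanlog = log(45), sdlog = 0.5),
    awakening_length_mean = c(meanlog = log(4.5), sdlog = 0.4),
    awakening_length_night_sd = c(meanlog = log(0.35), sdlog = 0.4),
    nap_prob = c(shape1 = 1.2, shape2 = 4),
    asleep_count_level = 2, awake_count_level = 60,
    daytime_count_level = 400, count_dispersion = 8,
    terminal_wake_mean = 5
  )
  pop[names(population)] <- population
  cfg <- list(
    nSubjects = as.integer(nSubjects), nDays = as.integer(nDays),
    epochSeconds = as.integer(epochSeconds), seed = as.integer(seed),
    planted = planted, noiseSD = noiseSD, pHIV = pHIV, population = pop,
    covariateEffects = covariateEffects, diaryNoiseMin = diaryNoiseMin,
    testNoiseSD = testNoiseSD, start = start
  )
  class(cfg) <- c("cohortConfig", "list")
  cfg
}

#' Default nine-test, five-domain cognitive battery
#'
#' A synthetic normative table and domain map for the cognitive battery used
#' by the simulator: nine tests covering language, attention, processing
#' speed, executive and motor function. The table is synthetic (the study's
#' proprietary norms are not available); `direction = -1` marks a timed test
#' where larger raw scores are worse.
#'
#' @return `defaultNormativeTable()`: `data.frame` with columns `test_id`,
#'   `mean`, `sd`, `direction`. `defaultDomainMap()`: named character vector
#'   mapping test_id to domain.
#' @export
defaultNormativeTable <- function() {
  data.frame(
    test_id = paste0("t0", 1:9),
    mean = c(55, 48, 31, 72, 40, 25, 64, 110, 95),
    sd = c(9, 11, 6, 18, 8, 5, 12, 22, 20),
    direction = c(1, 1, 1, -1, 1, 1, 1, 1, 1)
  )
}

#' @rdname defaultNormativeTable
#' @export
defaultDomainMap <- function() {
  c(t01 = "language", t02 = "attention", t03 = "attention",
    t04 = "processing_speed", t05 = "processing_speed",
    t06 = "executive", t07 = "executive", t08 = "motor", t09 = "motor")
}

.isiLevels <- c("Very dissatisfied", "Dissatisfied", "Moderately satisfied",
                "Satisfied", "Very satisfied")
.promisLevels <- c("Not at all", "A little bit", "Somewhat", "Quite a lot",
                   "Very much")

# Ordinal satisfaction responses from a latent normal score.
.ordinalResponse <- function(latent, labels, cuts = c(-1.2, -0.5, 0.2, 1.0)) {
  labels[findInterval(latent, cuts) + 1L]
}

#' Simulate a full actigraphy cohort with planted cognition association
#'
#' Draws subject profiles from the population hyper-parameters, simulates
#' each subject's epoch series and diary with [simulateSubject()], and
#' generates phenotypes: covariates, two ordinal sleep-satisfaction items,
#' and raw cognitive test scores. The global cognitive T-score is built as
#' `50 + sum_j beta_j * z(true summary_j) + covariate effects + Normal(0,
#' noiseSD)`; raw test scores are back-generated from it through the
#' normative table so that the T-score pipeline ([tScore()], [globalT()])
#' reproduces the generated score (exactly when `testNoiseSD = 0`).
#'
#' @param config A [cohortConfig()].
#' @param epochData Generate the epoch-level activity counts (default).
#'   `FALSE` produces a bundle whose epoch series are all-zero
#'   placeholders, for truth-level studies of the generator and the
#'   association methods that do not touch the counts (see [truthFrame()]).
#' @return A [CohortBundle-class].
#' @examples
#' cb <- simulateCohort(cohortConfig(nSubjects = 4, seed = 7))
#' cb
#' @export
simulateCohort <- function(config, epochData = TRUE) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  n <- config$nSubjects
  pop <- config$population
  ids <- sprintf("s%04d", seq_len(n))

  rln <- function(par, n) stats::rlnorm(n, par["meanlog"], par["sdlog"])
  hiv <- stats::rbinom(n, 1, config$pHIV)
  age <- round(pmin(85, pmax(30, stats::rnorm(n, ifelse(hiv == 1, 57, 61), 8))))
  gender <- ifelse(stats::runif(n) < ifelse(hiv == 1, 0.86, 0.67), "male", "female")
  ethnicity <- sample(c("white", "black", "other"), n, TRUE, c(0.85, 0.08, 0.07))
  education <- sample(c("secondary", "college", "university"), n, TRUE,
                      c(0.3, 0.3, 0.4))
  sleep_med <- stats::rbinom(n, 1, ifelse(hiv == 1, 0.09, 0.02))

  # bound the nightly WASO budget: the ceiling keeps even tail subjects able
  # to realize nights with WASO below half the sleep span, the floor keeps
  # the implied awakening rate high enough that zero-awakening nights stay
  # rare (their mean-length-0 convention would otherwise couple the
  # awakening-length summaries to the budget)
  wasoBudget <- pmin(150, pmax(20, rln(pop$waso_budget, n)))
  awkLen <- rln(pop$awakening_length_mean, n)
  profiles <- lapply(seq_len(n), function(i) {
    subjectProfile(
      subject_id = ids[i],
      mean_onset = stats::rnorm(1, pop$mean_onset["mean"], pop$mean_onset["sd"]),
      sd_onset = rln(pop$sd_onset, 1),
      mean_sleep_duration = stats::rnorm(1, pop$mean_sleep_duration["mean"],
                                         pop$mean_sleep_duration["sd"]),
      sd_duration = rln(pop$sd_duration, 1),
      onset_latency_mean = rln(pop$onset_latency_mean, 1),
      awakening_rate = min(60, max(3, wasoBudget[i] / awkLen[i])),
      awakening_length_mean = awkLen[i],
      awakening_length_night_sd = rln(pop$awakening_length_night_sd, 1),
      nap_prob = stats::rbeta(1, pop$nap_prob["shape1"], pop$nap_prob["shape2"]),
      asleep_count_level = pop$asleep_count_level,
      awake_count_level = pop$awake_count_level,
      daytime_count_level = pop$daytime_count_level,
      count_dispersion = pop$count_dispersion,
      terminal_wake_mean = pop$terminal_wake_mean,
      hiv_status = hiv[i], age = age[i], gender = gender[i],
      ethnicity = ethnicity[i], education = education[i], sleep_med = sleep_med[i]
    )
  })
  subSeeds <- sample.int(.Machine$integer.max - 1L, n)

  sims <- lapply(seq_len(n), function(i) {
    simulateSubject(profiles[[i]], config$nDays, subSeeds[i],
                    epochSeconds = config$epochSeconds, start = config$start,
                    diaryNoiseMin = config$diaryNoiseMin,
                    generateCounts = epochData)
  })
  epochs <- stats::setNames(lapply(sims, `[[`, "epochs"), ids)
  diary <- do.call(rbind, lapply(sims, `[[`, "diary"))
  truthNights <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(diary) <- rownames(truthNights) <- NULL
  truthSum <- truthSummaries(truthNights)

  # planted outcome on the standardized true summaries
  beta <- config$planted
  lin <- rep(0, n)
  if (length(beta)) {
    Z <- scale(as.matrix(truthSum[match(ids, truthSum$subject_id), names(beta),
                                  drop = FALSE]))
    lin <- drop(Z %*% beta)
  }
  ce <- config$covariateEffects
  covEff <- ce$age * (age - 59) + ce$sleep_med * sleep_med +
    ce$education_college * (education == "college") +
    ce$education_university * (education == "university")
  globalT <- 50 + lin + covEff + stats::rnorm(n, 0, config$noiseSD)

  # satisfaction items: latent partly tracks true WASO and onset variability
  zw <- drop(scale(truthSum$avg_waso[match(ids, truthSum$subject_id)]))
  zo <- drop(scale(truthSum$sd_onset[match(ids, truthSum$subject_id)]))
  latent <- -0.3 * zw - 0.2 * zo + stats::rnorm(n, 0, 0.9)
  isi <- .ordinalResponse(latent, .isiLevels)
  promis <- .ordinalResponse(latent + stats::rnorm(n, 0, 0.5), .promisLevels)

  # raw cognitive tests back-generated from the target global T-score
  norm <- defaultNormativeTable()
  testT <- matrix(rep(globalT, each = nrow(norm)), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, norm$test_id))
  if (config$testNoiseSD > 0) {
    testT <- testT + matrix(stats::rnorm(n * nrow(norm), 0, config$testNoiseSD),
                            nrow = n)
  }
  raw <- sweep(sweep(sweep(testT, 2, 50, "-") / 10, 2, norm$direction, "*"),
               2, norm$sd, "*")
  raw <- sweep(raw, 2, norm$mean, "+")
  colnames(raw) <- paste0("raw_", norm$test_id)

  phen <- data.frame(
    subject_id = ids, hiv_status = hiv, age = age, gender = gender,
    ethnicity = ethnicity, education = education, sleep_med = sleep_med,
    isi_satisfaction = isi, promis_satisfaction = promis, raw,
    stringsAsFactors = FALSE
  )
  new("CohortBundle",
    epochs = epochs, diary = diary, phenotypes = phen, normative = norm,
    groundTruth = list(nights = truthNights, summaries = truthSum,
                       planted = beta,
                       global_t = stats::setNames(globalT, ids)),
    config = unclass(config)
  )
}

#' Ground-truth analysis frame for a simulated cohort
#'
#' Assembles the analysis frame directly from the generator's ground truth
#' (true 22 summary variables, generated global T-score, covariates),
#' bypassing the scoring pipeline. Used to validate the association
#' methods against the planted coefficients without the measurement layer.
#'
#' @param bundle A [CohortBundle-class].
#' @return `data.frame` with `subject_id`, the 22 true summaries,
#'   `global_t` and the covariates.
#' @export
truthFrame <- function(bundle) {
  gt <- cohortTruth(bundle)
  phen <- cohortPhenotypes(bundle)
  frame <- merge(gt$summaries,
                 data.frame(subject_id = names(gt$global_t),
                            global_t = unname(gt$global_t)),
                 by = "subject_id")
  frame <- merge(frame,
                 phen[, c("subject_id", "age", "gender", "ethnicity",
                          "education", "sleep_med", "hiv_status")],
                 by = "subject_id")
  rownames(frame) <- NULL
  frame
}
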