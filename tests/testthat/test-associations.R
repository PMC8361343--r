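# Independent oracle for the adjusted rho: partial correlation of the
# ranked outcome and predictor given the confounder design, from the
# inverse correlation (precision) matrix.
precisionPartial <- function(y, x, Z) {
  M <- cbind(rank(y), rank(x), Z)
  P <- solve(stats::cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

test_that("adjusted rho equals the precision-matrix partial correlation", {
  for (seed in 1:5) {
    fr <- randomFrame(150, seed = seed)
    # correlate predictor, outcome and confounder to make adjustment matter
    fr$global_t <- fr$global_t + 0.4 * fr$age + 2 * fr$avg_waso
    Z <- cbind(
      rank(fr$age),
      model.matrix(~gender, fr)[, -1, drop = FALSE],
      model.matrix(~ethnicity, fr)[, -1, drop = FALSE],
      model.matrix(~education, fr)[, -1, drop = FALSE],
      fr$sleep_med
    )
    got <- rankRegression(fr, "avg_waso")
    want <- precisionPartial(fr$global_t, fr$avg_waso, Z)
    expect_equal(got$estimate, want, tolerance = 1e-10)
    expect_true(got$ci_low <= got$estimate && got$estimate <= got$ci_high)
  }
})

test_that("rank regression is exact, monotone-invariant and guards inputs", {
  fr <- randomFrame(80, seed = 3)
  # self-correlation of ranks is exactly 1
  self <- rankRegression(fr, "global_t", confounders = character(0))
  expect_equal(self$estimate, 1)

  # invariant under strictly monotone transforms of predictor and outcome
  a <- rankRegression(fr, "avg_waso")
  frT <- fr
  frT$avg_waso <- exp(frT$avg_waso)
  frT$global_t <- frT$global_t^3
  b <- rankRegression(frT, "avg_waso")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  fr$flat <- 1
  expect_error(rankRegression(fr, "flat"), "zero variance")
  expect_error(rankRegression(fr, "nope"), "unknown predictor")
})

test_that("adjusted rho is near zero under independence", {
  fr <- randomFrame(5000, seed = 10)
  out <- rankRegression(fr, "avg_onset")
  expect_lt(abs(out$estimate), 0.05)
})

test_that("centered duration is the symmetric 7-h deviation", {
  expect_equal(centeredDuration(7), 0)
  expect_equal(centeredDuration(5.5), 1.5)
  expect_equal(centeredDuration(6), centeredDuration(8))
})

test_that("VIP satisfies its normalization identity and finds planted signal", {
  for (seed in 1:4) {
    fr <- randomFrame(120, beta = c(avg_waso = 1.5), noise = 0.5, seed = seed)
    fit <- plsFit(fr)
    expect_equal(sum(fit$vip^2), 22, tolerance = 1e-8)
    expect_equal(names(which.max(fit$vip)), "avg_waso")
    expect_equal(sum(fit$weights[, 1]^2), 1, tolerance = 1e-12)
  }
  # exchangeable predictors: all VIP equal 1
  set.seed(2)
  n <- 200
  z <- rnorm(n)
  fr2 <- randomFrame(n, seed = 2)
  for (v in summaryVariables()) fr2[[v]] <- z + rnorm(n, 0, 1e-6)
  fit2 <- plsFit(fr2)
  expect_equal(unname(fit2$vip), rep(1, 22), tolerance = 1e-3)

  fr3 <- randomFrame(30, seed = 1)
  fr3$avg_waso <- 2
  expect_error(plsFit(fr3), "avg_waso")
})

test_that("one-component PLS agrees with the mixOmics reference", {
  library(mixOmics)
  fr <- randomFrame(100, beta = c(avg_waso = 1, sd_onset = -0.8), seed = 6)
  fit <- plsFit(fr)
  ref <- mixOmics::pls(as.matrix(fr[, summaryVariables()]),
                       fr$global_t, ncomp = 1, scale = TRUE,
                       mode = "regression")
  refVip <- mixOmics::vip(ref)[, 1]
  expect_gt(abs(cor(fit$scores[, 1], ref$variates$X[, 1])), 1 - 1e-8)
  expect_equal(unname(fit$vip[names(refVip)]), unname(refVip),
               tolerance = 1e-6)
})

test_that("random-forest VIM is deterministic and recovers a planted signal", {
  fr <- randomFrame(300, beta = c(sd_waso = 1), noise = 1, seed = 12)
  a <- rfFit(fr, nTrees = 300, mTry = 15, seed = 5)
  b <- rfFit(fr, nTrees = 300, mTry = 15, seed = 5)
  expect_identical(a$vim, b$vim)
  expect_equal(max(a$relativeVIM), 100)
  expect_equal(names(which.max(a$vim)), "sd_waso")
  expect_error(rfFit(fr, mTry = 99), "between 1")

  # leave-one-out delta R2 drops most for the planted variable
  d <- rfFit(fr, nTrees = 150, mTry = 15, seed = 5, deltaR2 = TRUE)
  expect_equal(names(which.max(d$deltaR2)), "sd_waso")
})

test_that("median regression recovers noise-free category shifts", {
  set.seed(4)
  n <- 90
  fr <- randomFrame(n, seed = 4)
  fr$efficiency <- rep(c(2, 1, 0), each = n / 3)
  fr$global_t <- 50 - 3 * (fr$efficiency == 1) - 5 * (fr$efficiency == 0)
  out <- dimensionRegression(fr, "efficiency", confounders = "age",
                             nBoot = 50, seed = 1)
  expect_equal(out$estimate[out$term == "efficiency:fair"], -3, tolerance = 1e-6)
  expect_equal(out$estimate[out$term == "efficiency:poor"], -5, tolerance = 1e-6)

  # identical outcome across categories: zero differences
  fr$global_t <- 50 + fr$age * 0.1
  out0 <- dimensionRegression(fr, "efficiency", confounders = "age",
                              nBoot = 50, seed = 1)
  expect_equal(out0$estimate, c(0, 0), tolerance = 1e-8)

  # a category with four subjects is excluded and flagged
  fr2 <- randomFrame(60, seed = 5)
  fr2$timing <- c(rep(2, 40), rep(1, 16), rep(0, 4))
  fr2$global_t <- rnorm(60) + 50
  out2 <- dimensionRegression(fr2, "timing", confounders = "age",
                              nBoot = 50, seed = 1)
  expect_identical(attr(out2, "excluded_categories"), "poor")
  expect_false(any(grepl("poor", out2$term)))

  fr3 <- randomFrame(30, seed = 6)
  fr3$duration <- 0
  expect_error(dimensionRegression(fr3, "duration"), "reference")
})

test_that("total-score regression delegates to rank regression", {
  fr <- randomFrame(100, seed = 7)
  fr$sleep_health_total <- sample(0:12, 100, TRUE)
  out <- totalScoreRegression(fr)
  ref <- rankRegression(fr, "sleep_health_total")
  expect_equal(out$estimate, ref$estimate)
  expect_equal(out$method, "total_score_rank_regression")
})

test_that("interaction test is symmetric and calibrated", {
  fr <- randomFrame(400, seed = 9)
  fr$global_t <- 50 + (2 * fr$hiv_status - 1) * 3 * fr$avg_waso + rnorm(400)
  p1 <- interactionTest(fr, "avg_waso")
  expect_lt(p1, 0.05)

  # swapping stratum labels leaves the p-value unchanged
  fr2 <- fr
  fr2$hiv_status <- 1 - fr2$hiv_status
  expect_equal(interactionTest(fr2, "avg_waso"), p1, tolerance = 1e-10)

  # under a common slope the rejection rate stays near the nominal level
  ps <- vapply(1:60, function(s) {
    f <- randomFrame(200, seed = 100 + s)
    f$global_t <- 50 + 2 * f$avg_waso + rnorm(200)
    interactionTest(f, "avg_waso")
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)

  fr3 <- randomFrame(50, seed = 11)
  fr3$hiv_status <- 1
  expect_error(interactionTest(fr3, "avg_waso"), "strata")
})

test_that("gaussian-mixture grouping recovers planted structure, blind to outcome", {
  set.seed(33)
  n <- 300
  truth <- rep(1:2, each = n / 2)
  delta <- 6 / sqrt(22)
  X <- matrix(rnorm(n * 22), n, 22) +
    outer(as.numeric(truth == 2), rep(delta, 22))
  colnames(X) <- summaryVariables()
  fr <- randomFrame(n, seed = 33)
  fr[, summaryVariables()] <- X
  fit <- lcaFit(fr, maxGroups = 4, seed = 1)
  expect_equal(fit$nGroups, 2L)
  agree <- max(mean(fit$classification == truth),
               mean(fit$classification == 3 - truth))
  expect_gte(agree, 0.99)
  expect_equal(rowSums(fit$posterior), rep(1, n), tolerance = 1e-12)
  expect_true(all(fit$groupMeans$ci_low <= fit$groupMeans$mean &
                    fit$groupMeans$mean <= fit$groupMeans$ci_high))

  # permuting the outcome never changes the grouping
  fr2 <- fr
  fr2$global_t <- sample(fr2$global_t)
  fit2 <- lcaFit(fr2, maxGroups = 4, seed = 1)
  expect_identical(fit2$classification, fit$classification)

  # a single Gaussian cloud yields one group
  fr3 <- randomFrame(250, seed = 44)
  fit3 <- lcaFit(fr3, maxGroups = 3, seed = 1)
  expect_equal(fit3$nGroups, 1L)

  # bootstrap LRT supports the two-group model over one
  fitB <- lcaFit(fr, maxGroups = 2, nBoot = 20, seed = 1)
  expect_true(is.data.frame(fitB$bootLRT))
  expect_lt(fitB$bootLRT$p[1], 0.1)
})

test_that("the analysis frame applies inclusion and complete-case filters", {
  cb <- simulateCohort(cohortConfig(nSubjects = 15, seed = 19))
  res <- processCohort(cohortEpochs(cb), cohortDiary(cb), cohortPhenotypes(cb))
  fr <- res$frame
  expect_true(all(summaryVariables() %in% names(fr)))
  expect_true(all(c("global_t", "sleep_health_total", "hiv_status") %in% names(fr)))
  expect_false(anyNA(fr[, summaryVariables()]))

  # breaking one subject's summaries excludes it with a reason
  summ <- res$summaries
  summ$avg_waso[2] <- NA
  fr2 <- buildAnalysisFrame(summ, res$dimensions, res$cognition,
                            cohortPhenotypes(cb))
  expect_true(summ$subject_id[2] %in% attr(fr2, "excluded")$subject_id)
  expect_equal(nrow(fr2), nrow(fr) - 1L)
})
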