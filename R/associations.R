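#' Assemble the analysis frame linking sleep summaries to cognition
#'
#' One row per included subject: the 22 weekly sleep summaries, the six
#' sleep-health dimension scores and their total, the global cognitive
#' T-score, and the covariates (age, gender, ethnicity, education, sleep
#' medication use, HIV status). Subjects failing the valid-night inclusion
#' filter or with missing cells among the analysis variables are dropped
#' (complete-case), with the exclusions recorded in the `"excluded"`
#' attribute.
#'
#' @param summaries `data.frame`: `subject_id`, the 22 summary variables,
#'   `n_valid_nights`, `included` ([summarizeSubject()] rows).
#' @param dimensions `data.frame`: `subject_id`, six dimension scores and
#'   `total` ([dimensionScores()] rows).
#' @param cognition `data.frame`: `subject_id`, `global_t`.
#' @param phenotypes `data.frame`: `subject_id` and covariate columns.
#' @return `data.frame` analysis frame; attribute `"excluded"` is a
#'   `data.frame` of dropped subjects and machine-readable reasons.
#' @export
buildAnalysisFrame <- function(summaries, dimensions, cognition, phenotypes) {
  covars <- c("age", "gender", "ethnicity", "education", "sleep_med",
              "hiv_status")
  frame <- merge(summaries, dimensions, by = "subject_id", all.x = TRUE)
  frame <- merge(frame, cognition[, c("subject_id", "global_t")], by = "subject_id",
                 all.x = TRUE)
  frame <- merge(frame, phenotypes[, c("subject_id", covars)], by = "subject_id",
                 all.x = TRUE)
  need <- c(summaryVariables(), "global_t", covars)
  excluded <- data.frame(subject_id = character(), reason = character())
  notIncl <- !frame$included
  if (any(notIncl)) {
    excluded <- rbind(excluded, data.frame(
      subject_id = frame$subject_id[notIncl], reason = "fewer_than_min_valid_nights"))
  }
  frame <- frame[frame$included, , drop = FALSE]
  incomplete <- !stats::complete.cases(frame[, need])
  if (any(incomplete)) {
    excluded <- rbind(excluded, data.frame(
      subject_id = frame$subject_id[incomplete], reason = "missing_analysis_variable"))
  }
  frame <- frame[!incomplete, , drop = FALSE]
  rownames(frame) <- NULL
  names(frame)[names(frame) == "total"] <- "sleep_health_total"
  attr(frame, "excluded") <- excluded
  frame
}

.defaultConfounders <- c("age", "gender", "ethnicity", "education", "sleep_med")

# Confounder design matrix: continuous confounders mid-ranked, categorical
# confounders as treatment contrasts with the most frequent level as
# reference. No intercept column (the caller's lm supplies it).
.confounderMatrix <- function(frame, confounders, rankContinuous = TRUE) {
  if (!length(confounders)) return(NULL)
  cols <- lapply(confounders, function(v) {
    x <- frame[[v]]
    if (is.null(x)) stop("unknown confounder: ", v)
    if (length(unique(x)) < 2L) return(NULL)
    if (is.numeric(x) && length(unique(x)) > 2L) {
      m <- matrix(if (rankContinuous) rank(x) else x, ncol = 1,
                  dimnames = list(NULL, v))
      return(m)
    }
    f <- factor(x)
    if (nlevels(f) < 2L) return(NULL)   # constant confounder carries nothing
    f <- stats::relevel(f, ref = names(which.max(table(f))))
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(v, sub("^f", "_", colnames(mm)))
    mm
  })
  do.call(cbind, cols)
}

# Fisher-z interval and p for a partial correlation with k adjustment
# columns.
.fisherInterval <- function(rho, n, k, level = 0.95) {
  if (n - k - 3 < 1) {
    # too few subjects for the normal approximation
    return(list(ci = c(NA_real_, NA_real_), p = NA_real_))
  }
  se <- 1 / sqrt(n - k - 3)
  z <- atanh(min(1 - 1e-15, max(-1 + 1e-15, rho)))
  crit <- stats::qnorm(1 - (1 - level) / 2)
  list(ci = tanh(z + c(-1, 1) * crit * se),
       p = 2 * stats::pnorm(-abs(z) / se))
}

#' Covariate-adjusted rank (partial Spearman) regression
#'
#' The outcome and the predictor are mid-rank transformed, both are
#' residualized on the confounder design (continuous confounders ranked,
#' categorical confounders as indicator contrasts with the most frequent
#' level as reference), and the adjusted rho is the correlation of the two
#' residual vectors. The confidence interval uses the Fisher z transform
#' with standard error `1 / sqrt(n - k - 3)` where `k` is the number of
#' confounder columns; the p-value is the corresponding two-sided normal
#' test.
#'
#' @param frame Analysis frame ([buildAnalysisFrame()]).
#' @param predictor Name of the predictor column.
#' @param confounders Character vector of confounder columns (default age,
#'   gender, ethnicity, education, sleep medication).
#' @param outcome Outcome column (default `"global_t"`).
#' @param level Confidence level (default 0.95).
#' @return One-row `data.frame`: `method`, `term`, `estimate` (adjusted
#'   rho), `ci_low`, `ci_high`, `p`, `n`.
#' @export
rankRegression <- function(frame, predictor,
                           confounders = .defaultConfounders,
                           outcome = "global_t", level = 0.95) {
  x <- frame[[predictor]]
  y <- frame[[outcome]]
  if (is.null(x)) stop("unknown predictor: ", predictor)
  if (stats::var(x) == 0) stop("predictor '", predictor, "' has zero variance")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  Z <- .confounderMatrix(frame, confounders)
  k <- if (is.null(Z)) 0L else ncol(Z)
  resid2 <- function(r) {
    if (is.null(Z)) r - mean(r) else stats::lm.fit(cbind(1, Z), r)$residuals
  }
  rho <- stats::cor(resid2(ry), resid2(rx))
  fi <- .fisherInterval(rho, n, k, level)
  data.frame(
    method = "rank_regression", term = predictor, estimate = rho,
    ci_low = fi$ci[1], ci_high = fi$ci[2], p = fi$p, n = n
  )
}

#' Median-centered absolute sleep duration
#'
#' `|duration - center|` with the center at the 7-h median sleep duration;
#' used where a U-shaped duration-cognition relationship is expected, so
#' that both short and long sleepers score high.
#'
#' @param avgDuration Average sleep duration (h).
#' @param center Center (h), default 7.
#' @return Absolute deviation from the center (h).
#' @export
centeredDuration <- function(avgDuration, center = 7) {
  abs(avgDuration - center)
}

#' Rank-regression interaction test between HIV status and a sleep measure
#'
#' Fits a linear model on the rank scale with the predictor, the stratum
#' indicator, their product, and the confounder design; returns the
#' two-sided p-value of the product term.
#'
#' @inheritParams rankRegression
#' @param stratum Binary stratification column (default `"hiv_status"`).
#' @return Scalar p-value for the interaction term.
#' @export
interactionTest <- function(frame, predictor,
                            confounders = .defaultConfounders,
                            outcome = "global_t", stratum = "hiv_status") {
  s <- frame[[stratum]]
  if (length(unique(s)) < 2L) {
    stop("both strata of '", stratum, "' must be present")
  }
  rx <- rank(frame[[predictor]])
  ry <- rank(frame[[outcome]])
  sInd <- as.numeric(factor(s)) - 1
  Z <- .confounderMatrix(frame, confounders)
  X <- cbind(x = rx, s = sInd, xs = rx * sInd, Z)
  fit <- stats::lm(ry ~ X)
  ct <- summary(fit)$coefficients
  unname(ct["Xxs", "Pr(>|t|)"])
}

#' One-component partial least-squares regression with VIP
#'
#' Fits PLS regression of the (standardized) global T-score on the
#' standardized sleep summaries by the NIPALS recursion and computes each
#' variable's importance in projection,
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)`,
#' which satisfies `sum_j VIP_j^2 = p` for a one-component fit. The
#' strength of the extracted component is summarized by the Spearman
#' correlation of the component score with the outcome (Fisher-z CI).
#'
#' @param frame Analysis frame.
#' @param predictors Predictor columns (default the 22 sleep summaries).
#' @param outcome Outcome column (default `"global_t"`).
#' @param nComponents Number of components (default 1).
#' @return Object of class `"plsResult"`: `weights` (p x A), `scores`
#'   (n x A component scores), `loadings`, `vip` (named, sorted order
#'   preserved as given), `varianceExplainedX` (% per component),
#'   `cor` (`data.frame` with Spearman rho, CI, p of the first component
#'   score vs the outcome), `signs` (sign of each first-component weight).
#' @export
plsFit <- function(frame, predictors = summaryVariables(),
                   outcome = "global_t", nComponents = 1L) {
  X0 <- as.matrix(frame[, predictors, drop = FALSE])
  sds <- apply(X0, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(predictors[sds == 0], collapse = ", "))
  }
  X <- scale(X0)
  y0 <- frame[[outcome]]
  y <- drop(scale(y0))
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(nComponents)
  W <- P <- matrix(0, p, A, dimnames = list(predictors, NULL))
  Tm <- matrix(0, n, A)
  q <- ssy <- numeric(A)
  Xa <- X; ya <- y
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(Xa %*% w)
    tt <- sum(t_^2)
    pa <- drop(crossprod(Xa, t_)) / tt
    qa <- sum(ya * t_) / tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t_; q[a] <- qa
    ssy[a] <- qa^2 * tt
    Xa <- Xa - tcrossprod(t_, pa)
    ya <- ya - qa * t_
  }
  vip <- sqrt(p * drop((W^2) %*% ssy) / sum(ssy))
  names(vip) <- predictors
  varX <- 100 * colSums(Tm^2) * colSums(P^2) / sum(X^2)
  rho <- stats::cor(Tm[, 1], y0, method = "spearman")
  fi <- .fisherInterval(rho, n, 0)
  res <- list(
    weights = W, loadings = P, scores = Tm, q = q, vip = vip,
    varianceExplainedX = varX,
    cor = data.frame(method = "pls", term = "component_1", estimate = rho,
                     ci_low = fi$ci[1], ci_high = fi$ci[2], p = fi$p, n = n),
    signs = sign(W[, 1]), predictors = predictors, nComponents = A
  )
  class(res) <- "plsResult"
  res
}

#' @export
print.plsResult <- function(x, ...) {
  cat(sprintf("PLS fit: %d component(s), %d predictors\n", x$nComponents,
              length(x$predictors)))
  cat(sprintf("X variance explained by component 1: %.1f%%\n",
              x$varianceExplainedX[1]))
  cat(sprintf("Spearman rho(component score, outcome) = %.3f [%.3f, %.3f]\n",
              x$cor$estimate, x$cor$ci_low, x$cor$ci_high))
  cat("Top variables by VIP:\n")
  print(round(sort(x$vip, decreasing = TRUE)[1:min(5, length(x$vip))], 3))
  invisible(x)
}

#' Random-forest regression of cognition on sleep summaries and covariates
#'
#' Grows a regression forest (bootstrap resampling, `mTry` candidate
#' variables per split) of the global T-score on the 22 sleep summaries
#' plus the five covariates (27 inputs), and reports each variable's
#' importance measure (VIM): the total decrease in the residual sum of
#' squares from splitting on that variable, averaged over all trees.
#' Relative VIM is expressed as a percentage of the largest VIM. Optionally
#' each variable's contribution is also measured as the drop in out-of-bag
#' R-squared when the variable is excluded and the forest refit.
#'
#' @param frame Analysis frame.
#' @param predictors Input columns (default the 22 summaries plus age,
#'   gender, ethnicity, education, sleep medication).
#' @param outcome Outcome column.
#' @param nTrees Number of trees (the source study used 5,000 for people
#'   with HIV and 8,200 for HIV-negative participants).
#' @param mTry Variables tried per split (study: 15 and 5 respectively).
#' @param seed Integer seed; fully determines the forest.
#' @param deltaR2 Also compute leave-one-variable-out out-of-bag
#'   R-squared drops (27 refits; default `FALSE`).
#' @return Object of class `"rfResult"`: `vim` (named), `relativeVIM` (%
#'   of maximum), `oobR2`, optional `deltaR2`, `settings`.
#' @export
rfFit <- function(frame, predictors = c(summaryVariables(), .defaultConfounders),
                  outcome = "global_t", nTrees = 5000L, mTry = 15L,
                  seed = 1L, deltaR2 = FALSE) {
  if (mTry < 1L || mTry > length(predictors)) {
    stop("mTry must be between 1 and the number of input variables (",
         length(predictors), ")")
  }
  x <- frame[, predictors, drop = FALSE]
  x[] <- lapply(x, function(v) if (is.character(v)) factor(v) else v)
  y <- frame[[outcome]]
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x, y, ntree = nTrees, mtry = mTry)
  vim <- drop(rf$importance[, "IncNodePurity"]) / nTrees
  oobR2 <- 1 - mean((y - rf$predicted)^2) / mean((y - mean(y))^2)
  dR2 <- NULL
  if (deltaR2) {
    dR2 <- vapply(predictors, function(v) {
      set.seed(as.integer(seed))
      sub <- randomForest::randomForest(
        x[, setdiff(predictors, v), drop = FALSE], y,
        ntree = nTrees, mtry = min(mTry, length(predictors) - 1L))
      oobR2 - (1 - mean((y - sub$predicted)^2) / mean((y - mean(y))^2))
    }, numeric(1))
  }
  res <- list(
    vim = vim, relativeVIM = 100 * vim / max(vim), oobR2 = oobR2,
    deltaR2 = dR2,
    settings = list(nTrees = nTrees, mTry = mTry, seed = as.integer(seed),
                    n = nrow(frame))
  )
  class(res) <- "rfResult"
  res
}

#' @export
print.rfResult <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, %d variables per split, n = %d\n",
              x$settings$nTrees, x$settings$mTry, x$settings$n))
  cat(sprintf("Out-of-bag R-squared: %.3f\n", x$oobR2))
  cat("Top variables by relative VIM (%):\n")
  print(round(sort(x$relativeVIM, decreasing = TRUE)[1:5], 1))
  invisible(x)
}

# Confounders that actually vary in the data (a constant column would make
# the regression design singular).
.usableConfounders <- function(data, confounders) {
  confounders[vapply(confounders, function(v) {
    length(unique(data[[v]])) > 1L
  }, logical(1))]
}

# Median (tau = 0.5) regression with xy-bootstrap standard errors.
.medianFit <- function(formula, data, nBoot = 200L, seed = 1L) {
  # rq warns about non-unique solutions whenever the outcome is heavily
  # tied, which is routine for degenerate or categorical frames
  fit <- suppressWarnings(
    quantreg::rq(formula, tau = 0.5, data = data, method = "br")
  )
  set.seed(as.integer(seed))
  sm <- suppressWarnings(summary(fit, se = "boot", bsmethod = "xy", R = nBoot))
  stats::coef(sm)
}

#' Median-regression contrast of cognition across one sleep dimension
#'
#' Quantile regression at the median of the global T-score on the
#' dimension's category (good = reference, versus fair and poor) plus
#' confounders. Categories with fewer than `minGroup` subjects are excluded
#' from the contrasts and flagged. Standard errors by xy-pair bootstrap.
#'
#' @param frame Analysis frame (dimension scores in `{0, 1, 2}`).
#' @param dimension Dimension column name (e.g. `"efficiency"`).
#' @param confounders Confounder columns.
#' @param minGroup Minimum subjects per category (default 5).
#' @param nBoot Bootstrap replicates for the standard errors.
#' @param seed Seed for the bootstrap.
#' @return `data.frame` with one row per retained non-reference category:
#'   `method`, `term`, `estimate` (adjusted median difference vs good),
#'   `ci_low`, `ci_high`, `p`, `n`; attribute `"excluded_categories"`.
#' @export
dimensionRegression <- function(frame, dimension,
                                confounders = .defaultConfounders,
                                minGroup = 5L, nBoot = 200L, seed = 1L) {
  sc <- frame[[dimension]]
  if (is.null(sc)) stop("unknown dimension: ", dimension)
  cat3 <- factor(sc, levels = c(2, 1, 0), labels = c("good", "fair", "poor"))
  tab <- table(cat3)
  if (tab["good"] == 0) {
    stop("reference category 'good' absent for dimension '", dimension, "'")
  }
  small <- names(tab)[tab > 0 & tab < minGroup]
  keep <- !(as.character(cat3) %in% small)
  d <- frame[keep, , drop = FALSE]
  d$.cat <- droplevels(cat3[keep])
  empty <- data.frame(method = character(), term = character(),
                      estimate = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(), n = integer())
  if (nlevels(d$.cat) < 2L) {
    # no contrastable category left
    attr(empty, "excluded_categories") <- small
    return(empty)
  }
  confounders <- .usableConfounders(d, confounders)
  f <- stats::as.formula(paste(
    "global_t ~ .cat",
    if (length(confounders)) paste("+", paste(confounders, collapse = " + ")) else ""
  ))
  ct <- .medianFit(f, d, nBoot = nBoot, seed = seed)
  rows <- grep("^\\.cat", rownames(ct))
  out <- if (length(rows)) {
    est <- ct[rows, "Value"]; se <- ct[rows, "Std. Error"]
    data.frame(
      method = "dimension_median_regression",
      term = paste0(dimension, ":", sub("^\\.cat", "", rownames(ct)[rows])),
      estimate = unname(est),
      ci_low = unname(est - stats::qnorm(0.975) * se),
      ci_high = unname(est + stats::qnorm(0.975) * se),
      p = unname(ct[rows, "Pr(>|t|)"]),
      n = nrow(d)
    )
  } else {
    empty
  }
  attr(out, "excluded_categories") <- small
  out
}

#' Rank regression of cognition on the total sleep-health score
#'
#' Delegates to [rankRegression()] with the 0-12 total sleep-health score
#' as the predictor.
#'
#' @inheritParams rankRegression
#' @export
totalScoreRegression <- function(frame, confounders = .defaultConfounders,
                                 outcome = "global_t") {
  out <- rankRegression(frame, "sleep_health_total", confounders, outcome)
  out$method <- "total_score_rank_regression"
  out
}

#' Latent-class grouping of sleep profiles by finite Gaussian mixtures
#'
#' Fits parameterized finite Gaussian mixture models to the standardized
#' 22-variable sleep-summary matrix for 1..`maxGroups` components over a
#' family of covariance parameterizations (spherical equal/varying,
#' diagonal equal/varying, full shared/varying), selects the model by BIC,
#' optionally runs the parametric bootstrap likelihood-ratio test of K vs
#' K-1 groups, profiles the groups (per-variable means with
#' normal-approximation 95% CIs on the original scale), and contrasts the
#' global T-score between groups by confounder-adjusted median regression.
#' Grouping uses the sleep variables only, never the outcome.
#'
#' @param frame Analysis frame.
#' @param predictors Columns to cluster on (default the 22 summaries).
#' @param maxGroups Largest number of groups considered (default 5).
#' @param nBoot Bootstrap LRT replicates (0 skips the test; the
#'   conventional choice is 999).
#' @param seed Seed for mixture initialization and bootstrap.
#' @param confounders Confounders for the outcome contrast.
#' @param outcome Outcome column.
#' @param modelNames mclust covariance parameterizations searched.
#' @return Object of class `"lcaResult"`: `nGroups`, `modelName`,
#'   `classification`, `posterior` (rows sum to 1), `bic` (full BIC
#'   table), `bootLRT` (`data.frame` or `NULL`), `groupMeans` (long
#'   `data.frame`: group, variable, mean, ci_low, ci_high), `contrast`
#'   (median-regression rows vs group 1), `n`.
#' @export
lcaFit <- function(frame, predictors = summaryVariables(), maxGroups = 5L,
                   nBoot = 0L, seed = 1L,
                   confounders = .defaultConfounders,
                   outcome = "global_t",
                   modelNames = c("EII", "VII", "EEI", "VVI", "EEE", "VVV")) {
  X <- scale(as.matrix(frame[, predictors, drop = FALSE]))
  set.seed(as.integer(seed))
  bic <- mclust::mclustBIC(X, G = 1:maxGroups, modelNames = modelNames,
                           verbose = FALSE)
  fit <- mclust::Mclust(X, x = bic, verbose = FALSE)
  if (is.null(fit)) stop("no mixture model could be fitted")
  cl <- fit$classification
  post <- fit$z
  if (is.null(post)) post <- matrix(1, nrow(X), 1)

  bootLRT <- NULL
  if (nBoot > 0 && fit$G > 1) {
    set.seed(as.integer(seed))
    lrt <- try(mclust::mclustBootstrapLRT(X, modelName = fit$modelName,
                                          nboot = nBoot, maxG = fit$G,
                                          verbose = FALSE), silent = TRUE)
    if (!inherits(lrt, "try-error")) {
      bootLRT <- data.frame(G = seq_along(lrt$p.value) + 1L, p = lrt$p.value)
    }
  }

  Xorig <- as.matrix(frame[, predictors, drop = FALSE])
  gm <- do.call(rbind, lapply(seq_len(fit$G), function(g) {
    idx <- which(cl == g)
    mu <- colMeans(Xorig[idx, , drop = FALSE])
    se <- apply(Xorig[idx, , drop = FALSE], 2, stats::sd) / sqrt(length(idx))
    data.frame(group = g, variable = predictors, mean = unname(mu),
               ci_low = unname(mu - stats::qnorm(0.975) * se),
               ci_high = unname(mu + stats::qnorm(0.975) * se),
               n = length(idx))
  }))

  contrast <- NULL
  if (fit$G > 1) {
    d <- frame
    d$.grp <- factor(cl)
    confounders <- .usableConfounders(d, confounders)
    f <- stats::as.formula(paste(
      outcome, "~ .grp",
      if (length(confounders)) paste("+", paste(confounders, collapse = " + ")) else ""
    ))
    ct <- tryCatch(.medianFit(f, d, seed = seed), error = function(e) NULL)
    if (!is.null(ct)) {
      rows <- grep("^\\.grp", rownames(ct))
      est <- ct[rows, "Value"]; se <- ct[rows, "Std. Error"]
      contrast <- data.frame(
        method = "lca_median_regression",
        term = paste0("group", sub("^\\.grp", "", rownames(ct)[rows]), "_vs_group1"),
        estimate = unname(est),
        ci_low = unname(est - stats::qnorm(0.975) * se),
        ci_high = unname(est + stats::qnorm(0.975) * se),
        p = unname(ct[rows, "Pr(>|t|)"]),
        n = nrow(d)
      )
    }
  }
  res <- list(
    nGroups = fit$G, modelName = fit$modelName, classification = cl,
    posterior = post, bic = fit$BIC, bootLRT = bootLRT, groupMeans = gm,
    contrast = contrast, n = nrow(X),
    settings = list(maxGroups = maxGroups, nBoot = nBoot, seed = seed,
                    modelNames = modelNames)
  )
  class(res) <- "lcaResult"
  res
}

#' @export
print.lcaResult <- function(x, ...) {
  cat(sprintf("Gaussian-mixture latent classes: %d group(s), model %s, n = %d\n",
              x$nGroups, x$modelName, x$n))
  print(table(x$classification))
  if (!is.null(x$contrast)) {
    cat("Adjusted median global T-score differences vs group 1:\n")
    print(x$contrast[, c("term", "estimate", "ci_low", "ci_high", "p")])
  }
  invisible(x)
}
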