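#' Nightly good/bad flags for five actigraphy sleep-health dimensions
#'
#' Applies the per-night "good" criteria of the RU SATED construct to one
#' scored night: alertness (0 naps that day), timing (sleep onset strictly
#' before 02:00 and out-of-bed time strictly after 04:00), efficiency
#' (maintenance efficiency at least 85%), duration (sleep duration between
#' 6 and 8 h inclusive), regularity (onset within 30 min of the subject's
#' mean onset over all scored nights). Clock comparisons use the
#' hours-since-noon scale (02:00 = 14.0, 04:00 = 16.0).
#'
#' @param night One-row `data.frame` of nightly measures
#'   ([computeNightly()]).
#' @param napsThatDay Number of scored naps on the night's day.
#' @param subjectMeanOnset Subject's mean sleep onset (hours since noon)
#'   over all scored nights.
#' @return Named logical vector: `alertness`, `timing`, `efficiency`,
#'   `duration`, `regularity`.
#' @export
nightDimensionFlags <- function(night, napsThatDay, subjectMeanOnset) {
  c(
    alertness = napsThatDay == 0,
    timing = night$onset < 14.0 && night$out_of_bed > 16.0,
    efficiency = night$maintenance_efficiency >= 85,
    duration = night$duration >= 6 && night$duration <= 8,
    regularity = abs(night$onset - subjectMeanOnset) <= 0.5
  )
}

#' Score one sleep-health dimension from its proportion of good nights
#'
#' 2 ("good") for at least 70% of recorded nights good, 0 ("poor") for less
#' than 30%, 1 ("fair") otherwise (the fair band is closed at 30%).
#'
#' @param propGood Proportion of good nights in `[0, 1]`.
#' @return Integer score in `{0, 1, 2}`.
#' @examples
#' scoreDimension(5 / 7)  # 2
#' scoreDimension(0.30)   # 1
#' @export
scoreDimension <- function(propGood) {
  if (is.na(propGood) || propGood < 0 || propGood > 1) {
    stop("propGood must be a proportion in [0, 1]")
  }
  if (propGood >= 0.70) 2L else if (propGood < 0.30) 0L else 1L
}

#' Score the satisfaction dimension from the two questionnaire items
#'
#' 2 ("good") when answering "Very satisfied" or "Moderately satisfied" to
#' the sleep-pattern satisfaction item and "Quite a lot" or "Very much" to
#' the "I was satisfied with my sleep" item; 0 ("poor") when answering
#' "Dissatisfied" or "Very dissatisfied" and "Not at all" or "A little
#' bit"; 1 ("fair") in all other circumstances.
#'
#' @param isiItem Response to "How satisfied/dissatisfied are you with your
#'   current sleep pattern?" (one of "Very satisfied", "Satisfied",
#'   "Moderately satisfied", "Dissatisfied", "Very dissatisfied").
#' @param promisItem Response to "I was satisfied with my sleep" (one of
#'   "Not at all", "A little bit", "Somewhat", "Quite a lot", "Very much").
#' @return Integer score in `{0, 1, 2}`.
#' @export
scoreSatisfaction <- function(isiItem, promisItem) {
  if (!isiItem %in% .isiLevels) {
    stop("unknown satisfaction response: '", isiItem, "'")
  }
  if (!promisItem %in% .promisLevels) {
    stop("unknown satisfaction response: '", promisItem, "'")
  }
  good <- isiItem %in% c("Very satisfied", "Moderately satisfied") &&
    promisItem %in% c("Quite a lot", "Very much")
  poor <- isiItem %in% c("Dissatisfied", "Very dissatisfied") &&
    promisItem %in% c("Not at all", "A little bit")
  if (good) 2L else if (poor) 0L else 1L
}

#' Total sleep-health score
#'
#' Sum of the six dimension scores; ranges 0-12, higher is better.
#'
#' @param scores Named numeric/integer vector or one-row data.frame with
#'   elements `satisfaction`, `alertness`, `timing`, `efficiency`,
#'   `duration`, `regularity`, each in `{0, 1, 2}`.
#' @return Integer total in `[0, 12]`.
#' @export
totalSleepHealth <- function(scores) {
  dims <- c("satisfaction", "alertness", "timing", "efficiency", "duration",
            "regularity")
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  missing <- setdiff(dims, names(scores))
  if (length(missing)) {
    stop("missing dimension score(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.integer(scores[dims])
  if (anyNA(vals) || any(vals < 0L | vals > 2L)) {
    stop("dimension scores must be integers in {0, 1, 2}")
  }
  sum(vals)
}

#' Six RU SATED dimension scores and total for one subject
#'
#' Combines a subject's scored nights, daily nap counts and the two
#' satisfaction questionnaire items into the six dimension scores (0/1/2)
#' and their 0-12 total. The denominator for each actigraphy dimension is
#' the subject's valid scored nights.
#'
#' @param nightly `data.frame` of nightly measures for one subject
#'   ([computeNightly()] rows with `valid` column).
#' @param naps `data.frame` with columns `night`, `n_naps`.
#' @param isiItem,promisItem Satisfaction questionnaire responses
#'   ([scoreSatisfaction()]).
#' @return One-row `data.frame`: the six dimension scores, `total`, and the
#'   per-dimension proportions of good nights (`prop_` columns).
#' @export
dimensionScores <- function(nightly, naps, isiItem, promisItem) {
  v <- nightly[which(nightly$valid), , drop = FALSE]
  if (!nrow(v)) stop("no valid scored nights; dimension scores undefined")
  meanOnset <- mean(v$onset)
  napCount <- naps$n_naps[match(v$night, naps$night)]
  napCount[is.na(napCount)] <- 0L
  flags <- t(vapply(seq_len(nrow(v)), function(i) {
    nightDimensionFlags(v[i, , drop = FALSE], napCount[i], meanOnset)
  }, logical(5)))
  props <- colMeans(flags)
  out <- data.frame(
    satisfaction = scoreSatisfaction(isiItem, promisItem),
    alertness = scoreDimension(props["alertness"]),
    timing = scoreDimension(props["timing"]),
    efficiency = scoreDimension(props["efficiency"]),
    duration = scoreDimension(props["duration"]),
    regularity = scoreDimension(props["regularity"])
  )
  out$total <- totalSleepHealth(out)
  for (d in names(props)) out[[paste0("prop_", d)]] <- unname(props[d])
  out
}
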