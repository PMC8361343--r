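#' EpochSeries: a gap-free activity-count series for one subject
#'
#' Container for wrist-actigraphy activity counts accumulated over fixed
#' epochs (15 s as exported by the device, 60 s after [aggregateEpochs()]).
#' The series is gap-free by construction: epoch start times are
#' `start + (seq_len(n) - 1) * epochSeconds`.
#'
#' @slot subjectID Character scalar subject identifier.
#' @slot start `POSIXct` start time of the first epoch.
#' @slot epochSeconds Integer epoch length in seconds.
#' @slot counts Numeric vector of non-negative activity counts (NA marks
#'   diary-reported device-off epochs).
#'
#' @seealso [epochSeries()], [aggregateEpochs()]
#' @export
setClass("EpochSeries",
  representation(
    subjectID = "character",
    start = "POSIXct",
    epochSeconds = "integer",
    counts = "numeric"
  )
)

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L || is.na(object@subjectID)) {
    msg <- c(msg, "subjectID must be a single non-missing string")
  }
  if (length(object@start) != 1L) msg <- c(msg, "start must be a single POSIXct")
  if (length(object@epochSeconds) != 1L || object@epochSeconds <= 0L) {
    msg <- c(msg, "epochSeconds must be a single positive integer")
  }
  if (length(object@counts) < 1L) msg <- c(msg, "counts must be non-empty")
  if (any(object@counts < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSeries
#'
#' @param subjectID Subject identifier.
#' @param start `POSIXct` start of the first epoch.
#' @param epochSeconds Epoch length in seconds.
#' @param counts Non-negative activity counts, one per epoch.
#' @return An [EpochSeries-class] object.
#' @examples
#' es <- epochSeries("s1", as.POSIXct("2024-01-01 12:00:00", tz = "UTC"), 15,
#'                   c(10, 0, 5, 0))
#' nEpochs(es)
#' @export
epochSeries <- function(subjectID, start, epochSeconds, counts) {
  new("EpochSeries",
    subjectID = as.character(subjectID),
    start = as.POSIXct(start),
    epochSeconds = as.integer(epochSeconds),
    counts = as.numeric(counts)
  )
}

#' SleepWakeSeries: scored 60-s epochs within one rest interval
#'
#' Output of [coleKripke()]: one 60-s epoch per minute of the rest interval,
#' each carrying its activity count, the weighted-sum score D and the
#' sleep/wake label (`asleep` is `TRUE` iff `D < threshold`, possibly
#' modified by Webster rescoring).
#'
#' @slot subjectID Character subject identifier.
#' @slot night Integer night index.
#' @slot start `POSIXct` start of the first scored epoch.
#' @slot counts Numeric per-minute activity counts.
#' @slot scores Numeric Cole-Kripke D per epoch.
#' @slot asleep Logical label per epoch.
#' @export
setClass("SleepWakeSeries",
  representation(
    subjectID = "character",
    night = "integer",
    start = "POSIXct",
    counts = "numeric",
    scores = "numeric",
    asleep = "logical"
  )
)

setValidity("SleepWakeSeries", function(object) {
  n <- length(object@asleep)
  if (length(object@scores) != n || length(object@counts) != n) {
    return("counts, scores and asleep must have equal length")
  }
  if (anyNA(object@asleep)) return("every epoch must carry a sleep/wake label")
  TRUE
})

#' CohortBundle: a simulated actigraphy cohort with ground truth
#'
#' Everything [simulateCohort()] produces: per-subject epoch series, sleep
#' diaries, phenotypes (covariates, questionnaire items, raw cognitive test
#' scores), the normative table used to back-generate the test scores, and
#' the generator's ground truth (true nightly intervals, true summary
#' variables, planted coefficients).
#'
#' @slot epochs Named list of [EpochSeries-class], one per subject.
#' @slot diary `data.frame` of nightly bed/wake times and naps.
#' @slot phenotypes `data.frame` of covariates, questionnaire responses and
#'   raw cognitive test scores (one row per subject).
#' @slot normative `data.frame` normative table (test_id, mean, sd, direction).
#' @slot groundTruth List with elements `nights`, `summaries`, `planted`,
#'   `global_t`.
#' @slot config List: the [cohortConfig()] used.
#' @export
setClass("CohortBundle",
  representation(
    epochs = "list",
    diary = "data.frame",
    phenotypes = "data.frame",
    normative = "data.frame",
    groundTruth = "list",
    config = "list"
  )
)

setValidity("CohortBundle", function(object) {
  if (length(object@epochs) &&
      !all(vapply(object@epochs, is, logical(1), "EpochSeries"))) {
    return("epochs must be a list of EpochSeries")
  }
  TRUE
})
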