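#' @name accessors
#' @title Accessors for actisleep S4 containers
#' @param object An [EpochSeries-class], [SleepWakeSeries-class] or
#'   [CohortBundle-class] object.
#' @return The slot content (see details of each generic).
NULL

#' @describeIn accessors Subject identifier.
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @describeIn accessors Epoch length in seconds.
#' @export
setGeneric("epochSeconds", function(object) standardGeneric("epochSeconds"))

#' @describeIn accessors Activity counts.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @describeIn accessors Number of epochs.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @describeIn accessors `POSIXct` start times of every epoch.
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @describeIn accessors Sleep/wake labels (`TRUE` = asleep).
#' @export
setGeneric("asleep", function(object) standardGeneric("asleep"))

#' @describeIn accessors Cole-Kripke scores D.
#' @export
setGeneric("ckScores", function(object) standardGeneric("ckScores"))

#' Aggregate an epoch series to a coarser epoch length
#'
#' Counts are summed within consecutive non-overlapping windows of
#' `targetSeconds`; a trailing partial window is dropped. Windows containing
#' any device-off (`NA`) epoch are `NA`.
#'
#' @param object An [EpochSeries-class].
#' @param targetSeconds Target epoch length; must be a multiple of the
#'   current epoch length.
#' @return An [EpochSeries-class] at the coarser resolution.
#' @examples
#' es <- epochSeries("s1", as.POSIXct("2024-01-01 12:00:00", tz = "UTC"), 15,
#'                   c(10, 0, 5, 0))
#' counts(aggregateEpochs(es, 60))  # 15
#' @export
setGeneric("aggregateEpochs", function(object, targetSeconds) {
  standardGeneric("aggregateEpochs")
})
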