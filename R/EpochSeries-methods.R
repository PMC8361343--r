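#' @rdname accessors
#' @aliases subjectID,EpochSeries-method
setMethod("subjectID", "EpochSeries", function(object) object@subjectID)

#' @rdname accessors
#' @aliases epochSeconds,EpochSeries-method
setMethod("epochSeconds", "EpochSeries", function(object) object@epochSeconds)

#' @rdname accessors
#' @aliases counts,EpochSeries-method
setMethod("counts", "EpochSeries", function(object) object@counts)

#' @rdname accessors
#' @aliases nEpochs,EpochSeries-method
setMethod("nEpochs", "EpochSeries", function(object) length(object@counts))

#' @rdname accessors
#' @aliases epochTimes,EpochSeries-method
setMethod("epochTimes", "EpochSeries", function(object) {
  object@start + (seq_along(object@counts) - 1L) * as.numeric(object@epochSeconds)
})

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@counts)
  span <- n * as.numeric(object@epochSeconds) / 3600
  cat(sprintf(
    "EpochSeries '%s': %d epochs of %d s (%.1f h), %d device-off\n",
    object@subjectID, n, object@epochSeconds, span, sum(is.na(object@counts))
  ))
})

#' @rdname aggregateEpochs
#' @aliases aggregateEpochs,EpochSeries-method
setMethod("aggregateEpochs", "EpochSeries", function(object, targetSeconds) {
  targetSeconds <- as.integer(targetSeconds)
  k <- targetSeconds %/% object@epochSeconds
  if (k < 1L || targetSeconds %% object@epochSeconds != 0L) {
    stop("targetSeconds (", targetSeconds, ") must be a multiple of the ",
         "epoch length (", object@epochSeconds, " s)")
  }
  if (k == 1L) return(object)
  nOut <- length(object@counts) %/% k
  if (nOut < 1L) stop("series shorter than one target window")
  m <- matrix(object@counts[seq_len(nOut * k)], nrow = k)
  new("EpochSeries",
    subjectID = object@subjectID,
    start = object@start,
    epochSeconds = targetSeconds,
    counts = colSums(m)
  )
})

#' @rdname accessors
#' @aliases subjectID,SleepWakeSeries-method
setMethod("subjectID", "SleepWakeSeries", function(object) object@subjectID)

#' @rdname accessors
#' @aliases counts,SleepWakeSeries-method
setMethod("counts", "SleepWakeSeries", function(object) object@counts)

#' @rdname accessors
#' @aliases nEpochs,SleepWakeSeries-method
setMethod("nEpochs", "SleepWakeSeries", function(object) length(object@asleep))

#' @rdname accessors
#' @aliases epochTimes,SleepWakeSeries-method
setMethod("epochTimes", "SleepWakeSeries", function(object) {
  object@start + (seq_along(object@asleep) - 1L) * 60
})

#' @rdname accessors
#' @aliases asleep,SleepWakeSeries-method
setMethod("asleep", "SleepWakeSeries", function(object) object@asleep)

#' @rdname accessors
#' @aliases ckScores,SleepWakeSeries-method
setMethod("ckScores", "SleepWakeSeries", function(object) object@scores)

setMethod("show", "SleepWakeSeries", function(object) {
  cat(sprintf(
    "SleepWakeSeries '%s' night %d: %d min in bed, %d min scored asleep\n",
    object@subjectID, object@night, length(object@asleep), sum(object@asleep)
  ))
})

setMethod("show", "CohortBundle", function(object) {
  cat(sprintf(
    "CohortBundle: %d subjects, %d diary nights, %d phenotype rows\n",
    length(object@epochs), nrow(object@diary), nrow(object@phenotypes)
  ))
  if (length(object@groundTruth$planted)) {
    cat("planted coefficients:\n")
    print(object@groundTruth$planted)
  }
})

#' @name CohortBundle-accessors
#' @title Extract components of a CohortBundle
#' @param object A [CohortBundle-class].
#' @return `cohortEpochs()` the named list of [EpochSeries-class];
#'   `cohortDiary()` the diary `data.frame`; `cohortPhenotypes()` the
#'   phenotype `data.frame`; `cohortTruth()` the ground-truth list;
#'   `cohortNormative()` the normative table.
NULL

#' @rdname CohortBundle-accessors
#' @export
cohortEpochs <- function(object) object@epochs

#' @rdname CohortBundle-accessors
#' @export
cohortDiary <- function(object) object@diary

#' @rdname CohortBundle-accessors
#' @export
cohortPhenotypes <- function(object) object@phenotypes

#' @rdname CohortBundle-accessors
#' @export
cohortTruth <- function(object) object@groundTruth

#' @rdname CohortBundle-accessors
#' @export
cohortNormative <- function(object) object@normative
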