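#' Default Cole-Kripke parameterization for 60-s epochs
#'
#' Seven weights applied to the four preceding, current, and two following
#' 60-s epoch counts, a common scale factor, and the wake threshold:
#' an epoch is scored asleep iff
#' `D = scale * sum(w[k] * count[t + k]) < threshold`, k = -4..+2.
#' All three are exposed so device-specific recalibrations can be swapped in.
#'
#' @return Named list with `weights` (length 7, named `w-4`..`w+2`),
#'   `scale` and `threshold`.
#' @export
coleKripkeDefaults <- function() {
  list(
    weights = stats::setNames(c(404, 598, 326, 441, 408, 508, 350),
                              c("w-4", "w-3", "w-2", "w-1", "w0", "w+1", "w+2")),
    scale = 0.00001,
    threshold = 1
  )
}

# Start indices of maximal runs (length >= minRun) of TRUE in a logical
# vector; NA counts break runs.
.runStarts <- function(ok, minRun) {
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths >= minRun]
}

#' Detect the nightly rest interval from counts and the diary
#'
#' Anchored on the diary bed and wake times, the in-bed time is placed at
#' the start of the maximal run of at least `minRunMinutes` consecutive
#' minutes with per-minute counts below `restThreshold` whose start is
#' nearest the diary bed time (within `windowMinutes`); the out-of-bed time
#' at the start of the nearest qualifying run of minutes at or above the
#' threshold around the diary wake time. When no qualifying run exists the
#' diary time itself is used and flagged `diary`.
#'
#' @param series60 [EpochSeries-class] at 60-s epochs for the subject.
#' @param diaryBed,diaryWake `POSIXct` diary bed and wake times.
#' @param windowMinutes Search half-window around each diary time (min).
#' @param restThreshold Counts-per-minute cutoff separating rest from
#'   activity (default 1000).
#' @param minRunMinutes Minimum qualifying run length (min, default 5).
#' @param night Night index recorded in the output.
#' @return One-row `data.frame`: `night`, `in_bed`, `out_of_bed` (POSIXct),
#'   `source_in`, `source_out` (`"activity"` or `"diary"`).
#' @export
detectRestInterval <- function(series60, diaryBed, diaryWake,
                               windowMinutes = 120, restThreshold = 1000,
                               minRunMinutes = 5, night = 1L) {
  if (epochSeconds(series60) != 60L) {
    stop("detectRestInterval expects a 60-s aggregated series")
  }
  cnt <- counts(series60)
  t0 <- series60@start
  nMin <- length(cnt)
  minuteOf <- function(t) floor(as.numeric(difftime(t, t0, units = "mins"))) + 1L
  bedIdx <- minuteOf(diaryBed)
  wakeIdx <- minuteOf(diaryWake)
  if (bedIdx < 1L || wakeIdx > nMin) {
    stop("diary times fall outside the recorded series for night ", night)
  }

  pick <- function(ok, anchor) {
    starts <- .runStarts(ok, minRunMinutes)
    starts <- starts[abs(starts - anchor) <= windowMinutes]
    if (!length(starts)) return(NA_integer_)
    starts[which.min(abs(starts - anchor))]
  }
  inIdx <- pick(cnt < restThreshold, bedIdx)
  outIdx <- pick(cnt >= restThreshold, wakeIdx)
  sourceIn <- if (is.na(inIdx)) "diary" else "activity"
  sourceOut <- if (is.na(outIdx)) "diary" else "activity"
  if (is.na(inIdx)) inIdx <- bedIdx
  if (is.na(outIdx)) outIdx <- wakeIdx
  if (inIdx >= outIdx) {
    stop("invalid night ", night, ": detected in-bed time is not before ",
         "out-of-bed time")
  }
  data.frame(
    night = as.integer(night),
    in_bed = t0 + (inIdx - 1L) * 60,
    out_of_bed = t0 + (outIdx - 1L) * 60,
    source_in = sourceIn, source_out = sourceOut
  )
}

#' Score 60-s epochs sleep/wake with the Cole-Kripke weighted sum
#'
#' For every 60-s epoch of the rest interval,
#' `D(t) = scale * sum_{k=-4}^{+2} w_k * count(t+k)`; the epoch is scored
#' asleep iff `D(t) < threshold`. Epochs outside the recorded series are
#' padded with zero counts; device-off (`NA`) epochs are treated as zero.
#' Optional Webster rescoring reclassifies short sleep bouts adjacent to
#' long wake bouts as wake.
#'
#' @param series60 [EpochSeries-class] at 60-s epochs.
#' @param rest One-row rest-interval `data.frame` from
#'   [detectRestInterval()] (fields `in_bed`, `out_of_bed`, `night`).
#' @param weights,scale,threshold Cole-Kripke parameters; defaults from
#'   [coleKripkeDefaults()].
#' @param rescore Apply Webster rescoring rules (default `FALSE`).
#' @return A [SleepWakeSeries-class] covering the rest interval.
#' @export
coleKripke <- function(series60, rest,
                       weights = coleKripkeDefaults()$weights,
                       scale = coleKripkeDefaults()$scale,
                       threshold = coleKripkeDefaults()$threshold,
                       rescore = FALSE) {
  if (epochSeconds(series60) != 60L) stop("coleKripke expects 60-s epochs")
  if (length(weights) != 7L) stop("weights must have length 7 (w-4..w+2)")
  cnt <- counts(series60)
  cnt[is.na(cnt)] <- 0
  t0 <- series60@start
  i0 <- floor(as.numeric(difftime(rest$in_bed, t0, units = "mins"))) + 1L
  i1 <- floor(as.numeric(difftime(rest$out_of_bed, t0, units = "mins")))
  if (i1 < i0) stop("empty rest interval")
  # slice with 4 leading / 2 trailing context epochs, zero-padded at edges
  idx <- (i0 - 4L):(i1 + 2L)
  padded <- ifelse(idx >= 1L & idx <= length(cnt), cnt[pmax(pmin(idx, length(cnt)), 1L)], 0)
  # embed(padded, 7) row t is padded[t+6], ..., padded[t]: reverse the weights
  D <- drop(stats::embed(padded, 7L) %*% rev(unname(weights))) * scale
  lab <- D < threshold
  if (rescore) lab <- websterRescore(lab)
  new("SleepWakeSeries",
    subjectID = subjectID(series60),
    night = as.integer(rest$night),
    start = t0 + (i0 - 1L) * 60,
    counts = cnt[i0:i1],
    scores = D,
    asleep = lab
  )
}

#' Webster rescoring rules
#'
#' Reclassifies sleep epochs as wake according to the five rescoring rules:
#' after at least 4 (10, 15) min scored wake, the next 1 (3, 4) min scored
#' sleep are rescored wake; 6 min or less of sleep surrounded by at least
#' 10 min of wake on both sides, and 10 min or less surrounded by at least
#' 20 min, are rescored wake.
#'
#' @param lab Logical vector of per-minute sleep labels (`TRUE` = asleep).
#' @return Rescored logical vector of the same length.
#' @export
websterRescore <- function(lab) {
  n <- length(lab)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- lab
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    prevWake <- if (i > 1L) runs$lengths[i - 1L] else 0L
    nextWake <- if (i < length(runs$values)) runs$lengths[i + 1L] else 0L
    len <- runs$lengths[i]
    # trailing rules: first 1/3/4 sleep minutes after long wake
    k <- if (prevWake >= 15L) 4L else if (prevWake >= 10L) 3L else
      if (prevWake >= 4L) 1L else 0L
    if (k > 0L) out[starts[i]:min(ends[i], starts[i] + k - 1L)] <- FALSE
    # surrounded-bout rules
    if ((len <= 6L && prevWake >= 10L && nextWake >= 10L) ||
        (len <= 10L && prevWake >= 20L && nextWake >= 20L)) {
      out[starts[i]:ends[i]] <- FALSE
    }
  }
  out
}

#' Score diary-reported naps against daytime activity
#'
#' A reported nap is scored iff a run of at least `minRunMinutes`
#' consecutive minutes with per-minute counts below `restThreshold` starts
#' within `withinMinutes` of the reported nap start; the scored nap
#' boundaries are taken from that low-activity run. Reports without an
#' accompanying activity decrease are dropped (returned in the `"dropped"`
#' attribute).
#'
#' @param series60 [EpochSeries-class] at 60-s epochs.
#' @param diaryNaps `data.frame` with `POSIXct` columns `nap_start`,
#'   `nap_end` (rows with missing starts are ignored).
#' @param restThreshold,minRunMinutes Low-activity run definition, shared
#'   with [detectRestInterval()].
#' @param withinMinutes Maximum distance between reported and detected nap
#'   start (default 30 min).
#' @return `data.frame` of scored naps: `start`, `end` (`POSIXct`),
#'   `reported_start`; attribute `"dropped"` holds unmatched report times.
#' @export
detectNaps <- function(series60, diaryNaps, restThreshold = 1000,
                       minRunMinutes = 5, withinMinutes = 30) {
  empty <- data.frame(start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      reported_start = as.POSIXct(character()))
  attr(empty, "dropped") <- as.POSIXct(character())
  if (is.null(diaryNaps) || !nrow(diaryNaps)) return(empty)
  reported <- diaryNaps$nap_start[!is.na(diaryNaps$nap_start)]
  if (!length(reported)) return(empty)

  cnt <- counts(series60)
  t0 <- series60@start
  low <- cnt < restThreshold
  starts <- .runStarts(low, minRunMinutes)
  r <- rle(ifelse(is.na(low), FALSE, low))
  runEnds <- cumsum(r$lengths)
  runStartsAll <- runEnds - r$lengths + 1L
  endOf <- function(s) runEnds[match(s, runStartsAll)]

  rows <- list(); dropped <- as.POSIXct(character())
  for (tRep in as.list(reported)) {
    repIdx <- floor(as.numeric(difftime(tRep, t0, units = "mins"))) + 1L
    cand <- starts[abs(starts - repIdx) <= withinMinutes]
    if (!length(cand)) {
      dropped <- c(dropped, tRep)
      next
    }
    s <- cand[which.min(abs(cand - repIdx))]
    rows[[length(rows) + 1L]] <- data.frame(
      start = t0 + (s - 1L) * 60,
      end = t0 + endOf(s) * 60,
      reported_start = tRep
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "dropped") <- dropped
  out
}
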