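#' Compute the eleven nightly sleep measures from scored epochs
#'
#' Given the 60-s sleep/wake labels of one rest interval, derives: sleep
#' onset (first sleep epoch), midpoint, out-of-bed time (all as hours since
#' the night's reference noon), onset latency (min), sleep duration (h,
#' total sleep between onset and offset), WASO (min, wake strictly between
#' onset and offset), maintenance efficiency (% of the onset-offset span
#' spent asleep), movement index (% of in-bed epochs with counts above
#' `movementThreshold`, divided by hours in bed), fragmentation index, the
#' number of nocturnal awakenings (maximal wake runs strictly between onset
#' and offset) and their mean length (min; 0 when there are none, keeping
#' the summary matrix complete).
#'
#' The default fragmentation index follows the literal definition
#' (% of 60-s sleep epochs among all epochs of the sleep period), which
#' coincides with maintenance efficiency; `fragmentation = "bouts"` selects
#' an ActiGraph-style alternative, 100 x the proportion of immobility bouts
#' (runs of epochs with counts at or below `movementThreshold`) lasting
#' one minute.
#'
#' @param sws [SleepWakeSeries-class] covering the rest interval.
#' @param rest One-row rest-interval `data.frame` ([detectRestInterval()]).
#' @param nightNoon `POSIXct` reference noon for the night's clock times.
#' @param movementThreshold Counts per 60-s epoch above which the epoch
#'   shows movement (default 0).
#' @param fragmentation `"literal"` (default) or `"bouts"`.
#' @return One-row `data.frame` with `night`, `valid`, and the eleven
#'   measures; `valid = FALSE` (all measures `NA`) when no epoch is scored
#'   asleep.
#' @export
computeNightly <- function(sws, rest, nightNoon,
                           movementThreshold = 0,
                           fragmentation = c("literal", "bouts")) {
  fragmentation <- match.arg(fragmentation)
  lab <- asleep(sws)
  n <- length(lab)
  blank <- stats::setNames(
    as.data.frame(as.list(rep(NA_real_, length(measureNames())))),
    measureNames()
  )
  if (!any(lab)) {
    return(cbind(data.frame(night = sws@night, valid = FALSE), blank))
  }
  onsetIdx <- which(lab)[1L]
  offsetIdx <- max(which(lab))
  inBedH <- hoursSinceNoon(rest$in_bed, nightNoon)
  onsetH <- inBedH + (onsetIdx - 1L) / 60
  offsetH <- inBedH + offsetIdx / 60        # end of the last sleep epoch
  outH <- hoursSinceNoon(rest$out_of_bed, nightNoon)

  spanIdx <- onsetIdx:offsetIdx
  sleepMin <- sum(lab[spanIdx])
  spanMin <- length(spanIdx)
  wasoMin <- spanMin - sleepMin
  me <- 100 * sleepMin / spanMin

  wakeRuns <- rle(lab[spanIdx])
  nAwk <- sum(!wakeRuns$values)
  meanAwk <- if (nAwk > 0) mean(wakeRuns$lengths[!wakeRuns$values]) else 0

  cnt <- counts(sws)
  hoursInBed <- n / 60
  movement <- 100 * (sum(cnt > movementThreshold, na.rm = TRUE) / n) / hoursInBed
  frag <- if (fragmentation == "literal") {
    me
  } else {
    immob <- rle(cnt[spanIdx] <= movementThreshold)
    bouts <- immob$lengths[immob$values]
    if (length(bouts)) 100 * mean(bouts == 1L) else 0
  }

  data.frame(
    night = sws@night, valid = TRUE,
    onset = onsetH, midpoint = (onsetH + offsetH) / 2, out_of_bed = outH,
    onset_latency = onsetIdx - 1L, duration = sleepMin / 60,
    waso = wasoMin, maintenance_efficiency = me,
    movement_index = movement, fragmentation_index = frag,
    n_awakenings = nAwk, mean_awakening_length = meanAwk
  )
}

#' Weekly subject summary of nightly measures
#'
#' Arithmetic mean (`avg_`) and within-person SD (`sd_`, sample n-1
#' denominator by default) of each of the eleven measures over the valid
#' nights, the number of valid nights, and the inclusion flag
#' (`n_valid_nights >= minNights`). Clock-time statistics are computed on
#' the hours-since-noon scale. SDs are `NA` with fewer than two valid
#' nights.
#'
#' @param nights `data.frame` of [computeNightly()] rows for one subject.
#' @param minNights Valid-night inclusion threshold (default 5).
#' @param sdType `"sample"` (n-1, default) or `"population"` (n).
#' @return One-row `data.frame`: 22 summary variables, `n_valid_nights`,
#'   `included`.
#' @export
summarizeSubject <- function(nights, minNights = 5, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  v <- nights[which(nights$valid), , drop = FALSE]
  nv <- nrow(v)
  meas <- measureNames()
  avg <- vapply(meas, function(m) if (nv) mean(v[[m]]) else NA_real_, numeric(1))
  sds <- vapply(meas, function(m) {
    if (nv < 2L) return(NA_real_)
    s <- stats::sd(v[[m]])
    if (sdType == "population") s * sqrt((nv - 1) / nv) else s
  }, numeric(1))
  out <- stats::setNames(
    data.frame(t(avg), t(sds)),
    c(paste0("avg_", meas), paste0("sd_", meas))
  )
  out$n_valid_nights <- nv
  out$included <- nv >= minNights
  out
}

#' Score a whole subject: rest detection, Cole-Kripke, measures, naps
#'
#' Convenience orchestration of the per-night pipeline for one subject:
#' aggregates the raw series to 60-s epochs, and for each diary night
#' detects the rest interval, scores sleep/wake, computes the nightly
#' measures, and scores diary naps for that day. A night whose rest
#' interval cannot be resolved, that contains more than
#' `maxMaskedFraction` device-off time, or that has no sleep epoch, is
#' marked invalid with a reason code.
#'
#' @param series Raw [EpochSeries-class] for the subject.
#' @param diary Subject's diary `data.frame` (columns `night`, `bed_time`,
#'   `wake_time`, `nap_start`, `nap_end`, optionally `device_off_start`,
#'   `device_off_end`).
#' @param windowMinutes,restThreshold,minRunMinutes Passed to
#'   [detectRestInterval()].
#' @param weights,scale,threshold,rescore Passed to [coleKripke()].
#' @param movementThreshold,fragmentation Passed to [computeNightly()].
#' @param maxMaskedFraction Maximum tolerated fraction of device-off epochs
#'   within a rest interval (default 0.1).
#' @return List: `nightly` (`data.frame`, one row per night with measures,
#'   validity and `reason`), `naps` (`data.frame` with `night` and per-day
#'   scored-nap count), `rests` (detected rest intervals).
#' @export
scoreSubject <- function(series, diary,
                         windowMinutes = 120, restThreshold = 1000,
                         minRunMinutes = 5,
                         weights = coleKripkeDefaults()$weights,
                         scale = coleKripkeDefaults()$scale,
                         threshold = coleKripkeDefaults()$threshold,
                         rescore = FALSE,
                         movementThreshold = 0,
                         fragmentation = "literal",
                         maxMaskedFraction = 0.1) {
  s60 <- aggregateEpochs(series, 60L)
  # mask diary device-off intervals as missing
  if (all(c("device_off_start", "device_off_end") %in% names(diary))) {
    offs <- diary[!is.na(diary$device_off_start), c("device_off_start", "device_off_end")]
    if (nrow(offs)) {
      cnt <- counts(s60)
      for (i in seq_len(nrow(offs))) {
        a <- floor(as.numeric(difftime(offs$device_off_start[i], s60@start, units = "mins"))) + 1L
        b <- ceiling(as.numeric(difftime(offs$device_off_end[i], s60@start, units = "mins")))
        cnt[max(1L, a):min(length(cnt), b)] <- NA_real_
      }
      s60 <- epochSeries(subjectID(s60), s60@start, 60L, cnt)
    }
  }

  nightsOut <- list(); rests <- list(); napRows <- list()
  blank <- stats::setNames(
    as.data.frame(as.list(rep(NA_real_, length(measureNames())))),
    measureNames()
  )
  for (i in seq_len(nrow(diary))) {
    nightI <- diary$night[i]
    noonI <- diary$bed_time[i]
    noonI <- trunc(noonI, "days") + ifelse(as.POSIXlt(diary$bed_time[i])$hour >= 12, 43200, -43200)
    rest <- tryCatch(
      detectRestInterval(s60, diary$bed_time[i], diary$wake_time[i],
                         windowMinutes = windowMinutes,
                         restThreshold = restThreshold,
                         minRunMinutes = minRunMinutes, night = nightI),
      error = function(e) NULL
    )
    if (is.null(rest)) {
      nightsOut[[i]] <- cbind(data.frame(night = nightI, valid = FALSE), blank,
                              data.frame(reason = "rest_interval_unresolved"))
      next
    }
    rests[[length(rests) + 1L]] <- rest
    i0 <- floor(as.numeric(difftime(rest$in_bed, s60@start, units = "mins"))) + 1L
    i1 <- floor(as.numeric(difftime(rest$out_of_bed, s60@start, units = "mins")))
    maskedFrac <- mean(is.na(counts(s60)[i0:i1]))
    if (maskedFrac > maxMaskedFraction) {
      nightsOut[[i]] <- cbind(data.frame(night = nightI, valid = FALSE), blank,
                              data.frame(reason = "device_off_exceeds_limit"))
      next
    }
    sws <- coleKripke(s60, rest, weights = weights, scale = scale,
                      threshold = threshold, rescore = rescore)
    nm <- computeNightly(sws, rest, noonI,
                         movementThreshold = movementThreshold,
                         fragmentation = fragmentation)
    nm$reason <- if (nm$valid) "" else "no_sleep_epoch"
    nightsOut[[i]] <- nm

    naps <- detectNaps(s60, diary[i, , drop = FALSE],
                       restThreshold = restThreshold,
                       minRunMinutes = minRunMinutes)
    napRows[[i]] <- data.frame(night = nightI, n_naps = nrow(naps))
  }
  nightly <- do.call(rbind, nightsOut)
  if (is.null(nightly)) nightly <- data.frame()
  napDf <- if (length(napRows)) do.call(rbind, napRows) else
    data.frame(night = integer(), n_naps = integer())
  list(
    nightly = nightly,
    naps = napDf,
    rests = if (length(rests)) do.call(rbind, rests) else NULL
  )
}
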