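#' Names of the eleven nightly sleep measures and 22 weekly summaries
#'
#' The nightly measures are: sleep onset, midpoint and out-of-bed time
#' (clock times on the hours-since-noon scale), onset latency (min), sleep
#' duration (h), WASO (min), maintenance efficiency (%), movement index,
#' fragmentation index, number of nocturnal awakenings and mean awakening
#' length (min). The 22 subject-level summary variables are the weekly mean
#' (`avg_`) and within-person SD (`sd_`) of each.
#'
#' @return Character vector of measure (`measureNames()`) or summary
#'   (`summaryVariables()`) names.
#' @export
measureNames <- function() {
  c("onset", "midpoint", "out_of_bed", "onset_latency", "duration", "waso",
    "maintenance_efficiency", "movement_index", "fragmentation_index",
    "n_awakenings", "mean_awakening_length")
}

#' @rdname measureNames
#' @export
summaryVariables <- function() {
  c(paste0("avg_", measureNames()), paste0("sd_", measureNames()))
}

#' Subject-level simulation profile
#'
#' Describes one subject's nightly sleep process and activity-count levels.
#' Clock times use the hours-since-noon scale (23:30 = 11.5, 02:00 = 14.0).
#'
#' @param subject_id Subject identifier.
#' @param mean_onset Mean in-bed time, hours since noon.
#' @param sd_onset Night-to-night SD of in-bed time (h).
#' @param mean_sleep_duration Mean sleep-period span, onset to offset (h).
#' @param sd_duration Night-to-night SD of the span (h).
#' @param onset_latency_mean Mean sleep-onset latency (min, exponential).
#' @param awakening_rate Expected nocturnal awakenings per night (Poisson mean).
#' @param awakening_length_mean Mean awakening length (min, exponential).
#' @param awakening_length_night_sd SD (log scale) of a nightly multiplier on
#'   awakening length, giving night-to-night variability in awakening length
#'   beyond Poisson/exponential sampling.
#' @param nap_prob Daily nap probability.
#' @param asleep_count_level,awake_count_level,daytime_count_level Mean
#'   activity counts per 15-s epoch while asleep, awake in bed, and out of
#'   bed. Must be strictly increasing so the <1,000 / >=1,000 counts-per-minute
#'   rest heuristic is realizable.
#' @param count_dispersion Negative-binomial size parameter for counts.
#' @param terminal_wake_mean Mean wake time between final sleep offset and
#'   out-of-bed (min).
#' @param hiv_status,age,gender,ethnicity,education,sleep_med Covariates.
#' @return A `subjectProfile` list.
#' @export
subjectProfile <- function(subject_id = "s1",
                           mean_onset = 11.5,
                           sd_onset = 0.5,
                           mean_sleep_duration = 7.3,
                           sd_duration = 0.5,
                           onset_latency_mean = 12,
                           awakening_rate = 7,
                           awakening_length_mean = 5,
                           awakening_length_night_sd = 0.35,
                           nap_prob = 0.2,
                           asleep_count_level = 2,
                           awake_count_level = 60,
                           daytime_count_level = 400,
                           count_dispersion = 8,
                           terminal_wake_mean = 5,
                           hiv_status = 1L, age = 57, gender = "male",
                           ethnicity = "white", education = "university",
                           sleep_med = 0L) {
  p <- list(
    subject_id = as.character(subject_id), mean_onset = mean_onset,
    sd_onset = sd_onset, mean_sleep_duration = mean_sleep_duration,
    sd_duration = sd_duration, onset_latency_mean = onset_latency_mean,
    awakening_rate = awakening_rate,
    awakening_length_mean = awakening_length_mean,
    awakening_length_night_sd = awakening_length_night_sd,
    nap_prob = nap_prob,
    asleep_count_level = asleep_count_level,
    awake_count_level = awake_count_level,
    daytime_count_level = daytime_count_level,
    count_dispersion = count_dispersion,
    terminal_wake_mean = terminal_wake_mean,
    hiv_status = hiv_status, age = age, gender = gender,
    ethnicity = ethnicity, education = education, sleep_med = sleep_med
  )
  stopifnot(
    p$sd_onset >= 0, p$mean_sleep_duration > 0, p$sd_duration >= 0,
    p$nap_prob >= 0, p$nap_prob <= 1,
    p$awakening_rate >= 0, p$awakening_length_mean > 0
  )
  if (!(p$asleep_count_level < p$awake_count_level &&
        p$awake_count_level < p$daytime_count_level)) {
    stop("count levels must satisfy asleep < awake < daytime")
  }
  class(p) <- c("subjectProfile", "list")
  p
}

# Draw one night's true structure for a profile; times in hours since the
# night's reference noon. Resamples up to maxRetry when the draw is
# infeasible (out-of-bed spilling past the next noon, or a degenerate span).
.simulateNight <- function(profile, maxRetry = 25L) {
  for (i in seq_len(maxRetry)) {
    in_bed <- stats::rnorm(1, profile$mean_onset, profile$sd_onset)
    latency <- stats::rexp(1) * profile$onset_latency_mean / 60
    span <- stats::rnorm(1, profile$mean_sleep_duration, profile$sd_duration)
    if (span < 1 || span > 14) next
    tau <- profile$awakening_length_night_sd
    # The night's mean awakening length is a trait-driven draw, and the
    # awakening count compensates it (nights with longer awakenings have
    # proportionally fewer), so each night's expected total wake time is the
    # subject constant awakening_rate x awakening_length_mean: night-to-night
    # variability of mean awakening length reflects the variability trait
    # alone, not the WASO budget. With tau > 0 the expected awakening count
    # is awakening_rate x exp(tau^2); with tau = 0 it is awakening_rate
    # exactly.
    nightMean <- profile$awakening_length_mean * exp(stats::rnorm(1, -tau^2 / 2, tau))
    nightRate <- profile$awakening_rate * profile$awakening_length_mean / nightMean
    nA <- stats::rpois(1, nightRate)
    lengths <- if (nA > 0) {
      raw <- stats::rexp(nA)
      raw / mean(raw) * nightMean
    } else numeric()
    waso <- sum(lengths) / 60
    if (waso > 0.5 * span) next
    terminal <- stats::rexp(1) * profile$terminal_wake_mean / 60
    onset <- in_bed + latency
    offset <- onset + span
    out_of_bed <- offset + terminal
    if (out_of_bed >= 23.75 || in_bed < 2) next
    # sleep segments between awakenings: stick-breaking of the sleep total
    segs <- stats::rexp(nA + 1L)
    segs <- segs / sum(segs) * (span - waso)
    wakeStart <- wakeEnd <- numeric(nA)
    pos <- onset
    for (j in seq_len(nA)) {
      pos <- pos + segs[j]
      wakeStart[j] <- pos
      pos <- pos + lengths[j] / 60
      wakeEnd[j] <- pos
    }
    return(list(
      in_bed = in_bed, onset = onset, offset = offset,
      out_of_bed = out_of_bed, latency_min = latency * 60,
      span_h = span, waso_min = waso * 60, terminal_min = terminal * 60,
      n_awakenings = nA,
      mean_awakening_length = if (nA > 0) mean(lengths) else 0,
      wake_start = wakeStart, wake_end = wakeEnd
    ))
  }
  stop("infeasible profile for subject ", profile$subject_id,
       ": could not draw a valid night in ", maxRetry, " attempts")
}

# True nightly measures implied by a .simulateNight() draw.
.trueNightMeasures <- function(nt) {
  sleep_h <- nt$span_h - nt$waso_min / 60
  in_bed_min <- (nt$out_of_bed - nt$in_bed) * 60
  awake_min <- nt$latency_min + nt$waso_min + nt$terminal_min
  hours_in_bed <- in_bed_min / 60
  me <- 100 * sleep_h / nt$span_h
  c(
    onset = nt$onset, midpoint = (nt$onset + nt$offset) / 2,
    out_of_bed = nt$out_of_bed, onset_latency = nt$latency_min,
    duration = sleep_h, waso = nt$waso_min, maintenance_efficiency = me,
    movement_index = 100 * (awake_min / in_bed_min) / hours_in_bed,
    fragmentation_index = me,
    n_awakenings = nt$n_awakenings,
    mean_awakening_length = nt$mean_awakening_length
  )
}

#' Simulate one subject's actigraphy week
#'
#' Generates a contiguous 15-s activity-count series over `nDays` days
#' starting at noon, a sleep diary (bed/wake times with reporting noise,
#' naps), and the ground truth: per-night sleep intervals and the true
#' nightly measures. Nightly structure: in-bed time ~ Normal(mean_onset,
#' sd_onset); sleep starts after an exponential latency; the sleep period
#' spans Normal(mean_sleep_duration, sd_duration) hours and contains
#' Poisson(awakening_rate) awakenings of exponential length; activity counts
#' are negative binomial at the asleep / awake-in-bed / daytime level of the
#' true state.
#'
#' @param profile A [subjectProfile()].
#' @param nDays Number of recording days (one night per day).
#' @param seed Integer seed; the output is a deterministic function of
#'   (profile, nDays, seed).
#' @param epochSeconds Raw epoch length (s); must divide 60.
#' @param start `POSIXct` recording start (the first day's noon).
#' @param diaryNoiseMin SD of Gaussian diary reporting noise (min),
#'   truncated at +/- 3 SD.
#' @param generateCounts Draw the activity counts (default). `FALSE` skips
#'   count generation (all-zero series) for truth-level studies that only
#'   need the ground-truth intervals and diary.
#' @return List with elements `epochs` ([EpochSeries-class]), `diary`
#'   (`data.frame`: night, bed_time, wake_time, nap_start, nap_end), and
#'   `truth` (`data.frame` of true intervals and nightly measures).
#' @examples
#' sim <- simulateSubject(subjectProfile(awakening_rate = 3), nDays = 5, seed = 1)
#' sim$truth$waso
#' @export
simulateSubject <- function(profile, nDays, seed,
                            epochSeconds = 15L,
                            start = as.POSIXct("2024-01-01 12:00:00", tz = "UTC"),
                            diaryNoiseMin = 10, generateCounts = TRUE) {
  stopifnot(nDays >= 1, 60L %% as.integer(epochSeconds) == 0L)
  set.seed(as.integer(seed))
  epochSeconds <- as.integer(epochSeconds)
  nEp <- nDays * 86400L %/% epochSeconds
  perHour <- 3600 / epochSeconds

  toIdx <- function(hAbs) pmax(1L, pmin(nEp, floor(hAbs * perHour) + 1L))
  state <- integer(nEp) # 0 daytime, 1 awake in bed, 2 asleep

  nights <- vector("list", nDays)
  napStart <- napEnd <- rep(NA_real_, nDays)
  for (d in seq_len(nDays)) {
    nt <- .simulateNight(profile)
    base <- (d - 1) * 24
    # rest interval: awake in bed by default, asleep within sleep segments
    state[toIdx(base + nt$in_bed):toIdx(base + nt$out_of_bed)] <- 1L
    sleepFrom <- c(nt$onset, nt$wake_end)
    sleepTo <- c(nt$wake_start, nt$offset)
    for (j in seq_along(sleepFrom)) {
      i0 <- toIdx(base + sleepFrom[j]); i1 <- toIdx(base + sleepTo[j])
      if (i1 > i0) state[i0:(i1 - 1L)] <- 2L
    }
    if (stats::runif(1) < profile$nap_prob) {
      ns <- stats::runif(1, 1.5, 4.5)           # 13:30-16:30
      ne <- ns + stats::runif(1, 20, 60) / 60
      if (ne < nt$in_bed - 0.5) {
        napStart[d] <- ns; napEnd[d] <- ne
        state[toIdx(base + ns):toIdx(base + ne)] <- 2L
      }
    }
    nights[[d]] <- nt
  }

  cnt <- if (generateCounts) {
    levels <- c(profile$daytime_count_level, profile$awake_count_level,
                profile$asleep_count_level)
    stats::rnbinom(nEp, mu = levels[state + 1L],
                   size = profile$count_dispersion)
  } else {
    rep(0, nEp)
  }

  noise <- function() {
    z <- stats::rnorm(1, 0, diaryNoiseMin)
    max(-3 * diaryNoiseMin, min(3 * diaryNoiseMin, z)) / 60
  }
  truth <- do.call(rbind, lapply(seq_len(nDays), function(d) {
    nt <- nights[[d]]
    data.frame(subject_id = profile$subject_id, night = d,
               in_bed = nt$in_bed, out_of_bed_true = nt$out_of_bed,
               onset_true = nt$onset, offset_true = nt$offset,
               terminal_min = nt$terminal_min,
               nap = as.integer(!is.na(napStart[d])),
               t(.trueNightMeasures(nt)))
  }))
  diary <- do.call(rbind, lapply(seq_len(nDays), function(d) {
    nt <- nights[[d]]
    noonD <- .nightNoon(start, d)
    data.frame(
      subject_id = profile$subject_id, night = d,
      bed_time = noonOffsetToTime(nt$in_bed + noise(), noonD),
      wake_time = noonOffsetToTime(nt$out_of_bed + noise(), noonD),
      nap_start = if (is.na(napStart[d])) as.POSIXct(NA) else
        noonOffsetToTime(napStart[d], noonD),
      nap_end = if (is.na(napEnd[d])) as.POSIXct(NA) else
        noonOffsetToTime(napEnd[d], noonD),
      device_off_start = as.POSIXct(NA), device_off_end = as.POSIXct(NA)
    )
  }))
  list(
    epochs = epochSeries(profile$subject_id, start, epochSeconds, cnt),
    diary = diary,
    truth = truth
  )
}

#' Subject-level summaries of true nightly measures
#'
#' @param truth The `truth` data.frame of [simulateSubject()] (or several
#'   subjects' stacked).
#' @return `data.frame` with one row per subject: the 22 `avg_`/`sd_` true
#'   summary variables.
#' @export
truthSummaries <- function(truth) {
  meas <- measureNames()
  out <- lapply(split(truth, truth$subject_id), function(tt) {
    avg <- vapply(meas, function(m) mean(tt[[m]]), numeric(1))
    sds <- vapply(meas, function(m) stats::sd(tt[[m]]), numeric(1))
    stats::setNames(
      data.frame(tt$subject_id[1], t(avg), t(sds)),
      c("subject_id", paste0("avg_", meas), paste0("sd_", meas))
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id), , drop = FALSE]
}
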