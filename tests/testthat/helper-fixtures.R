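# Shared fixtures, all built in code.

.START <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")

# A minute-resolution EpochSeries from a vector of per-minute counts.
minuteSeries <- function(counts, subject = "s1", start = .START) {
  epochSeries(subject, start, 60L, counts)
}

# A one-row rest interval covering minutes [fromMin, toMin) of a series.
restRow <- function(series60, fromMin, toMin, night = 1L) {
  data.frame(
    night = night,
    in_bed = series60@start + (fromMin - 1L) * 60,
    out_of_bed = series60@start + (toMin - 1L) * 60,
    source_in = "activity", source_out = "activity"
  )
}

# A SleepWakeSeries directly from a logical label vector (counts follow the
# labels: 0 while asleep, 300 while awake, unless given).
labelledNight <- function(lab, counts = ifelse(lab, 0, 300),
                          subject = "s1", night = 1L, start = .START) {
  new("SleepWakeSeries",
    subjectID = subject, night = as.integer(night), start = start,
    counts = as.numeric(counts), scores = as.numeric(!lab), asleep = lab
  )
}

# Brute-force Cole-Kripke oracle: per-epoch loop over the weighted window.
bruteForceCK <- function(cnt, weights, scale, threshold) {
  n <- length(cnt)
  padded <- c(0, 0, 0, 0, cnt, 0, 0)
  D <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0
    for (k in -4:2) s <- s + weights[k + 5] * padded[t + 4 + k]
    D[t] <- scale * s
  }
  list(D = D, asleep = D < threshold)
}

# Random analysis frame with independent standard-normal sleep summaries,
# covariates, and an outcome built from a named coefficient vector.
randomFrame <- function(n, beta = NULL, noise = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 22), n, 22, dimnames = list(NULL, summaryVariables()))
  y <- rnorm(n, 0, noise)
  if (!is.null(beta)) y <- y + drop(X[, names(beta), drop = FALSE] %*% beta)
  data.frame(
    subject_id = sprintf("r%04d", seq_len(n)), X,
    global_t = 50 + 10 * y,
    age = round(runif(n, 35, 80)),
    gender = sample(c("male", "female"), n, TRUE),
    ethnicity = sample(c("white", "black", "other"), n, TRUE),
    education = sample(c("secondary", "college", "university"), n, TRUE),
    sleep_med = rbinom(n, 1, 0.1),
    hiv_status = rbinom(n, 1, 0.5)
  )
}
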