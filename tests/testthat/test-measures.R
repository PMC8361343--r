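noon <- .START

test_that("an all-sleep rest interval gives the degenerate measures", {
  lab <- rep(TRUE, 480)                       # 8 h, every epoch asleep
  sws <- labelledNight(lab, start = noon + 11 * 3600)   # in bed 23:00
  rest <- data.frame(night = 1L, in_bed = noon + 11 * 3600,
                     out_of_bed = noon + 19 * 3600,
                     source_in = "activity", source_out = "activity")
  nm <- computeNightly(sws, rest, noon)
  expect_true(nm$valid)
  expect_equal(nm$onset_latency, 0)
  expect_equal(nm$waso, 0)
  expect_equal(nm$maintenance_efficiency, 100)
  expect_equal(nm$n_awakenings, 0)
  expect_equal(nm$mean_awakening_length, 0)
  expect_equal(nm$duration, 8)
  expect_equal(nm$onset, 11)
  expect_equal(nm$out_of_bed, 19)
})

test_that("the ten-epoch toy night reproduces the hand counts", {
  lab <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  sws <- labelledNight(lab, start = noon + 10 * 3600)
  rest <- data.frame(night = 1L, in_bed = noon + 10 * 3600,
                     out_of_bed = noon + 10 * 3600 + 600,
                     source_in = "activity", source_out = "activity")
  nm <- computeNightly(sws, rest, noon)
  expect_equal(nm$onset_latency, 2)                    # onset at epoch 3
  expect_equal(nm$duration, 5 / 60)                    # 5 sleep minutes
  expect_equal(nm$waso, 2)
  expect_equal(nm$maintenance_efficiency, 100 * 5 / 7, tolerance = 1e-12)
  expect_equal(nm$n_awakenings, 1)
  expect_equal(nm$mean_awakening_length, 2)
  # onset clock = in_bed + 2 min; offset = in_bed + 9 min
  expect_equal(nm$onset, 10 + 2 / 60)
  expect_equal(nm$midpoint, 10 + (2 + 9) / 2 / 60)
})

test_that("wake placement inside the sleep period does not change totals", {
  base <- c(FALSE, rep(TRUE, 20), rep(FALSE, 3), rep(TRUE, 20), FALSE)
  rest <- data.frame(night = 1L, in_bed = noon + 11 * 3600,
                     out_of_bed = noon + 11 * 3600 + length(base) * 60,
                     source_in = "activity", source_out = "activity")
  nm1 <- computeNightly(labelledNight(base, start = noon + 11 * 3600), rest, noon)
  # move the 3-min awakening elsewhere between onset and offset
  moved <- c(FALSE, rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 35), FALSE)
  nm2 <- computeNightly(labelledNight(moved, start = noon + 11 * 3600), rest, noon)
  for (f in c("duration", "waso", "maintenance_efficiency", "n_awakenings")) {
    expect_equal(nm1[[f]], nm2[[f]])
  }
})

test_that("a rest interval with no sleep is marked invalid, never NaN", {
  sws <- labelledNight(rep(FALSE, 60))
  rest <- data.frame(night = 1L, in_bed = .START, out_of_bed = .START + 3600,
                     source_in = "activity", source_out = "activity")
  nm <- computeNightly(sws, rest, .START)
  expect_false(nm$valid)
  expect_true(all(is.na(unlist(nm[measureNames()]))))
})

test_that("nightly components conserve the rest interval within one epoch", {
  set.seed(20)
  for (i in 1:40) {
    nMin <- sample(300:600, 1)
    lab <- runif(nMin) < 0.85
    rest <- data.frame(night = 1L, in_bed = noon + 11 * 3600,
                       out_of_bed = noon + 11 * 3600 + nMin * 60,
                       source_in = "activity", source_out = "activity")
    nm <- computeNightly(labelledNight(lab, start = noon + 11 * 3600), rest, noon)
    if (!nm$valid) next
    terminal <- nMin - (nm$onset_latency + nm$duration * 60 + nm$waso)
    expect_gte(terminal, -1e-9)   # duration*60 can round off by an ulp
    expect_equal(nm$onset_latency + nm$duration * 60 + nm$waso + terminal, nMin)
  }
})

test_that("subject summaries use sample SDs and the five-night filter", {
  mk <- function(durs) {
    do.call(rbind, lapply(seq_along(durs), function(i) {
      data.frame(night = i, valid = TRUE, onset = 11.5, midpoint = 15,
                 out_of_bed = 19, onset_latency = 10, duration = durs[i],
                 waso = 30, maintenance_efficiency = 90, movement_index = 5,
                 fragmentation_index = 90, n_awakenings = 4,
                 mean_awakening_length = 7)
    }))
  }
  s <- summarizeSubject(mk(c(6, 7, 8)))
  expect_equal(s$avg_duration, 7)
  expect_equal(s$sd_duration, 1)
  expect_false(s$included)           # 3 valid nights < 5

  s7 <- summarizeSubject(mk(rep(7, 7)))
  expect_true(s7$included)
  expect_true(all(unlist(s7[paste0("sd_", measureNames())]) == 0))

  s4 <- summarizeSubject(mk(rep(7, 4)))
  expect_false(s4$included)
  expect_equal(s4$n_valid_nights, 4)

  s1 <- summarizeSubject(mk(7))
  expect_true(is.na(s1$sd_duration))  # SD undefined below two nights

  # population-SD switch
  sp <- summarizeSubject(mk(c(6, 8)), sdType = "population")
  expect_equal(sp$sd_duration, 1)
})

test_that("pipeline summaries recover ground truth across subjects", {
  cb <- simulateCohort(cohortConfig(nSubjects = 40, seed = 17))
  res <- processCohort(cohortEpochs(cb), cohortDiary(cb), cohortPhenotypes(cb))
  m <- merge(res$summaries, cohortTruth(cb)$summaries, by = "subject_id",
             suffixes = c("", ".true"))
  for (v in c("avg_waso", "avg_maintenance_efficiency")) {
    expect_gt(cor(m[[v]], m[[paste0(v, ".true")]], method = "spearman"), 0.85)
  }
})
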