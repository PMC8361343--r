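test_that("rest-interval detection follows the 1,000-count run rules", {
  # high activity until 23:00 (minute 661), zero after; diary bed 23:10
  cnt <- c(rep(2000, 660), rep(0, 540))
  es <- minuteSeries(cnt)
  bed <- .START + (670 - 1) * 60   # 23:09
  wake <- .START + (1150 - 1) * 60
  rest <- detectRestInterval(es, bed, wake, windowMinutes = 60)
  expect_identical(rest$in_bed, .START + 660 * 60)  # start of the low run, 23:00
  expect_equal(rest$source_in, "activity")

  # no qualifying >=1000 run near the diary wake: fall back to the diary time
  expect_equal(rest$out_of_bed, wake)
  expect_equal(rest$source_out, "diary")

  # a 4-min dip below 1,000 is ignored; the 10-min dip wins
  cnt2 <- c(rep(2000, 600), rep(0, 4), rep(2000, 26), rep(0, 10), rep(2000, 800))
  es2 <- minuteSeries(cnt2)
  bed2 <- .START + 600 * 60
  rest2 <- detectRestInterval(es2, bed2, .START + 1200 * 60, windowMinutes = 120)
  expect_identical(rest2$in_bed, .START + 630 * 60)

  # in-bed at/after out-of-bed is an invalid night
  expect_error(
    detectRestInterval(minuteSeries(rep(0, 1200)), .START + 700 * 60,
                       .START + 650 * 60),
    "invalid night"
  )
})

test_that("Cole-Kripke scoring matches the hand-computed weighted sum", {
  ck <- coleKripkeDefaults()

  # all-zero counts: D = 0 everywhere, everything asleep
  es <- minuteSeries(rep(0, 120))
  rest <- restRow(es, 10, 110)
  sws <- coleKripke(es, rest)
  expect_true(all(asleep(sws)))
  expect_equal(ckScores(sws), rep(0, 100))

  # a single large count wakes its weighted window, per hand evaluation
  cnt <- rep(0, 30); cnt[15] <- 300   # scale*w0*300 = 1.323 >= 1
  es2 <- minuteSeries(cnt)
  rest2 <- restRow(es2, 5, 26)
  sws2 <- coleKripke(es2, rest2)
  # epochs scored wake: those whose window covers minute 15 with any weight
  # => minutes 13..19 (w+2 back to w-4)
  expected <- 300 * ck$scale * c(ck$weights["w+2"], ck$weights["w+1"],
                                 ck$weights["w0"], ck$weights["w-1"],
                                 ck$weights["w-2"], ck$weights["w-3"],
                                 ck$weights["w-4"])
  minutes <- epochTimes(sws2)
  idx <- which(minutes >= .START + 12 * 60 & minutes <= .START + 18 * 60)
  expect_equal(ckScores(sws2)[idx], unname(expected))
  expect_identical(asleep(sws2)[idx], unname(expected < 1))

  # monotonicity: doubling counts never flips wake to sleep
  set.seed(42)
  cnt3 <- rpois(60, 40)
  es3 <- minuteSeries(cnt3)
  rest3 <- restRow(es3, 6, 55)
  lab1 <- asleep(coleKripke(es3, rest3))
  lab2 <- asleep(coleKripke(minuteSeries(2 * cnt3), rest3))
  expect_true(all(lab2 <= lab1))
})

test_that("Cole-Kripke agrees exactly with the brute-force oracle", {
  ck <- coleKripkeDefaults()
  set.seed(7)
  for (i in 1:25) {
    cnt <- rpois(50, sample(c(5, 50, 200), 1))
    es <- minuteSeries(cnt)
    rest <- restRow(es, 1, 51)   # whole series in bed
    sws <- coleKripke(es, rest)
    oracle <- bruteForceCK(cnt, ck$weights, ck$scale, ck$threshold)
    expect_equal(ckScores(sws), oracle$D, tolerance = 1e-12)
    expect_identical(asleep(sws), oracle$asleep)
  }
})

test_that("every epoch of the rest interval receives exactly one label", {
  set.seed(8)
  cnt <- rpois(300, 30)
  es <- minuteSeries(cnt)
  rest <- restRow(es, 20, 280)
  sws <- coleKripke(es, rest)
  expect_equal(nEpochs(sws), 260)
  expect_false(anyNA(asleep(sws)))
})

test_that("Webster rescoring converts short sleep after long wake", {
  # 5 min wake, then sleep: first minute of sleep rescored
  lab <- c(rep(FALSE, 5), rep(TRUE, 20))
  out <- websterRescore(lab)
  expect_identical(out[6], FALSE)
  expect_identical(out[7:25], rep(TRUE, 19))

  # 12 min wake: first 3 sleep minutes rescored
  lab2 <- c(rep(FALSE, 12), rep(TRUE, 20))
  expect_identical(websterRescore(lab2)[13:15], rep(FALSE, 3))

  # 6-min sleep island between 10-min wakes disappears
  lab3 <- c(rep(FALSE, 10), rep(TRUE, 6), rep(FALSE, 10))
  expect_true(all(!websterRescore(lab3)))
})

test_that("nap scoring requires a diary report and an activity decrease", {
  # counts low from 14:05 for 30 min; nap reported 14:00-14:30
  cnt <- rep(2000, 400); cnt[126:155] <- 0
  es <- minuteSeries(cnt)
  naps <- data.frame(nap_start = .START + 120 * 60, nap_end = .START + 150 * 60)
  scored <- detectNaps(es, naps)
  expect_equal(nrow(scored), 1L)
  expect_identical(scored$start, .START + 125 * 60)   # 14:05

  # uniformly high counts: report dropped
  scored2 <- detectNaps(minuteSeries(rep(2000, 400)), naps)
  expect_equal(nrow(scored2), 0L)
  expect_length(attr(scored2, "dropped"), 1L)

  # no diary naps: empty regardless of counts
  scored3 <- detectNaps(es, data.frame(nap_start = as.POSIXct(character()),
                                       nap_end = as.POSIXct(character())))
  expect_equal(nrow(scored3), 0L)
})

test_that("detected rest intervals recover the true ones on simulated nights", {
  cb <- simulateCohort(cohortConfig(nSubjects = 12, seed = 31))
  ok <- 0L; total <- 0L
  for (id in names(cohortEpochs(cb))) {
    s60 <- aggregateEpochs(cohortEpochs(cb)[[id]], 60L)
    dsub <- cohortDiary(cb)[cohortDiary(cb)$subject_id == id, ]
    tsub <- cohortTruth(cb)$nights[cohortTruth(cb)$nights$subject_id == id, ]
    for (i in seq_len(nrow(dsub))) {
      rest <- detectRestInterval(s60, dsub$bed_time[i], dsub$wake_time[i],
                                 night = dsub$night[i])
      noon <- .START + (dsub$night[i] - 1) * 86400
      errIn <- abs(hoursSinceNoon(rest$in_bed, noon) - tsub$in_bed[i]) * 60
      errOut <- abs(hoursSinceNoon(rest$out_of_bed, noon) -
                      tsub$out_of_bed_true[i]) * 60
      total <- total + 1L
      if (errIn <= 10 && errOut <= 10) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.9)
})
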