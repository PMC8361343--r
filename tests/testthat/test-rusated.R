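goodNight <- function(onset = 11.5, out = 19, me = 95, dur = 7) {
  data.frame(night = 1L, valid = TRUE, onset = onset, midpoint = 15,
             out_of_bed = out, onset_latency = 10, duration = dur, waso = 20,
             maintenance_efficiency = me, movement_index = 4,
             fragmentation_index = me, n_awakenings = 3,
             mean_awakening_length = 6)
}

test_that("nightly dimension flags follow the printed cutoffs", {
  flags <- nightDimensionFlags(goodNight(), napsThatDay = 0,
                               subjectMeanOnset = 11.4)
  expect_true(all(flags))

  # efficiency at exactly 85% is good ("at least 85%")
  f85 <- nightDimensionFlags(goodNight(me = 85), 0, 11.5)
  expect_true(f85[["efficiency"]])
  expect_false(nightDimensionFlags(goodNight(me = 84.9), 0, 11.5)[["efficiency"]])

  # onset at exactly 02:00 is bad ("before 02:00 am" is strict)
  f2am <- nightDimensionFlags(goodNight(onset = 14.0), 0, 14.0)
  expect_false(f2am[["timing"]])
  expect_true(nightDimensionFlags(goodNight(onset = 13.99), 0, 13.99)[["timing"]])

  # out-of-bed must be strictly after 04:00
  expect_false(nightDimensionFlags(goodNight(out = 16.0), 0, 11.5)[["timing"]])

  # duration bounds are inclusive
  expect_true(nightDimensionFlags(goodNight(dur = 6), 0, 11.5)[["duration"]])
  expect_true(nightDimensionFlags(goodNight(dur = 8), 0, 11.5)[["duration"]])
  expect_false(nightDimensionFlags(goodNight(dur = 8.01), 0, 11.5)[["duration"]])

  # regularity: within 30 min of the subject mean onset
  expect_true(nightDimensionFlags(goodNight(), 0, 11.5 + 0.5)[["regularity"]])
  expect_false(nightDimensionFlags(goodNight(), 0, 11.5 + 0.51)[["regularity"]])

  # any nap that day breaks alertness
  expect_false(nightDimensionFlags(goodNight(), 1, 11.5)[["alertness"]])
})

test_that("dimension scoring bands follow at-least-70 / below-30", {
  expect_equal(scoreDimension(1), 2L)
  expect_equal(scoreDimension(5 / 7), 2L)     # 0.714 >= 0.70
  expect_equal(scoreDimension(0.70), 2L)
  expect_equal(scoreDimension(0.30), 1L)      # poor requires < 30%
  expect_equal(scoreDimension(0.299), 0L)
  expect_equal(scoreDimension(0), 0L)
  expect_error(scoreDimension(1.2), "proportion")
  # monotone non-decreasing over the unit interval
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(vapply(p, scoreDimension, integer(1))) >= 0))
})

test_that("satisfaction requires agreement of both questionnaire items", {
  expect_equal(scoreSatisfaction("Very satisfied", "Very much"), 2L)
  expect_equal(scoreSatisfaction("Moderately satisfied", "Quite a lot"), 2L)
  expect_equal(scoreSatisfaction("Very dissatisfied", "Not at all"), 0L)
  expect_equal(scoreSatisfaction("Dissatisfied", "A little bit"), 0L)
  expect_equal(scoreSatisfaction("Very satisfied", "A little bit"), 1L)
  expect_equal(scoreSatisfaction("Satisfied", "Very much"), 1L)
  expect_equal(scoreSatisfaction("Dissatisfied", "Somewhat"), 1L)
  expect_error(scoreSatisfaction("Meh", "Very much"), "unknown")
})

test_that("the total sleep-health score is the bounded six-dimension sum", {
  all2 <- c(satisfaction = 2, alertness = 2, timing = 2, efficiency = 2,
            duration = 2, regularity = 2)
  expect_equal(totalSleepHealth(all2), 12L)
  expect_equal(totalSleepHealth(all2 * 0), 0L)
  expect_equal(totalSleepHealth(c(satisfaction = 2, alertness = 1, timing = 2,
                                  efficiency = 0, duration = 1,
                                  regularity = 2)), 8L)
  expect_error(totalSleepHealth(all2[-1]), "missing dimension")
  expect_error(totalSleepHealth(replace(all2, 1, 3)), "in \\{0, 1, 2\\}")
})

test_that("subject dimension scores integrate nights, naps and questionnaire", {
  nights <- do.call(rbind, lapply(1:7, function(i) {
    n <- goodNight(); n$night <- i; n
  }))
  naps <- data.frame(night = 1:7, n_naps = c(0, 0, 0, 0, 0, 1, 1))
  ds <- dimensionScores(nights, naps, "Very satisfied", "Very much")
  expect_equal(ds$satisfaction, 2L)
  expect_equal(ds$alertness, 2L)       # 5/7 good days >= 70%
  expect_equal(ds$timing, 2L)
  expect_equal(ds$total, 12L)
  expect_equal(ds$prop_alertness, 5 / 7)
})
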