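test_that("a constant trace has no outliers", {
  tr <- make_trace(seq(0, 100, by = 5), rep(5, 21), epoch = 5)
  expect_length(detect_outliers(tr), 0)
})

test_that("smooth circadian traces are not flagged", {
  fx <- generate_fixture("smooth", n_days = 2, epoch_minutes = 5, seed = 3)
  expect_length(detect_outliers(fx$trace), 0)
})

test_that("an isolated spike above both neighbours is the only flag", {
  set.seed(11)
  g <- smooth_day(289) + rnorm(289, sd = 0.05)
  sigma <- sqrt(mean((diff(g) - mean(diff(g)))^2))
  g[150] <- g[150] + 10 * sigma
  tr <- make_trace(seq(0, by = 5, length.out = 289), g, epoch = 5)
  flags <- detect_outliers(tr)
  expect_equal(flags, tr$readings$time[150])
  # agrees with the brute-force oracle
  expect_equal(match(flags, tr$readings$time), oracle_outliers(g))
})

test_that("flags are annotations: no reading is removed or altered", {
  fx <- generate_fixture("spiky", n_days = 1, epoch_minutes = 5, seed = 5)
  before <- fx$trace$readings
  tr <- flag_outliers(fx$trace)
  expect_gte(length(tr$outliers), 1)
  expect_identical(tr$readings, before)
})

test_that("outlier flagging survives a change of trace resolution", {
  # same underlying spike, described at 1-min and sub-sampled to 5-min
  set.seed(21)
  g1 <- smooth_day(1441) + rnorm(1441, sd = 0.05)
  spike_at <- 701  # minute 700: on the 5-min grid
  g1[spike_at] <- g1[spike_at] + 10 * sd(diff(g1))
  tr1 <- make_trace(0:1440, g1, epoch = 1)
  sub <- seq(1, 1441, by = 5)
  tr5 <- make_trace((sub - 1), g1[sub], epoch = 5)
  f1 <- detect_outliers(tr1)
  f5 <- detect_outliers(tr5)
  expect_true(tr1$readings$time[spike_at] %in% f1)
  expect_true(tr1$readings$time[spike_at] %in% f5)
})

test_that("complete-day determination counts native epochs", {
  fx <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 2)
  days <- segment_days(fx$trace)
  kept <- complete_day_filter(days, fx$trace)
  expect_equal(kept$day_index, 1L)
  expect_equal(kept$n_readings, 288L)
  # drop one reading -> 287 -> excluded
  tr2 <- fx$trace
  tr2$readings <- tr2$readings[-100, ]
  expect_equal(nrow(complete_day_filter(days, tr2)), 0)
  # 1-min day needs 1440
  fx1 <- generate_fixture("smooth", n_days = 1, epoch_minutes = 1, seed = 2)
  d1 <- segment_days(fx1$trace)
  expect_equal(complete_day_filter(d1, fx1$trace)$n_readings, 1440L)
})

test_that("approximal imputation mirrors the flanking index blocks", {
  # gap at native indices i=5..j=8: k = 5 + floor(4/2) - 1 = 6,
  # {SG5,SG6} <- {SG3,SG4} and {SG7,SG8} <- {SG9,SG10}
  fx <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 9)
  full <- fx$trace
  g <- full$readings$glucose
  tr <- full
  tr$readings <- tr$readings[-(5:8), ]
  days <- segment_days(tr)
  res <- approximal_impute(tr, days[1, ])
  expect_true(res$imputed)
  out <- res$trace$readings
  expect_equal(out$glucose[5:6], g[3:4])
  expect_equal(out$glucose[7:8], g[9:10])
  expect_equal(out$source[5:8],
               c(rep("imputed_approximal_left", 2),
                 rep("imputed_approximal_right", 2)))
  expect_equal(res$minutes_imputed, 20L)
  # the two halves are distinct sections, both distinct from observed data
  expect_length(unique(out$section[5:8]), 2)
  expect_false(any(out$section[5:8] == 1L))
  # imputed day now passes the complete-days filter
  expect_equal(nrow(complete_day_filter(days, res$trace)), 1)
})

test_that("a single missing epoch is filled from its right neighbour", {
  # gap length 1 at i = j: k = i + floor(1/2) - 1 = i - 1, so the left half
  # is empty and the whole gap belongs to the right half, sourced from j + 1
  fx <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 9)
  g <- fx$trace$readings$glucose
  tr <- fx$trace
  tr$readings <- tr$readings[-50, ]
  days <- segment_days(tr)
  res <- approximal_impute(tr, days[1, ])
  expect_true(res$imputed)
  expect_equal(res$trace$readings$glucose[50], g[51])
  expect_equal(res$trace$readings$source[50], "imputed_approximal_right")
})

test_that("gaps of 2 h or more make the day ineligible for approximal", {
  fx <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 9)
  tr <- fx$trace
  tr$readings <- tr$readings[-(20:44), ]  # 25 epochs = 125 min >= 2 h
  days <- segment_days(tr)
  res <- approximal_impute(tr, days[1, ])
  expect_false(res$imputed)
  expect_equal(res$reason, "gap_2h_or_longer")
  # a 115-min gap (23 epochs) is still eligible
  tr2 <- fx$trace
  tr2$readings <- tr2$readings[-(20:42), ]
  expect_true(approximal_impute(tr2, segment_days(tr2)[1, ])$imputed)
})

test_that("days with more than 6 h missing are never imputed", {
  fx <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 9)
  tr <- fx$trace
  # four separate 95-min gaps: each < 2 h, total 380 min > 6 h
  drop <- c(20:38, 60:78, 120:138, 180:198)
  tr$readings <- tr$readings[-drop, ]
  days <- segment_days(tr)
  expect_false(approximal_impute(tr, days[1, ])$imputed)
  expect_equal(approximal_impute(tr, days[1, ])$reason, "over_6h_missing")
  expect_false(otherday_impute(tr, days[1, ], days)$imputed)
})

test_that("imputation never alters observed readings", {
  fx <- generate_fixture("gappy", n_days = 3, epoch_minutes = 5, seed = 13)
  tr <- fx$trace
  days <- segment_days(tr)
  before <- tr$readings
  for (method in c("approximal", "otherday")) {
    res <- impute_missing(tr, days, method = method, seed = 4)
    obs <- res$trace$readings[res$trace$readings$source == "observed", ]
    expect_identical(obs$glucose, before$glucose)
    expect_identical(obs$time, before$time)
    expect_gte(res$n_days_imputed, 1)
  }
})

test_that("other-day imputation copies the donor's time-matched values", {
  fx <- generate_fixture("gappy", n_days = 2, epoch_minutes = 5, seed = 17)
  tr <- fx$trace
  days <- segment_days(tr)
  gap <- fx$truth$gap_spans[1, ]
  # single donor (day 1): copy semantics must be exact
  res <- otherday_impute(tr, days[gap$day, ], days, rng_seed = 99)
  expect_true(res$imputed)
  filled <- res$trace$readings
  in_gap <- filled$time >= gap$start & filled$time < gap$end
  expect_true(all(filled$source[in_gap] == "imputed_otherday"))
  donor <- tr$readings$time >= (gap$start - 86400) &
    tr$readings$time < (gap$end - 86400)
  expect_equal(filled$glucose[in_gap], tr$readings$glucose[donor])
})

test_that("other-day donor choice is reproducible from the seed", {
  fx <- generate_fixture("gappy", n_days = 5, epoch_minutes = 5, seed = 23)
  tr <- fx$trace
  days <- segment_days(tr)
  day <- days[2, ]
  g1 <- otherday_impute(tr, day, days, rng_seed = 7)$trace$readings$glucose
  g2 <- otherday_impute(tr, day, days, rng_seed = 7)$trace$readings$glucose
  expect_identical(g1, g2)
})

test_that("a day without any eligible donor is dropped, not imputed", {
  # two days, both missing the same clock-time span
  fx <- generate_fixture("meals", n_days = 2, epoch_minutes = 5, seed = 29)
  tr <- fx$trace
  m <- glucotrace:::minute_of_day(tr$readings$time)
  drop <- m >= 180 & m < 240  # 03:00-04:00 on both days
  tr$readings <- tr$readings[!drop, ]
  days <- segment_days(tr)
  res <- otherday_impute(tr, days[1, ], days)
  expect_false(res$imputed)
  expect_equal(res$reason, "no_eligible_donor_day")
  imp <- impute_missing(tr, days, method = "otherday", seed = 1)
  expect_equal(imp$n_days_imputed, 0L)
  expect_equal(nrow(complete_day_filter(imp$days, imp$trace)), 0)
})

test_that("the QC report counts are internally consistent", {
  fx <- generate_fixture("gappy", n_days = 3, epoch_minutes = 5, seed = 31)
  tr <- flag_outliers(fx$trace)
  days <- segment_days(tr)
  imp <- impute_missing(tr, days, method = "approximal")
  rep <- qc_report(imp$trace, imp$days)
  expect_lte(rep$summary$n_days_complete, rep$summary$n_days_total)
  expect_equal(rep$summary$n_days_imputed, imp$n_days_imputed)
  expect_equal(nrow(rep$days), nrow(imp$days))
  expect_true(all(rep$days$minutes_missing >= 0))
})
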