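test_that("AUC per minute is the time-averaged glucose", {
  expect_equal(auc_per_minute(rep(5, 1441)), 5)
  # linear ramp -> midpoint
  expect_equal(auc_per_minute(seq(4, 6, length.out = 1441)), 5)
  # hand trapezoid: ((4+6)/2 + (6+5)/2) / 2 = 5.25
  expect_equal(auc_per_minute(c(4, 6, 5)), 5.25)
  set.seed(1)
  x <- runif(200, 4, 9)
  expect_equal(auc_per_minute(x), oracle_auc(x))
})

test_that("range proportions follow the printed boundary semantics", {
  for (pop in c("general", "diabetes", "pregnancy")) {
    thr <- threshold_set(pop)
    # exactly at the hyper cutpoint -> hyper
    expect_equal(unname(time_in_ranges(thr$hyper_at_or_above, thr)),
                 c(0, 0, 1))
    # exactly at the hypo cutpoint -> normo
    expect_equal(unname(time_in_ranges(thr$hypo_below, thr)), c(0, 1, 0))
    # just below hypo -> hypo
    expect_equal(unname(time_in_ranges(thr$hypo_below - 1e-9, thr)),
                 c(1, 0, 0))
  }
  expect_equal(threshold_set("general")[c("hypo_below", "hyper_at_or_above")],
               list(hypo_below = 3.3, hyper_at_or_above = 10.0))
  expect_equal(threshold_set("diabetes")$hypo_below, 3.9)
  expect_equal(threshold_set("pregnancy")[c("hypo_below",
                                            "hyper_at_or_above")],
               list(hypo_below = 3.5, hyper_at_or_above = 7.8))
})

test_that("range proportions sum to one and match minute counting", {
  thr <- threshold_set("pregnancy")
  x <- c(rep(3.0, 720), rep(5.0, 720))
  p <- time_in_ranges(x, thr)
  expect_equal(unname(p), c(0.5, 0.5, 0))
  set.seed(2)
  for (rep in 1:20) {
    x <- runif(1440, 2, 12)
    p <- time_in_ranges(x, thr)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("MAD is the median absolute deviation about the median", {
  expect_equal(mad_glucose(rep(7, 100)), 0)
  expect_equal(mad_glucose(c(1, 2, 3, 4, 5)), 1)
  expect_equal(mad_glucose(c(1, 1, 1, 100)), 0)
  # unscaled counterpart of stats::mad
  set.seed(3)
  x <- rlnorm(500, log(5), 0.2)
  expect_equal(mad_glucose(x), stats::mad(x, constant = 1))
})

test_that("GVP is zero iff constant and doubles for the root-3 sawtooth", {
  expect_equal(gvp(rep(5, 100)), 0)
  saw <- 5 + cumsum(c(0, rep(c(sqrt(3), -sqrt(3)), 720)))[1:1440]
  expect_equal(gvp(saw), 100)
  # single segment: Pythagoras (3,4,5) -> 25%
  expect_equal(gvp(c(5, 8), minutes = c(0, 4)), 25)
  set.seed(4)
  for (rep in 1:20) expect_gte(gvp(runif(100, 4, 8)), 0)
})

test_that("GVP excludes transitions across section boundaries", {
  g <- c(5, 5, 5, 9, 9, 9)  # jump is a section boundary, not physiology
  sec <- c(1, 1, 1, 2, 2, 2)
  expect_equal(gvp(g, section = sec), 0)
  expect_gt(gvp(g), 0)
})

test_that("sGVP is invariant under affine rescaling of glucose", {
  set.seed(5)
  for (rep in 1:10) {
    x <- 5 + cumsum(rnorm(500, sd = 0.1))
    x <- pmax(x, 0.5)
    a <- runif(1, 0.2, 5)
    b <- runif(1, -1, 5)
    expect_equal(sgvp(a * x + b), sgvp(x), tolerance = 1e-9)
  }
})

test_that("sGVP of a constant trace is zero with a warning", {
  expect_warning(v <- sgvp(rep(5, 10)), "MAD is 0")
  expect_equal(v, 0)
})

test_that("sGVP is invariant to the native epoch of an equivalent shape", {
  # sawtooth described at 5-min native epochs, then resampled to 1-min,
  # matches the same shape written directly on the 1-min grid
  peaks <- 5 + rep(c(0, 1.5), 60)
  tr5 <- make_trace(seq(0, by = 5, length.out = 120), peaks, epoch = 5)
  rs <- resample_to_1min(tr5)
  direct <- approx(seq(0, by = 5, length.out = 120), peaks,
                   xout = 0:595)$y
  expect_equal(sgvp(rs$readings$glucose), sgvp(direct), tolerance = 1e-6)
})

test_that("summary statistics are duration-invariant", {
  set.seed(6)
  x <- 5 + cumsum(rnorm(300, sd = 0.08))
  x <- pmax(x, 1)
  double_x <- c(x, x)
  sec <- rep(1:2, each = 300)  # junction is a section break
  expect_equal(auc_per_minute(double_x, run = rep(1:2, each = 300)),
               auc_per_minute(x), tolerance = 1e-9)
  expect_equal(gvp(double_x, section = sec), gvp(x), tolerance = 1e-9)
  expect_equal(sgvp(double_x, section = sec), sgvp(x), tolerance = 1e-6)
  thr <- threshold_set()
  expect_equal(time_in_ranges(double_x, thr), time_in_ranges(x, thr))
  expect_equal(mad_glucose(double_x), mad_glucose(x))
})

test_that("the fasting proxy equals the sliding-window oracle", {
  expect_equal(fasting_proxy(rep(4.5, 450)), 4.5)
  dec <- seq(6, 4, length.out = 450)
  expect_equal(fasting_proxy(dec), mean(dec[421:450]))
  # planted trough amid a 5.0 baseline
  x <- rep(5, 450); x[200:229] <- 3.8
  expect_equal(fasting_proxy(x), 3.8)
  expect_equal(fasting_proxy(x), oracle_fasting(x))
  set.seed(7)
  for (rep in 1:25) {
    x <- runif(450, 3, 9)
    expect_equal(fasting_proxy(x), oracle_fasting(x))
  }
  expect_error(fasting_proxy(rep(5, 20)), "shorter")
})

test_that("time to peak applies the plateau-skipping rule", {
  expect_equal(time_to_peak(c(5, 6, 7, 6), 0:3, 0), 2)
  expect_equal(time_to_peak(c(5, 6, 7, 7, 7, 6), 0:5, 0), 2)
  # monotone rise to the end of day -> missing
  expect_true(is.na(time_to_peak(5 + 0:10 * 0.1, 0:10, 0)))
  # peak at or before the event does not count
  expect_equal(time_to_peak(c(5, 7, 5, 6, 8, 6), 0:5, 1), 3)
})

test_that("post-event AUC integrates the 15-min window at each horizon", {
  g <- rep(6, 200)
  expect_equal(post_event_auc(g, 0:199, 10, "1h"), 6)
  expect_equal(post_event_auc(g, 0:199, 10, "2h"), 6)
  ramp <- seq(4, 8, length.out = 200)
  # window [70, 85]: trapezoid of a line = its midpoint value
  expect_equal(post_event_auc(ramp, 0:199, 10, "1h"),
               mean(ramp[c(71, 86)]))
  # hand-computed trapezoid on a bumpy fixture
  set.seed(8)
  g2 <- runif(200, 4, 9)
  w <- g2[131:146]
  expect_equal(post_event_auc(g2, 0:199, 10, "2h"), oracle_auc(w))
  # window past the end of data -> missing
  expect_true(is.na(post_event_auc(g[1:60], 0:59, 10, "1h")))
})

test_that("per-day summaries carry the documented structure", {
  fx <- generate_fixture("meals", n_days = 2, epoch_minutes = 5, seed = 41)
  tr <- resample_to_1min(fx$trace)
  days <- segment_days(fx$trace)
  s <- summarise_trace(tr, days, save_events = TRUE)
  expect_equal(nrow(s$records), 6)  # 2 days x 3 scopes
  expect_setequal(unique(s$records$scope),
                  c("whole_day", "night", "day_time"))
  night <- s$records[s$records$scope == "night", ]
  expect_true(all(!is.na(night$fasting_proxy)))
  expect_true(all(is.na(s$records$fasting_proxy[s$records$scope !=
                                                  "night"])))
  expect_equal(night$n_minutes, c(450, 450))
  expect_equal(s$records$n_minutes[s$records$scope == "day_time"],
               c(990, 990))
  # proportions conserve
  expect_equal(s$records$prop_hypo + s$records$prop_normo +
                 s$records$prop_hyper, rep(1, 6), tolerance = 1e-9)
  # 3 meals per day, each with a post-meal rise -> event stats present
  wd <- s$records[s$records$scope == "whole_day", ]
  expect_true(all(!is.na(wd$tt_peak_meal)))
  expect_true(all(!is.na(wd$auc1h_meal)))
  expect_equal(nrow(s$events), 6)
})

test_that("across-day rows are unweighted means of the daily values", {
  fx <- generate_fixture("meals", n_days = 3, epoch_minutes = 5, seed = 43)
  tr <- resample_to_1min(fx$trace)
  days <- segment_days(fx$trace)
  s <- summarise_trace(tr, days)
  agg <- aggregate_summaries(s$records)
  expect_equal(nrow(agg), 9 + 3)
  for (sc in c("whole_day", "night", "day_time")) {
    m <- agg[agg$scope == paste0(sc, "_mean"), ]
    expect_equal(m$auc_per_min,
                 mean(s$records$auc_per_min[s$records$scope == sc]))
    expect_equal(m$mad, mean(s$records$mad[s$records$scope == sc]))
  }
  # one included day: mean equals that day's value
  fx1 <- generate_fixture("smooth", n_days = 1, epoch_minutes = 5, seed = 44)
  s1 <- summarise_trace(resample_to_1min(fx1$trace), segment_days(fx1$trace))
  a1 <- aggregate_summaries(s1$records)
  expect_equal(a1$auc_per_min[a1$scope == "whole_day_mean"],
               s1$records$auc_per_min[s1$records$scope == "whole_day"])
})

test_that("imputation boundaries do not leak into line-length statistics", {
  # one imputed day vs the same day fully observed: sGVP must be computed
  # only from within-section transitions
  fx <- generate_fixture("gappy", n_days = 2, epoch_minutes = 5, seed = 47)
  days <- segment_days(fx$trace)
  imp <- impute_missing(fx$trace, days, method = "otherday", seed = 3)
  rs <- resample_to_1min(imp$trace)
  s <- summarise_trace(rs, imp$days)
  day2 <- s$records[s$records$day_index == 2 & s$records$scope == "night", ]
  expect_equal(nrow(day2), 1)
  expect_gt(day2$n_minutes_imputed, 0)
  expect_true(is.finite(day2$sgvp))
  expect_gte(day2$sgvp, 0)
})
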