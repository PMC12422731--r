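test_that("jitter-free LD onsets are detected at lights-off", {
  p <- mouse_params(onset_jitter_min = 0, seed = 31)
  act <- simulate_activity(p, protocol(seg_ld(10)))
  on <- detect_onsets(act, 24)
  expect_true(all(abs(on$onset_min - 720) <= 1))
  expect_lt(onset_variability(on), 1)
})

test_that("DD slope recovers -24 min/day for tau = 23.6", {
  slopes <- vapply(1:10, function(s) {
    p <- mouse_params(tau_hours = 23.6, onset_jitter_min = 5, seed = s)
    act <- simulate_activity(p, protocol(seg_dd(10)))
    detect_onsets(act, 23.6)$fit_coef[2]
  }, 0)
  expect_lt(abs(mean(slopes) + 24), 2)
})

test_that("an all-zero trace yields missing onsets without crashing", {
  tr <- activity_trace(integer(1440 * 5), 1)
  on <- detect_onsets(tr, 24)
  expect_true(all(is.na(on$onset_min)))
  expect_equal(on$n_missing, 5L)
  expect_error(onset_variability(on), "non-missing")
})

test_that("onset variability: linear series give 0; invariances hold", {
  o <- onset_series(720 + (0:9) * 1430, day = 1:10)
  expect_equal(onset_variability(o), 0, tolerance = 1e-9)
  set.seed(32)
  base <- 720 + (0:9) * 1440 + rnorm(10, 0, 20)
  v0 <- onset_variability(onset_series(base, 1:10))
  # translation invariance
  expect_equal(onset_variability(onset_series(base + 90, 1:10)), v0)
  # adding a linear trend changes nothing
  expect_equal(onset_variability(onset_series(base + 3 * (1:10), 1:10)),
               v0, tolerance = 1e-9)
  # mean-absolute-residual variant is also available
  expect_lt(onset_variability(onset_series(base, 1:10), "mad"), v0 * 2)
  expect_error(onset_variability(onset_series(c(720, NA, NA, NA, NA,
                                                720, 700, NA, NA, 710),
                                              1:10)), "non-missing")
})

test_that("injected onset jitter is recovered from DD records", {
  for (j in c(5, 25)) {
    est <- vapply(1:20, function(s) {
      p <- mouse_params(tau_hours = 23.6, onset_jitter_min = j, seed = s)
      act <- simulate_activity(p, protocol(seg_dd(10)))
      onset_variability(detect_onsets(act, 23.6))
    }, 0)
    expect_lt(abs(mean(est) - j) / j, 0.3)
  }
})

test_that("bout segmentation honors the 21-min gap boundary", {
  mk <- function(x) activity_trace(x, 1)
  day <- integer(1440)
  day[100:200] <- 10
  expect_equal(count_activity_bouts(mk(day))$n_bouts, 1L)
  two20 <- integer(1440); two20[100:150] <- 10; two20[171:220] <- 10
  expect_equal(count_activity_bouts(mk(two20))$n_bouts, 1L)  # 20-min gap
  two21 <- integer(1440); two21[100:150] <- 10; two21[172:221] <- 10
  expect_equal(count_activity_bouts(mk(two21))$n_bouts, 2L)  # 21-min gap
})

test_that("bout counting matches the brute-force oracle on random traces", {
  set.seed(33)
  for (k in 1:300) {
    x <- rpois(1440, runif(1, 0.5, 4)) *
      rbinom(1440, 1, runif(1, 0.2, 0.9))
    got <- count_activity_bouts(activity_trace(x, 1))$n_bouts
    expect_identical(got, brute_activity_bouts(x))
  }
})

test_that("bout count is scale-invariant above threshold and monotone in gap", {
  set.seed(34)
  x <- rpois(1440 * 2, 1.2) * rbinom(1440 * 2, 1, 0.4)
  # scaling the supra-threshold counts leaves the segmentation unchanged
  x_scaled <- ifelse(x >= 3, x * 5, x)
  n1 <- count_activity_bouts(activity_trace(x, 1))$n_bouts
  n2 <- count_activity_bouts(activity_trace(x_scaled, 1))$n_bouts
  expect_identical(n1, n2)
  gaps <- c(5, 10, 21, 40)
  ns <- vapply(gaps, function(g)
    count_activity_bouts(activity_trace(x, 1), max_gap_min = g)$n_bouts,
    0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("windowed activity integrates the ZT window", {
  sch <- build_schedule(protocol(seg_ld(3)))
  tr <- activity_trace(rep(10, 3 * 1440), 1, schedule = sch)
  expect_equal(windowed_activity(tr, c(0, 3)), 1800)
  # night-only activity leaves ZT0-3 empty
  p <- mouse_params(onset_jitter_min = 0, rest_rate = 0, seed = 35)
  act <- simulate_activity(p, protocol(seg_ld(3)))
  expect_lt(windowed_activity(act, c(0, 3)),
            0.01 * windowed_activity(act, c(12, 24)))
  # day-% consistency: percentages from windows sum to 100
  tot <- windowed_activity(act, c(0, 24))
  expect_equal(windowed_activity(act, c(0, 12)) +
                 windowed_activity(act, c(12, 24)), tot)
  expect_error(windowed_activity(activity_trace(rep(1, 1440), 1),
                                 c(0, 3)), "schedule")
})
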