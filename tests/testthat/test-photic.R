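test_that("masking arithmetic, sign convention and scale invariance", {
  sch <- build_schedule(protocol(seg_ld(3)))
  x <- rep(0, 3 * 1440)
  zt14 <- function(d) (d - 1) * 1440 + 14 * 60 + 1
  x[zt14(2):(zt14(2) + 59)] <- 100 / 60    # baseline day: 100 counts
  x[zt14(3):(zt14(3) + 59)] <- 25 / 60     # light day: 25 counts
  tr <- activity_trace(x, 1, schedule = sch)
  r <- masking_suppression(tr, 3)
  expect_equal(r$percent_suppression, 75)
  tr2 <- activity_trace(x * 2, 1, schedule = sch)
  expect_equal(masking_suppression(tr2, 3)$percent_suppression, 75)
  # no suppression when light equals baseline
  x[zt14(3):(zt14(3) + 59)] <- 100 / 60
  expect_equal(masking_suppression(activity_trace(x, 1, schedule = sch),
                                   3)$percent_suppression, 0)
  # zero baseline flagged undefined
  x0 <- rep(0, 3 * 1440)
  r0 <- masking_suppression(activity_trace(x0, 1, schedule = sch), 3)
  expect_true(r0$undefined)
})

test_that("simulated masking coefficient is recovered", {
  pr <- protocol(seg_ld(4), pulses = list(light_pulse(3, 14, 60, "zt")))
  for (m in c(0.3, 0.8)) {
    p <- mouse_params(onset_jitter_min = 0, masking_coeff = m)
    est <- vapply(1:60, function(s)
      masking_suppression(simulate_activity(p, pr, seed = s),
                          3)$percent_suppression / 100, 0)
    expect_lt(abs(mean(est) - m), 0.1)
  }
})

test_that("days_to_reentrain finds the first full aligned run", {
  # aligned from day 6 on
  onset_abs <- c(360, 300, 240, 180, 120, rep(c(10, -8, 5, 0, 12, -4,
                                                7, 2, -10, 6), 2)[1:10]) +
    720 + (0:14) * 1440
  os <- onset_series(onset_abs, day = 1:15)
  expect_equal(days_to_reentrain(os, 720), 6)
  # a broken run postpones re-entrainment to the next full run
  onset_abs2 <- onset_abs
  onset_abs2[8] <- 720 + 7 * 1440 + 200   # day 8 breaks the run
  os2 <- onset_series(onset_abs2, day = 1:15)
  expect_equal(days_to_reentrain(os2, 720), 9)
  # never aligned: sentinel
  far <- onset_series(720 + 300 + (0:9) * 1440, day = 1:10)
  r <- days_to_reentrain(far, 720)
  expect_true(is.na(r))
  expect_false(attr(r, "reentrained"))
  # monotone non-increasing in tolerance
  tols <- c(10, 30, 60, 120)
  ds <- vapply(tols, function(tl)
    as.integer(days_to_reentrain(os, 720, tol_min = tl)), 0L)
  expect_true(all(diff(ds) <= 0))
})

test_that("simulated 6-h advance at 1 h/day re-entrains in 6 +/- 1 days", {
  est <- vapply(1:25, function(s) {
    p <- mouse_params(tau_hours = 24, onset_jitter_min = 5,
                      reentrain_rate_h_per_day = 1, seed = s)
    act <- simulate_activity(p, protocol(seg_ld(4), seg_ld(14,
                                                           advance_h = 6)))
    on <- detect_onsets(act, 24)
    post <- onset_series(on$onset_abs_min[5:18], day = 1:14)
    new_off <- act$schedule$days$zt0_min[5] + 720
    as.integer(days_to_reentrain(post, new_off))
  }, 0L)
  expect_lt(abs(mean(est) - 6), 1)
})

test_that("phase shift from pre/post lines: exact cases and recovery", {
  pre <- onset_series(720 + (0:9) * 1440, day = 1:10)
  post_same <- onset_series(720 + (11:20) * 1440, day = 12:21)
  expect_equal(phase_shift(pre, post_same, 11), 0, tolerance = 1e-9)
  post_60 <- onset_series(780 + (11:20) * 1440, day = 12:21)
  expect_equal(phase_shift(pre, post_60, 11), -60, tolerance = 1e-9)
  expect_error(phase_shift(pre, onset_series(720 + (10:19) * 1440,
                                             day = 11:20), 11), "after")
  # simulated CT16 pulse with a 64-min programmed delay
  pr <- protocol(seg_dd(21), pulses = list(light_pulse(11, 16, 15, "ct")))
  est <- vapply(1:40, function(s) {
    p <- mouse_params(tau_hours = 23.6, onset_jitter_min = 15,
                      phase_shift_delay_min = 64, seed = s)
    on <- detect_onsets(simulate_activity(p, pr), 23.6)
    phase_shift(onset_series(on$onset_abs_min[1:10], day = 1:10),
                onset_series(on$onset_abs_min[12:21], day = 12:21), 11)
  }, 0)
  expect_lt(abs(mean(est) + 64), 10)
})

test_that("SPP metrics separate entrained and free-running animals", {
  pr <- protocol(seg_ld(3), seg_spp(14))
  wt <- simulate_activity(mouse_preset("wt", seed = 41), pr)
  ko <- simulate_activity(mouse_preset("ko", seed = 41), pr)
  mw <- spp_metrics(wt, n_days = 10, start_day = 7)
  mk <- spp_metrics(ko, n_days = 10, start_day = 7)
  expect_true(mw$entrained)
  expect_equal(mw$tau_h, 24, tolerance = 0.1)
  expect_false(mk$entrained)
  expect_lt(mk$tau_h, 24)
  expect_gt(mk$day_activity_pct, mw$day_activity_pct)
  # a night-only entrained animal has near-zero day activity
  p0 <- mouse_params(onset_jitter_min = 0, rest_rate = 0,
                     masking_coeff = 0, seed = 42)
  m0 <- spp_metrics(simulate_activity(p0, pr), n_days = 10, start_day = 7)
  expect_lt(m0$day_activity_pct, 3)
})
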