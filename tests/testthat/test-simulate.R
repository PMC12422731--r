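test_that("parameter invariants are enforced", {
  expect_error(mouse_params(tau_hours = 19), "tau")
  expect_error(mouse_params(masking_coeff = 1.2), "masking")
  expect_error(mouse_params(sleep_bout_mean_day_min = 0), "bout means")
  p <- mouse_params(active_rate = 30, rest_rate = NA,
                    activity_frac_night = 0.9)
  expect_equal(p$rest_rate, 30 * 0.1 / 0.9)
})

test_that("zero-jitter LD onsets sit exactly at lights-off", {
  p <- mouse_params(onset_jitter_min = 0, seed = 2)
  act <- simulate_activity(p, protocol(seg_ld(10)))
  truth <- attr(act, "truth")
  expect_equal(truth$onsets %% 1440, rep(720, length(truth$onsets)))
})

test_that("DD anchors advance by (24 - tau) h per day", {
  p <- mouse_params(tau_hours = 23.5, onset_jitter_min = 0)
  a <- predicted_onsets(p, protocol(seg_dd(10)))
  tod <- a$anchor_min - (a$cycle - 1) * 1440
  expect_equal(diff(tod), rep(-30, nrow(a) - 1))
})

test_that("nocturnal light suppresses the active rate by 1 - m", {
  # 1-h light at ZT14: mean counts in that hour ~ 0.3 x active baseline
  m <- 0.7
  p <- mouse_params(onset_jitter_min = 0, masking_coeff = m,
                    active_rate = 30, rest_rate = 0)
  pr <- protocol(seg_ld(3), pulses = list(light_pulse(2, 14, 60, "zt")))
  tots <- vapply(1:100, function(s) {
    act <- simulate_activity(p, pr, seed = s)
    i0 <- 1440 + 14 * 60
    sum(act$counts[(i0 + 1):(i0 + 60)])
  }, 0)
  exp_mean <- (1 - m) * 30 * 60
  expect_lt(abs(mean(tots) - exp_mean) / exp_mean, 0.05)
})

test_that("generators are deterministic given the seed", {
  p <- mouse_preset("wt", seed = 7)
  pr <- protocol(seg_ld(3))
  expect_identical(simulate_activity(p, pr)$counts,
                   simulate_activity(p, pr)$counts)
  expect_identical(simulate_immobility(p, pr)$flags,
                   simulate_immobility(p, pr)$flags)
  expect_false(identical(simulate_activity(p, pr, seed = 8)$counts,
                         simulate_activity(p, pr)$counts))
})

test_that("immobility phase structure follows the day/night bout means", {
  p <- mouse_params(sleep_bout_mean_day_min = 22,
                    sleep_bout_mean_night_min = 9,
                    wake_bout_mean_day_min = 12,
                    wake_bout_mean_night_min = 28, seed = 3)
  im <- simulate_immobility(p, protocol(seg_ld(2)))
  sch <- im$schedule
  day_idx <- rep(to_zt((seq_len(2 * 1440) - 0.5), sch) < 12, each = 60)
  f_day <- mean(im$flags[day_idx])
  f_night <- mean(im$flags[!day_idx])
  expect_gt(f_day, f_night)   # more immobile in the light phase
  # scored mean day bout length exceeds night bout length (direction)
  sl <- score_sleep(im)
  smd <- sleep_metrics(sl, "day")
  smn <- sleep_metrics(sl, "night")
  expect_gt(smd$mean_bout_min, smn$mean_bout_min)
})

test_that("infinite wake bouts give an all-mobile trace and zero sleep", {
  p <- mouse_params(wake_bout_mean_day_min = Inf,
                    wake_bout_mean_night_min = Inf, seed = 4)
  im <- simulate_immobility(p, protocol(seg_ld(2)))
  sl <- score_sleep(im)
  expect_equal(sum(sl$counts), 0)
  expect_equal(sleep_metrics(sl, "24h")$duration_min, 0)
})

test_that("profile generator: determinism, degenerate cases, jitter SD", {
  pf0 <- simulate_profiles(4, 100, 12, 50, 0, 0, seed = 1)
  expect_true(all(vapply(pf0[-1], function(y)
    identical(as.numeric(y), as.numeric(pf0[[1]])), TRUE)))
  flat <- simulate_profiles(3, 100, 12, 0, 0, 0, seed = 1)
  expect_true(all(vapply(flat, function(y) sd(y) == 0, TRUE)))
  pf <- simulate_profiles(200, 120, 12, 60, 1, 10, n_bins = 300, seed = 2)
  peaks <- vapply(pf, attr, 0, "true_peak")
  expect_lt(abs(sd(peaks) - 10) / 10, 0.2)
})

test_that("group-table generator respects shapes and seeds", {
  eff <- list(WT = list(powV = c(45, 5), bouts = c(21, 3)),
              KO = list(powV = c(30, 5), bouts = c(24, 3)))
  tab <- simulate_group_table(8, eff, seed = 5)
  expect_equal(nrow(tab), 16)
  expect_equal(sort(unique(tab$group)), c("KO", "WT"))
  expect_identical(tab, simulate_group_table(8, eff, seed = 5))
  expect_error(simulate_group_table(8, list(A = list(x = c(0, -1))),
                                    seed = 1), "SD")
  # 5-SD separation is detected in every replicate
  eff2 <- list(A = list(x = c(0, 1)), B = list(x = c(5, 1)))
  ps <- vapply(1:20, function(s)
    gated_two_group_test(simulate_group_table(6, eff2, seed = s)$x[1:6],
                         simulate_group_table(6, eff2, seed = s)$x[7:12])$p,
    0)
  expect_true(all(ps < 0.05))
})
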