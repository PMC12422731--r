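test_that("LD schedule maps ZT correctly and light intervals are sane", {
  sch <- build_schedule(protocol(seg_ld(3)))
  expect_equal(sch$n_days, 3L)
  expect_equal(to_zt(720, sch), 12)        # lights-off is ZT12
  expect_equal(to_zt(0, sch), 0)
  expect_equal(to_zt(1440 + 360, sch), 6)
  expect_true(all(light_at(sch, c(0, 300, 719))))
  expect_false(any(light_at(sch, c(720, 1000, 1439))))
})

test_that("phase advance shifts ZT0 and DD queries are gated", {
  sch <- build_schedule(protocol(seg_ld(2), seg_ld(2, advance_h = 6)))
  # on day 3 lights come on 6 h earlier
  expect_equal(sch$days$zt0_min[3], 2 * 1440 - 360)
  expect_equal(to_zt(2 * 1440, sch), 6)
  schd <- build_schedule(protocol(seg_ld(1), seg_dd(2)))
  expect_error(to_zt(2000, schd), "DD epoch")
  expect_equal(to_zt(2000, schd, projected = TRUE),
               ((2000 - 0) / 60) %% 24)
})

test_that("SPP schedule places the two skeleton pulses", {
  sch <- build_schedule(protocol(seg_spp(2)))
  expect_true(all(light_at(sch, c(0, 30, 660 + 5))))
  expect_false(any(light_at(sch, c(61, 300, 725, 1400))))
})

test_that("protocol YAML round-trips", {
  pr <- protocol(seg_ld(5), seg_dd(10),
                 pulses = list(light_pulse(12, 16, 15, "ct")),
                 feeding = c(15, 21))
  path <- withr::local_tempfile(fileext = ".yml")
  write_protocol(pr, path)
  pr2 <- read_protocol(path)
  expect_equal(build_schedule(pr2), build_schedule(pr))
  expect_equal(pr2$pulses[[1]]$at, 16)
  expect_equal(pr2$feeding, c(15, 21))
})

test_that("trace CSV round-trips bit-exactly and rejects bad rows", {
  set.seed(5)
  tr <- activity_trace(rpois(200, 8), bin_min = 6, units = "rev")
  tr$counts[17] <- NA                       # missing bin survives
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_identical(tr2$counts, tr$counts)
  expect_equal(tr2$bin_min, 6)
  expect_equal(tr2$units, "rev")
  im <- immobility_trace(rbinom(120, 1, 0.5))
  write_trace(im, path)
  expect_identical(read_trace(path)$flags, im$flags)
  # negative count rejected with its line number
  lines <- readLines({write_trace(tr, path); path})
  lines[8] <- "12,-3"
  writeLines(lines, path)
  expect_error(read_trace(path), "negative counts.*8")
  lines[8] <- "12,4"; lines[9] <- "bogus,4"
  writeLines(lines, path)
  expect_error(read_trace(path), "malformed rows.*9")
})

test_that("a 1-min 10-day record has 14400 rows and rebins consistently", {
  tr <- activity_trace(rep(1, 14400), bin_min = 1)
  expect_equal(trace_days(tr), 10)
  r6 <- rebin(tr, 6)
  expect_equal(length(r6$counts), 2400)
  expect_true(all(r6$counts == 6))
})

test_that("fold_daily averages cycles and a mismatched fold smears", {
  # square wave with 24-h period folds back exactly at its own period
  x <- rep(rep(c(0, 10), each = 720), 10)
  tr <- activity_trace(x, bin_min = 1)
  w24 <- fold_daily(tr, 24, out_bin_min = 60)
  expect_equal(w24$mean, rep(c(0, 600), each = 12))
  expect_equal(w24$sem, rep(0, 24))
  # constant trace: flat waveform (counts summed per 1-h bin), SEM 0
  wc <- fold_daily(activity_trace(rep(3, 1440 * 2), 1), 24)
  expect_true(all(wc$mean == 180) && all(wc$sem == 0))
  # 23.5-h signal folded at 24 h loses amplitude relative to its own period
  per <- 23.5 * 60
  t <- seq_len(47 * 1440)
  x2 <- as.numeric((t %% per) < per / 2) * 10
  tr2 <- activity_trace(x2, bin_min = 1)
  amp_own <- diff(range(fold_daily(tr2, 23.5, out_bin_min = 6)$mean))
  amp_24 <- diff(range(fold_daily(tr2, 24, out_bin_min = 6)$mean))
  expect_lt(amp_24, amp_own)
})

test_that("ZT/CT conversions agree with hand arithmetic", {
  # onsets drifting -30 min/day (tau 23.5): CT16 sits 4 * tau / 24 h
  # after the predicted onset
  onset_abs <- 720 + (0:9) * (23.5 * 60)
  os <- onset_series(onset_abs[1:10], day = 1:10)
  tau_min <- 23.5 * 60
  t_ct16 <- onset_abs[4] + 4 / 24 * tau_min
  expect_equal(to_ct(t_ct16, os), 16, tolerance = 1e-6)
  expect_equal(to_ct(onset_abs[6], os), 12, tolerance = 1e-6)
})
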