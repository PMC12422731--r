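#' Photic suppression of nocturnal activity (negative masking)
#'
#' Compares activity during a 1-h nocturnal light exposure with the same
#' clock hour on the preceding (baseline) day.  Reported as
#' `100 * (baseline - light) / baseline`, so positive values mean
#' suppression; the measure is invariant to rescaling the counts.
#'
#' @param trace an [activity_trace()] with a schedule.
#' @param light_day calendar day (1-based) of the light exposure.
#' @param zt_window window of the exposure in ZT hours (default ZT14-15).
#' @return list with `percent_suppression`, `baseline`, `light`, and an
#'   `undefined` flag (TRUE when the baseline is zero).
#' @export
masking_suppression <- function(trace, light_day, zt_window = c(14, 15)) {
  stopifnot(inherits(trace, "activity_trace"), light_day >= 2)
  sched <- trace$schedule
  if (is.null(sched)) stop("trace has no schedule")
  counts_in <- function(day) {
    z0 <- sched$days$zt0_min[day]
    t0 <- z0 + zt_window[1] * 60
    t1 <- z0 + zt_window[2] * 60
    mid <- trace$start_min + (seq_along(trace$counts) - 0.5) * trace$bin_min
    sum(trace$counts[mid >= t0 & mid < t1], na.rm = TRUE)
  }
  base <- counts_in(light_day - 1)
  light <- counts_in(light_day)
  if (base == 0)
    return(list(percent_suppression = NA_real_, baseline = 0,
                light = light, undefined = TRUE))
  list(percent_suppression = 100 * (base - light) / base,
       baseline = base, light = light, undefined = FALSE)
}

#' Days to re-entrain after a shift of the light schedule
#'
#' The first post-shift day `d` such that the activity onset stays within
#' `tol_min` of the new lights-off for `run` consecutive days starting at
#' `d`.
#'
#' @param onsets an `onset_series` covering the post-shift days (day 1 =
#'   first day after the shift).
#' @param new_lights_off_min absolute minute of the new lights-off on each
#'   post-shift day: either a vector (one per onset day) or a single value
#'   for day 1 (subsequent days advance by 1440 min).
#' @param tol_min alignment tolerance, minutes.
#' @param run required number of consecutive aligned days.
#' @return integer day (1-based after the shift), or `NA` with attribute
#'   `reentrained = FALSE` when the criterion is never met.
#' @export
days_to_reentrain <- function(onsets, new_lights_off_min, tol_min = 30,
                              run = 5) {
  stopifnot(inherits(onsets, "onset_series"))
  n <- onsets$n_days
  if (n < run) stop("need at least `run` post-shift days with onsets")
  target <- if (length(new_lights_off_min) == 1)
    new_lights_off_min + (onsets$day - onsets$day[1]) * 1440
  else new_lights_off_min
  dev <- abs(onsets$onset_abs_min - target)
  aligned <- !is.na(dev) & dev <= tol_min
  for (d in seq_len(n - run + 1)) {
    if (all(aligned[d:(d + run - 1)])) return(d)
  }
  structure(NA_integer_, reentrained = FALSE)
}

#' Light-pulse phase shift from pre/post onset regressions
#'
#' Fits least-squares lines to the onset-vs-day series before and after
#' the pulse and evaluates both on the day after the pulse; the shift is
#' the pre-line minus the post-line there, so delays (later onsets) are
#' negative.
#'
#' @param onsets_pre,onsets_post `onset_series` objects indexed by
#'   calendar day on a common timebase, each with >= 5 non-missing
#'   onsets; the post window must not include the pulse day.
#' @param pulse_day calendar day of the pulse.
#' @return phase shift in minutes (negative = delay).
#' @export
phase_shift <- function(onsets_pre, onsets_post, pulse_day) {
  stopifnot(inherits(onsets_pre, "onset_series"),
            inherits(onsets_post, "onset_series"))
  for (o in list(onsets_pre, onsets_post))
    if (sum(!is.na(o$onset_min)) < 5)
      stop("need >= 5 non-missing onsets on each side of the pulse")
  if (any(onsets_post$day <= pulse_day))
    stop("post window must start after the pulse day")
  line_at <- function(o, d) o$fit_coef[1] + o$fit_coef[2] * d
  unname(line_at(onsets_pre, pulse_day + 1) -
           line_at(onsets_post, pulse_day + 1))
}

#' Rhythm metrics under a skeleton photoperiod
#'
#' Delegates to the periodogram and activity modules with the SPP
#' schedule defining the subjective day: ZT0-12 is the span bracketed by
#' the two 1-h pulses.  "Activity in the day (%)" is
#' `100 * counts in ZT0-12 / total`.
#'
#' @param trace an [activity_trace()] recorded under an SPP segment with
#'   its schedule attached (>= 10 SPP days).
#' @param n_days days used for the periodogram and onset fits.
#' @param range_h,bin_min periodogram settings (see
#'   [chi2_periodogram()]).
#' @param start_day first day of the analysis window.
#' @return list with `tau_h`, `rhythmic_power`, `day_activity_pct`,
#'   `onset_variability_min`, `entrained` (tau within one grid step of
#'   24 h), and the underlying periodogram.
#' @export
spp_metrics <- function(trace, n_days = 10, range_h = c(20, 28),
                        bin_min = 6, start_day = 1) {
  stopifnot(inherits(trace, "activity_trace"))
  if (floor(trace_days(trace)) - start_day + 1 < n_days)
    stop("need >= 10 SPP days")
  pg <- chi2_periodogram(trace, range_h = range_h, bin_min = bin_min,
                         n_days = n_days, start_day = start_day)
  day_tot <- windowed_activity(trace, c(0, 12), n_days = NULL)
  all_tot <- windowed_activity(trace, c(0, 24), n_days = NULL)
  onsets <- detect_onsets(trace, expected_period_h = 24)
  ov <- tryCatch(onset_variability(onsets), error = function(e) NA_real_)
  grid_h <- bin_min / 60
  entrained <- !is.na(pg$tau_h) && abs(pg$tau_h - 24) <= grid_h + 1e-9
  list(tau_h = pg$tau_h, rhythmic_power = pg$rhythmic_power,
       day_activity_pct = 100 * day_tot / all_tot,
       onset_variability_min = ov, entrained = entrained,
       periodogram = pg)
}
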