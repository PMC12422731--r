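#' Detect daily activity onsets
#'
#' Template-correlation onset detector.  For each calendar day the onset
#' candidate maximises the correlation of the per-minute activity profile
#' with a step template (`template_h` hours of -1 followed by
#' `template_h` hours of +1), searched within +/- `search_h` hours of the
#' previous onset plus the expected period.  The candidate is refined to
#' the first minute at or above `threshold` counts/min that follows at
#' least `quiescence_h` hours below threshold, when such a point exists
#' inside the search window (sparse-activity records); otherwise the
#' template maximum stands.
#'
#' Onsets are reported as (possibly unwrapped) time-of-day in minutes, so
#' that a free-running record gives a linear onset-vs-day series whose
#' slope is `(tau - 24) * 60` min/day.
#'
#' @param trace an [activity_trace()] (>= 3 days).
#' @param expected_period_h expected cycle length used to propagate the
#'   search window, hours.
#' @param threshold activity threshold, counts/min.
#' @param template_h half-width of the step template, hours.
#' @param search_h half-width of the search window, hours.
#' @param quiescence_h quiescent span required before a threshold
#'   crossing, hours.
#' @return object of class `onset_series`: data.frame-like list with
#'   `day`, `onset_min` (unwrapped time-of-day, NA for arrhythmic days),
#'   `onset_abs_min`, the least-squares `fit_coef` (intercept, slope
#'   min/day), `resid_sd_min`, `n_days`.
#' @export
detect_onsets <- function(trace, expected_period_h = 24, threshold = 3,
                          template_h = 6, search_h = 6,
                          quiescence_h = 4) {
  stopifnot(inherits(trace, "activity_trace"))
  tr <- if (trace$bin_min > 1) trace else rebin(trace, 1)
  if (tr$bin_min != 1) {
    # onset detection needs 1-min resolution: spread coarser bins evenly
    x <- rep(tr$counts / tr$bin_min, each = tr$bin_min)
  } else x <- tr$counts
  x[is.na(x)] <- 0
  total <- length(x)
  n_days <- floor(total / 1440)
  if (n_days < 3) stop("need at least 3 days for onset detection")
  w <- as.integer(template_h * 60)
  cs <- c(0, cumsum(x))
  # step-template score for candidate onset minutes t (1-based index of
  # the first active minute): counts in [t, t+w) minus counts in [t-w, t)
  corr_at <- function(t) (cs[t + w] - cs[t]) - (cs[t] - cs[t - w])
  period <- expected_period_h * 60
  sw <- as.integer(search_h * 60)
  qmin <- as.integer(quiescence_h * 60)
  quiet <- c(0, cumsum(x >= threshold))
  onset_abs <- rep(NA_real_, n_days)
  prev <- NA_real_
  guess <- NA_real_
  for (d in seq_len(n_days)) {
    center <- if (is.na(prev)) (d - 1) * 1440 + 720 + period - 1440
              else prev + period
    cand_rng <- max(w + 1, round(center - sw)):min(total - w + 1,
                                                   round(center + sw))
    if (!length(cand_rng)) { prev <- center; next }
    ext_lo <- max(cand_rng[1] - w, 1)
    ext_hi <- min(cand_rng[length(cand_rng)] + w - 1, total)
    if (cs[ext_hi + 1] - cs[ext_lo] == 0) {
      prev <- center   # arrhythmic/empty day: no candidate
      next
    }
    t_hat <- cand_rng[which.max(corr_at(cand_rng))]
    # threshold refinement within the search window
    win <- cand_rng
    above <- x[win] >= threshold
    if (any(above)) {
      ref <- NA_integer_
      for (m in win[above]) {
        if (m - qmin >= 1 && (quiet[m] - quiet[m - qmin]) == 0) {
          ref <- m; break
        }
      }
      if (!is.na(ref)) t_hat <- ref
    }
    onset_abs[d] <- t_hat - 1   # minutes, 0-based time
    prev <- t_hat - 1
  }
  tod <- onset_abs - (seq_len(n_days) - 1) * 1440
  ok <- !is.na(tod)
  fit_coef <- c(NA_real_, NA_real_); rsd <- NA_real_
  if (sum(ok) >= 3) {
    fit <- stats::lm(tod[ok] ~ seq_len(n_days)[ok])
    fit_coef <- unname(stats::coef(fit))
    if (sum(ok) > 2)
      rsd <- sqrt(sum(stats::resid(fit)^2) / (sum(ok) - 2))
  }
  structure(list(day = seq_len(n_days), onset_min = tod,
                 onset_abs_min = onset_abs, fit_coef = fit_coef,
                 resid_sd_min = rsd, n_days = n_days,
                 n_missing = sum(!ok)),
            class = "onset_series")
}

#' Build an onset series from known onset times
#'
#' Wraps per-day onset times (absolute minutes) into an `onset_series`
#' with the same regression bookkeeping as [detect_onsets()]; useful for
#' assembling pre/post windows for [phase_shift()] or for simulated
#' ground truth.
#'
#' @param onset_abs_min absolute onset times in minutes, one per day (NA
#'   for missing days).
#' @param day calendar day indices (default `1:length(onset_abs_min)`).
#' @export
onset_series <- function(onset_abs_min, day = seq_along(onset_abs_min)) {
  tod <- onset_abs_min - (day - 1) * 1440
  ok <- !is.na(tod)
  fit_coef <- c(NA_real_, NA_real_); rsd <- NA_real_
  if (sum(ok) >= 3) {
    fit <- stats::lm(tod[ok] ~ day[ok])
    fit_coef <- unname(stats::coef(fit))
    rsd <- sqrt(sum(stats::resid(fit)^2) / (sum(ok) - 2))
  }
  structure(list(day = day, onset_min = tod,
                 onset_abs_min = onset_abs_min, fit_coef = fit_coef,
                 resid_sd_min = rsd, n_days = length(day),
                 n_missing = sum(!ok)),
            class = "onset_series")
}

#' @export
print.onset_series <- function(x, ...) {
  cat(sprintf("onset_series: %d days, %d missing\n", x$n_days,
              x$n_missing))
  if (!anyNA(x$fit_coef))
    cat(sprintf(
      "  fit: onset = %.1f %+.2f min/day (period %.2f h), resid SD %.1f min\n",
      x$fit_coef[1], x$fit_coef[2], (1440 + x$fit_coef[2]) / 60,
      x$resid_sd_min))
  invisible(x)
}

#' Onset variability (imprecision)
#'
#' Cycle-to-cycle variability of the activity onset: the SD of the
#' residuals about the least-squares onset-vs-day line, with an `n - 2`
#' denominator (or the mean absolute residual with `method = "mad"`).
#'
#' @param onsets an `onset_series` with >= 5 non-missing onsets.
#' @param method `"sd"` (default) or `"mad"` (mean absolute residual).
#' @return minutes.
#' @export
onset_variability <- function(onsets, method = c("sd", "mad")) {
  method <- match.arg(method)
  stopifnot(inherits(onsets, "onset_series"))
  ok <- !is.na(onsets$onset_min)
  if (sum(ok) < 5) stop("need >= 5 non-missing onsets")
  fit <- stats::lm(onsets$onset_min[ok] ~ onsets$day[ok])
  r <- stats::resid(fit)
  if (method == "sd") sqrt(sum(r^2) / (length(r) - 2)) else mean(abs(r))
}

#' Count activity bouts (fragmentation)
#'
#' Segments the per-minute activity record into bouts: minutes at or
#' above `threshold` counts/min belong to the same bout when the
#' sub-threshold gap separating them is shorter than `max_gap_min`; a gap
#' of `max_gap_min` or more starts a new bout.  Reported as bouts per
#' day.
#'
#' @param trace an [activity_trace()] (>= 1 day).
#' @param threshold counts/min.
#' @param max_gap_min minimum sub-threshold gap that splits bouts,
#'   minutes.
#' @param n_days number of days to analyse (default: all complete days).
#' @return list with `bouts_per_day`, `n_bouts`, `n_days`, and the bout
#'   table (`start`, `end` minute indices, `total_counts` including
#'   sub-threshold minutes inside the bout).
#' @export
count_activity_bouts <- function(trace, threshold = 3, max_gap_min = 21,
                                 n_days = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  tr <- rebin(trace, 1)
  x <- tr$counts
  x[is.na(x)] <- 0
  avail <- floor(length(x) / 1440)
  if (avail < 1) stop("need >= 1 complete day")
  if (is.null(n_days)) n_days <- avail
  x <- x[seq_len(n_days * 1440)]
  pos <- which(x >= threshold)
  if (!length(pos)) {
    return(list(bouts_per_day = 0, n_bouts = 0L, n_days = n_days,
                bouts = data.frame(start = integer(0), end = integer(0),
                                   total_counts = numeric(0))))
  }
  gap <- diff(pos) - 1            # sub-threshold minutes between actives
  newb <- c(TRUE, gap >= max_gap_min)
  id <- cumsum(newb)
  start <- pos[newb]
  end <- pos[c(newb[-1], TRUE)]
  cs <- c(0, cumsum(x))
  total_counts <- cs[end + 1] - cs[start]
  list(bouts_per_day = max(id) / n_days, n_bouts = max(id),
       n_days = n_days,
       bouts = data.frame(start = start, end = end,
                          total_counts = total_counts))
}

#' Activity within a ZT window
#'
#' Mean daily total counts inside a ZT window across the complete days of
#' the record.  The window may wrap midnight (e.g. `c(22, 2)`).
#'
#' @param trace an [activity_trace()] with a schedule.
#' @param zt_window `c(start, end)` in ZT hours.
#' @param n_days number of days to analyse (default: all complete days).
#' @param projected allow projected ZT during DD (see [to_zt()]).
#' @return mean counts per day in the window.
#' @export
windowed_activity <- function(trace, zt_window, n_days = NULL,
                              projected = FALSE) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(trace$schedule))
    stop("trace has no schedule: ZT undefined")
  avail <- floor(trace_days(trace))
  if (avail < 1) stop("need >= 1 complete day")
  if (is.null(n_days)) n_days <- avail
  nb <- n_days * 1440 / trace$bin_min
  counts <- trace$counts[seq_len(nb)]
  mid <- trace$start_min + (seq_len(nb) - 0.5) * trace$bin_min
  zt <- to_zt(mid, trace$schedule, projected = projected)
  a <- zt_window[1]; b <- zt_window[2]
  in_win <- if (a <= b) zt >= a & zt < b else zt >= a | zt < b
  sum(counts[in_win], na.rm = TRUE) / n_days
}
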