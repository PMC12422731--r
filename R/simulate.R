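#' Virtual-mouse parameters
#'
#' Ground-truth parameters of the stochastic virtual mouse.  The activity
#' generator is a square-wave rate model: the animal is "active" for half
#' of each circadian cycle starting at its predicted onset and "at rest"
#' otherwise; per-bin counts are Poisson with the corresponding rate.
#' Nocturnal light multiplies the active-state rate by `1 - masking_coeff`
#' (negative masking).  Immobility is an alternating-renewal process with
#' exponential bout durations whose means differ between the (subjective)
#' day and night.
#'
#' @param tau_hours free-running period, hours (20-28).
#' @param onset_jitter_min SD of the daily activity-onset noise, minutes.
#' @param active_rate mean counts/min in the active state.
#' @param rest_rate mean counts/min at rest; if `NA` it is derived from
#'   `activity_frac_night` as `active_rate * (1 - f) / f`, which makes the
#'   expected fraction of counts falling in the 12-h active phase equal
#'   `f`.
#' @param activity_frac_night target fraction of daily activity occurring
#'   in the active (dark) phase.
#' @param masking_coeff multiplicative suppression of the active rate
#'   under nocturnal light, in `[0, 1]`.
#' @param phase_shift_delay_min asymptotic phase delay produced by a CT16
#'   light pulse, minutes (positive number = delay magnitude).
#' @param reentrain_rate_h_per_day maximal daily phase adjustment toward a
#'   shifted light schedule, h/day.
#' @param sleep_bout_mean_day_min,sleep_bout_mean_night_min mean immobile
#'   bout durations, minutes.
#' @param wake_bout_mean_day_min,wake_bout_mean_night_min mean mobile bout
#'   durations, minutes.
#' @param seed default RNG seed used by the generators.
#' @return an object of class `mouse_params`.
#' @export
mouse_params <- function(tau_hours = 23.8, onset_jitter_min = 10,
                         active_rate = 25, rest_rate = NA,
                         activity_frac_night = 0.92,
                         masking_coeff = 0.7,
                         phase_shift_delay_min = 120,
                         reentrain_rate_h_per_day = 1,
                         sleep_bout_mean_day_min = 20,
                         sleep_bout_mean_night_min = 9,
                         wake_bout_mean_day_min = 12,
                         wake_bout_mean_night_min = 28,
                         seed = 1L) {
  if (tau_hours < 20 || tau_hours > 28) stop("tau_hours must be in [20, 28]")
  if (masking_coeff < 0 || masking_coeff > 1)
    stop("masking_coeff must be in [0, 1]")
  if (is.na(rest_rate)) {
    f <- activity_frac_night
    stopifnot(f > 0, f <= 1)
    rest_rate <- active_rate * (1 - f) / f
  }
  rates <- c(active_rate, rest_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  bouts <- c(sleep_bout_mean_day_min, sleep_bout_mean_night_min,
             wake_bout_mean_day_min, wake_bout_mean_night_min)
  if (any(bouts <= 0)) stop("bout means must be > 0")
  structure(list(tau_hours = tau_hours, onset_jitter_min = onset_jitter_min,
                 active_rate = active_rate, rest_rate = rest_rate,
                 activity_frac_night = activity_frac_night,
                 masking_coeff = masking_coeff,
                 phase_shift_delay_min = phase_shift_delay_min,
                 reentrain_rate_h_per_day = reentrain_rate_h_per_day,
                 sleep_bout_mean_day_min = sleep_bout_mean_day_min,
                 sleep_bout_mean_night_min = sleep_bout_mean_night_min,
                 wake_bout_mean_day_min = wake_bout_mean_day_min,
                 wake_bout_mean_night_min = wake_bout_mean_night_min,
                 seed = as.integer(seed)), class = "mouse_params")
}

#' Named virtual-mouse presets
#'
#' Two qualitative presets bracketing the phenotypes contrasted in the
#' package's validation suite.  The "wt" preset is a precisely entrained
#' nocturnal mouse; "ko" is its degraded counterpart: noisier onsets, more
#' light-phase activity, weaker masking, slower re-entrainment, a smaller
#' light-evoked phase delay and shorter, more fragmented daytime sleep.
#' Values are central tendencies, not fits.
#'
#' @param which `"wt"` or `"ko"`.
#' @param seed RNG seed stored in the preset.
#' @export
mouse_preset <- function(which = c("wt", "ko"), seed = 1L) {
  which <- match.arg(which)
  if (which == "wt")
    mouse_params(tau_hours = 23.6, onset_jitter_min = 8,
                 active_rate = 25.3, rest_rate = 2.3,
                 activity_frac_night = 0.92,
                 masking_coeff = 0.78,
                 phase_shift_delay_min = 136,
                 reentrain_rate_h_per_day = 1.0,
                 sleep_bout_mean_day_min = 22.4,
                 sleep_bout_mean_night_min = 9.0,
                 wake_bout_mean_day_min = 12.4,
                 wake_bout_mean_night_min = 26.6,
                 seed = seed)
  else
    mouse_params(tau_hours = 23.4, onset_jitter_min = 25,
                 active_rate = 27.6, rest_rate = 6.1,
                 activity_frac_night = 0.82,
                 masking_coeff = 0.33,
                 phase_shift_delay_min = 64,
                 reentrain_rate_h_per_day = 0.53,
                 sleep_bout_mean_day_min = 13,
                 sleep_bout_mean_night_min = 9.5,
                 wake_bout_mean_day_min = 9.5,
                 wake_bout_mean_night_min = 34.7,
                 seed = seed)
}

# Deterministic per-cycle onset anchors under a protocol.
#
# LD: the anchor is pulled toward lights-off, limited to
# reentrain_rate_h_per_day per cycle (so a stable 12:12 cycle locks the
# anchor exactly when the daily pull covers |24 - tau|).  DD: the anchor
# advances by tau each cycle; a CT16 pulse adds the full phase delay on the
# following cycle.  SPP: like LD but with half the zeitgeber strength.
resolve_anchors <- function(params, proto, schedule = build_schedule(proto)) {
  tau_min <- params$tau_hours * 60
  pull_ld <- params$reentrain_rate_h_per_day * 60
  total <- schedule$total_min
  dtab <- schedule$days
  day_of <- function(t) min(max(floor(t / 1440) + 1, 1), schedule$n_days)
  seg_type <- function(t) dtab$type[day_of(t)]
  nearest_lights_off <- function(t) {
    z0 <- dtab$zt0_min[day_of(t)]
    off <- z0 + 720
    off + round((t - off) / 1440) * 1440
  }
  first_type <- dtab$type[1]
  a0 <- if (first_type == "dd") 720 else dtab$zt0_min[1] + 720
  anchors <- a0
  pulse_abs <- NULL
  ct_pulses <- Filter(function(p) p$frame == "ct", proto$pulses)
  pending <- 0
  t <- a0
  while (t < total + tau_min) {
    naive <- t + tau_min + pending
    pending <- 0
    # a CT pulse falling between this anchor and the next delays the next
    for (p in ct_pulses) {
      pt <- t + (p$at - 12) / 24 * tau_min
      if (pt >= t && pt < t + tau_min &&
          day_of(pt) == p$day && !any(abs(pulse_abs - pt) < 1e-6)) {
        pulse_abs <- rbind(pulse_abs, c(pt, pt + p$duration_min))
        naive <- naive + params$phase_shift_delay_min
      }
    }
    ty <- seg_type(min(naive, total - 1))
    nxt <- if (ty == "dd") naive else {
      pull <- if (ty == "spp") pull_ld * 0.5 else pull_ld
      target <- nearest_lights_off(naive)
      delta <- target - naive
      naive + sign(delta) * min(abs(delta), pull)
    }
    anchors <- c(anchors, nxt)
    t <- nxt
  }
  if (!is.null(pulse_abs)) {
    schedule$light <- rbind(schedule$light, pulse_abs)
    schedule$light <- schedule$light[order(schedule$light[, 1]), ,
                                     drop = FALSE]
  }
  list(anchors = anchors[anchors < total], schedule = schedule)
}

#' Ground-truth activity onsets predicted by the virtual-mouse model
#'
#' Deterministic (jitter-free) per-cycle onset anchors; mainly useful as
#' the reference in recovery experiments.
#' @param params a [mouse_params()].
#' @param proto a [protocol()].
#' @return data.frame with `cycle` and `anchor_min` (absolute minutes).
#' @export
predicted_onsets <- function(params, proto) {
  a <- resolve_anchors(params, proto)$anchors
  data.frame(cycle = seq_along(a), anchor_min = a)
}

#' Simulate an activity trace
#'
#' Per-bin Poisson counts from the square-wave rate model described in
#' [mouse_params()], under an arbitrary lighting protocol.  The realised
#' (jittered) onsets are kept in the result as ground truth.
#'
#' @param params a [mouse_params()].
#' @param proto a [protocol()] spanning at least 1 day.
#' @param bin_min bin width in minutes; must divide 60.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param units unit tag, `"rev"` (wheel) or `"a.u."` (infrared).
#' @return an [activity_trace()] with attributes `truth` (list with the
#'   jittered onsets and the anchors) and `params`.
#' @export
simulate_activity <- function(params, proto, bin_min = 1,
                              seed = params$seed, units = "rev") {
  stopifnot(inherits(params, "mouse_params"), inherits(proto, "protocol"))
  if (bin_min <= 0 || 60 %% bin_min != 0) stop("bin_min must divide 60")
  res <- resolve_anchors(params, proto)
  schedule <- res$schedule
  anchors <- res$anchors
  total <- schedule$total_min
  set.seed(seed)
  onsets <- anchors + stats::rnorm(length(anchors), 0,
                                   params$onset_jitter_min)
  t_min <- seq_len(total) - 1
  active_frac <- rep(0, total)
  for (o in onsets) {
    ov <- pmin(t_min + 1, o + 720) - pmax(t_min, o)
    active_frac <- pmax(active_frac, pmin(pmax(ov, 0), 1))
  }
  lf <- light_fraction(schedule, t_min, 1)
  mu <- params$rest_rate * (1 - active_frac) +
    params$active_rate * active_frac * (1 - params$masking_coeff * lf)
  nb <- total / bin_min
  mu_bin <- rowsum(mu, rep(seq_len(nb), each = bin_min))[, 1]
  counts <- stats::rpois(nb, mu_bin)
  tr <- activity_trace(counts, bin_min = bin_min, schedule = schedule,
                       units = units)
  attr(tr, "truth") <- list(onsets = onsets, anchors = anchors)
  attr(tr, "params") <- params
  attr(tr, "seed") <- seed
  tr
}

# probability that a second inside an immobile bout registers as mobile,
# and that a second inside a mobile bout registers as immobile (tracker
# noise); fixed model constants
.immobile_flip <- 0.02
.mobile_still <- 0.05

#' Simulate a per-second immobility trace
#'
#' Alternating immobile/mobile bouts with exponential durations; the bout
#' mean is chosen by the phase (day vs night) at the bout start.  Under LD
#' the phase follows the light schedule; in DD the subjective night is the
#' 12 h following each onset anchor.  A small fixed per-second flip noise
#' emulates tracker error.
#'
#' @inheritParams simulate_activity
#' @return an [immobility_trace()].
#' @export
simulate_immobility <- function(params, proto, seed = params$seed) {
  stopifnot(inherits(params, "mouse_params"), inherits(proto, "protocol"))
  res <- resolve_anchors(params, proto)
  schedule <- res$schedule
  total_s <- schedule$total_min * 60
  dtab <- schedule$days
  night_iv <- NULL
  for (d in seq_len(schedule$n_days)) {
    if (dtab$type[d] == "dd") next
    z0 <- dtab$zt0_min[d]
    night_iv <- rbind(night_iv, c(z0 + 720, z0 + 1440))
  }
  for (a in res$anchors) {
    d <- floor(a / 1440) + 1
    if (d >= 1 && d <= schedule$n_days && dtab$type[d] == "dd")
      night_iv <- rbind(night_iv, c(a, a + 720))
  }
  is_night <- function(t_min) {
    if (is.null(night_iv)) return(FALSE)
    any(t_min >= night_iv[, 1] & t_min < night_iv[, 2])
  }
  set.seed(seed)
  flags <- integer(total_s)
  t <- 0                      # seconds
  immobile <- FALSE           # start mobile: animal freshly handled
  while (t < total_s) {
    night <- is_night(t / 60)
    m <- if (immobile) {
      if (night) params$sleep_bout_mean_night_min
      else params$sleep_bout_mean_day_min
    } else {
      if (night) params$wake_bout_mean_night_min
      else params$wake_bout_mean_day_min
    }
    dur <- if (is.finite(m)) max(1L, round(stats::rexp(1, 1 / (m * 60))))
           else total_s
    idx <- seq.int(t + 1, min(t + dur, total_s))
    flags[idx] <- as.integer(immobile)
    t <- t + dur
    immobile <- !immobile
  }
  flip <- stats::runif(total_s)
  noisy <- ifelse(flags == 1L, as.integer(flip >= .immobile_flip),
                  as.integer(flip < .mobile_still))
  tr <- immobility_trace(noisy, schedule = schedule)
  attr(tr, "params") <- params
  attr(tr, "seed") <- seed
  tr
}

#' Simulate 1-D intensity profiles
#'
#' Gaussian bump over a flat baseline with additive noise and per-section
#' peak-position jitter; emulates densitometric profile plots of tracer
#' fluorescence across a fixed ROI.
#'
#' @param n_sections number of profiles (>= 1).
#' @param peak_pos true peak position, bins.
#' @param peak_sd Gaussian width of the bump, bins (> 0).
#' @param amplitude bump amplitude, arbitrary units.
#' @param noise_sd additive noise SD, arbitrary units.
#' @param jitter_bins SD of the per-section peak-position offset, bins.
#' @param n_bins profile length, bins.
#' @param baseline baseline intensity, arbitrary units.
#' @param side `"left"` or `"right"` tag carried on each profile.
#' @param seed RNG seed.
#' @return list of `intensity_profile` objects (numeric vectors with
#'   attributes `side`, `section`, `true_peak`).
#' @export
simulate_profiles <- function(n_sections, peak_pos, peak_sd, amplitude,
                              noise_sd, jitter_bins, n_bins = 240,
                              baseline = 50, side = "left", seed = 1L) {
  stopifnot(n_sections >= 1)
  if (peak_sd <= 0) stop("peak_sd must be > 0")
  if (noise_sd < 0 || jitter_bins < 0) stop("SDs must be >= 0")
  set.seed(seed)
  x <- seq_len(n_bins)
  lapply(seq_len(n_sections), function(s) {
    p <- peak_pos + stats::rnorm(1, 0, jitter_bins)
    y <- baseline + amplitude * exp(-(x - p)^2 / (2 * peak_sd^2)) +
      stats::rnorm(n_bins, 0, noise_sd)
    y <- pmax(y, 0)
    structure(y, side = side, section = s, true_peak = p,
              class = "intensity_profile")
  })
}

#' Simulate a per-animal group metric table
#'
#' Independent normal draws for each metric within each group; fixtures
#' for the group-statistics layer.
#'
#' @param n_per_group animals per group (>= 2).
#' @param effects named list: one element per group, each a named list of
#'   metrics mapping to `c(mean, sd)`.
#' @param factors optional data.frame keyed by `group` adding factor
#'   columns (e.g. genotype, treatment) to the output.
#' @param seed RNG seed.
#' @return data.frame with `animal`, `group`, any factor columns, and one
#'   column per metric.
#' @export
simulate_group_table <- function(n_per_group, effects, factors = NULL,
                                 seed = 1L) {
  stopifnot(n_per_group >= 2, length(effects) >= 1)
  metrics <- names(effects[[1]])
  set.seed(seed)
  rows <- lapply(names(effects), function(g) {
    spec <- effects[[g]]
    stopifnot(identical(sort(names(spec)), sort(metrics)))
    vals <- lapply(metrics, function(m) {
      ms <- spec[[m]]
      if (ms[2] < 0) stop("SD must be >= 0")
      stats::rnorm(n_per_group, ms[1], ms[2])
    })
    names(vals) <- metrics
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(animal = sprintf("a%03d", seq_len(nrow(tab))), tab)
  if (!is.null(factors))
    tab <- merge(tab, factors, by = "group", sort = FALSE)
  tab
}
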