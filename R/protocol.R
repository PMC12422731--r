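#' Lighting protocol segments
#'
#' A protocol is an ordered list of lighting segments plus optional timed
#' light pulses and an optional daily feeding window.  Segments are built
#' with `seg_ld()` (12:12 light/dark, optionally phase-advanced),
#' `seg_dd()` (constant darkness) and `seg_spp()` (skeleton photoperiod,
#' two 1-h light pulses at ZT0-1 and ZT11-12 separated by 11 h of dark).
#'
#' The experiment timebase is minutes from the start of day 1; at time 0
#' lights turn on (ZT0) for protocols that start in LD.
#'
#' @param days number of days the segment lasts (> 0).
#' @param advance_h phase advance in hours applied at the start of the
#'   segment (positive = lights-on earlier), cumulative across segments.
#' @return a protocol segment (list) for use in [protocol()].
#' @export
seg_ld <- function(days, advance_h = 0) {
  stopifnot(days > 0)
  structure(list(type = "ld", days = as.integer(days),
                 advance_h = advance_h), class = "protocol_segment")
}

#' @rdname seg_ld
#' @export
seg_dd <- function(days) {
  stopifnot(days > 0)
  structure(list(type = "dd", days = as.integer(days), advance_h = 0),
            class = "protocol_segment")
}

#' @rdname seg_ld
#' @param pulse1_start,pulse2_start start of the two skeleton pulses, in ZT
#'   hours; defaults give the 1L:11D:1L:11D cycle.
#' @param pulse_len_h duration of each skeleton pulse, hours.
#' @export
seg_spp <- function(days, pulse1_start = 0, pulse2_start = 11,
                    pulse_len_h = 1) {
  stopifnot(days > 0, pulse_len_h > 0)
  if (pulse1_start + pulse_len_h > pulse2_start &&
      pulse2_start + pulse_len_h > pulse1_start)
    stop("skeleton photoperiod pulses overlap")
  structure(list(type = "spp", days = as.integer(days), advance_h = 0,
                 pulse1_start = pulse1_start, pulse2_start = pulse2_start,
                 pulse_len_h = pulse_len_h), class = "protocol_segment")
}

#' Timed light pulse
#'
#' A discrete light exposure, placed either at a Zeitgeber time (resolved
#' against the schedule) or at a circadian time (resolved against the
#' animal's own predicted onset, so only the simulator or an onset fit can
#' place it on the absolute timebase).
#'
#' @param day calendar day (1-based) on which the pulse occurs.
#' @param at time of the pulse in hours, ZT or CT depending on `frame`.
#' @param duration_min pulse duration in minutes.
#' @param frame `"zt"` or `"ct"`.
#' @export
light_pulse <- function(day, at, duration_min, frame = c("zt", "ct")) {
  frame <- match.arg(frame)
  stopifnot(day >= 1, duration_min > 0)
  structure(list(day = as.integer(day), at = at,
                 duration_min = duration_min, frame = frame),
            class = "light_pulse")
}

#' Assemble a lighting/feeding protocol
#'
#' @param ... protocol segments (see [seg_ld()]).
#' @param pulses optional list of [light_pulse()] events.
#' @param feeding optional feeding window `c(zt_start, zt_end)` in hours
#'   within 0-24 (e.g. `c(15, 21)` for a 6-h window in the middle of the
#'   active phase); `NULL` means ad libitum.
#' @return an object of class `protocol`.
#' @export
protocol <- function(..., pulses = list(), feeding = NULL) {
  segments <- list(...)
  if (length(segments) == 1L && is.list(segments[[1]]) &&
      !inherits(segments[[1]], "protocol_segment"))
    segments <- segments[[1]]
  if (!length(segments)) stop("protocol needs at least one segment")
  ok <- vapply(segments, inherits, logical(1), "protocol_segment")
  if (!all(ok)) stop("all segments must be built with seg_ld/seg_dd/seg_spp")
  if (inherits(pulses, "light_pulse")) pulses <- list(pulses)
  if (!is.null(feeding)) {
    stopifnot(length(feeding) == 2, all(feeding >= 0), all(feeding <= 24))
  }
  structure(list(segments = segments, pulses = pulses, feeding = feeding),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("Lighting protocol,", protocol_days(x), "days\n")
  for (s in x$segments) {
    lab <- switch(s$type,
      ld  = sprintf("LD 12:12%s",
                    if (s$advance_h != 0)
                      sprintf(" (phase advance %g h)", s$advance_h) else ""),
      dd  = "DD",
      spp = sprintf("SPP %gL:%gD (pulses ZT %g and ZT %g)",
                    s$pulse_len_h, 12 - s$pulse_len_h,
                    s$pulse1_start, s$pulse2_start))
    cat(sprintf("  %3d d  %s\n", s$days, lab))
  }
  for (p in x$pulses)
    cat(sprintf("  pulse: day %d, %s %g h, %g min\n",
                p$day, toupper(p$frame), p$at, p$duration_min))
  if (!is.null(x$feeding))
    cat(sprintf("  feeding window ZT %g-%g\n", x$feeding[1], x$feeding[2]))
  invisible(x)
}

#' Total protocol length in days
#' @param x a `protocol`.
#' @export
protocol_days <- function(x) sum(vapply(x$segments, `[[`, 0L, "days"))

#' Build the light schedule implied by a protocol
#'
#' Expands a [protocol()] into per-day bookkeeping: the segment type, the
#' absolute minute of ZT0 for every day (lights-on, projected through DD
#' from the last lit segment), and the list of absolute light intervals.
#' ZT-frame pulses are resolved here; CT-frame pulses can only be placed by
#' the simulator (which knows the anchor) and are added to the schedule it
#' returns.
#'
#' @param proto a `protocol`.
#' @return an object of class `light_schedule` with elements `days`
#'   (data.frame: `day`, `type`, `start_min`, `zt0_min`), `light`
#'   (two-column matrix of absolute on/off minutes), `feeding`, `n_days`,
#'   `total_min`.
#' @export
build_schedule <- function(proto) {
  stopifnot(inherits(proto, "protocol"))
  day_type <- character(0); day_adv <- numeric(0)
  seg_extra <- list()
  adv <- 0
  for (s in proto$segments) {
    adv <- adv + s$advance_h
    day_type <- c(day_type, rep(s$type, s$days))
    day_adv <- c(day_adv, rep(adv, s$days))
    seg_extra <- c(seg_extra, rep(list(s), s$days))
  }
  n_days <- length(day_type)
  start_min <- (seq_len(n_days) - 1) * 1440
  zt0_min <- start_min - day_adv * 60
  light <- NULL
  for (d in seq_len(n_days)) {
    z0 <- zt0_min[d]
    if (day_type[d] == "ld") {
      light <- rbind(light, c(z0, z0 + 720))
    } else if (day_type[d] == "spp") {
      s <- seg_extra[[d]]
      light <- rbind(light,
                     c(z0 + s$pulse1_start * 60,
                       z0 + (s$pulse1_start + s$pulse_len_h) * 60),
                     c(z0 + s$pulse2_start * 60,
                       z0 + (s$pulse2_start + s$pulse_len_h) * 60))
    }
  }
  pulse_int <- NULL
  for (p in proto$pulses) {
    if (p$frame == "zt") {
      if (p$day > n_days) stop("pulse day beyond protocol")
      t0 <- zt0_min[p$day] + p$at * 60
      pulse_int <- rbind(pulse_int, c(t0, t0 + p$duration_min))
    }
  }
  light <- rbind(light, pulse_int)
  if (!is.null(light)) light <- light[order(light[, 1]), , drop = FALSE]
  structure(list(
    days = data.frame(day = seq_len(n_days), type = day_type,
                      start_min = start_min, zt0_min = zt0_min),
    light = light,
    feeding = proto$feeding,
    n_days = n_days,
    total_min = n_days * 1440), class = "light_schedule")
}

#' Is the light on at a given time?
#'
#' @param schedule a `light_schedule`.
#' @param t_min absolute time(s) in minutes.
#' @return logical vector.
#' @export
light_at <- function(schedule, t_min) {
  li <- schedule$light
  if (is.null(li)) return(rep(FALSE, length(t_min)))
  out <- rep(FALSE, length(t_min))
  for (k in seq_len(nrow(li)))
    out <- out | (t_min >= li[k, 1] & t_min < li[k, 2])
  out
}

# fraction of [t, t+w) minutes that are lit, vectorised over t
light_fraction <- function(schedule, t_min, w = 1) {
  li <- schedule$light
  if (is.null(li)) return(rep(0, length(t_min)))
  out <- rep(0, length(t_min))
  for (k in seq_len(nrow(li))) {
    ov <- pmin(t_min + w, li[k, 2]) - pmax(t_min, li[k, 1])
    out <- out + pmax(ov, 0)
  }
  pmin(out / w, 1)
}

#' Write / read a protocol as YAML
#'
#' Plain-text round-trip of the protocol definition (segments, pulses,
#' feeding window).
#' @param proto a `protocol`.
#' @param path file path.
#' @export
write_protocol <- function(proto, path) {
  segs <- lapply(proto$segments, function(s) unclass(s))
  pls <- lapply(proto$pulses, function(p) unclass(p))
  yaml::write_yaml(list(segments = segs, pulses = pls,
                        feeding = proto$feeding), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- lapply(y$segments, function(s) {
    switch(s$type,
      ld  = seg_ld(s$days, s$advance_h),
      dd  = seg_dd(s$days),
      spp = seg_spp(s$days, s$pulse1_start, s$pulse2_start, s$pulse_len_h),
      stop("unknown segment type: ", s$type))
  })
  pls <- lapply(y$pulses, function(p)
    light_pulse(p$day, p$at, p$duration_min, p$frame))
  protocol(segs, pulses = pls, feeding = unlist(y$feeding))
}
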