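#' Activity and immobility trace containers
#'
#' An `activity_trace` holds uniformly binned non-negative activity counts
#' on an absolute minute timebase (bin timestamps are bin starts, bins are
#' half-open `[t, t + bin)`), with a link to the [build_schedule()] light
#' schedule that defines ZT.  An `immobility_trace` holds per-second 0/1
#' immobility flags.
#'
#' @param counts integer activity counts per bin (NA allowed for missing).
#' @param bin_min bin width, minutes.
#' @param schedule a `light_schedule` covering the trace, or `NULL`.
#' @param units `"rev"` for wheel revolutions, `"a.u."` for infrared.
#' @param start_min absolute start time of the first bin, minutes.
#' @export
activity_trace <- function(counts, bin_min = 1, schedule = NULL,
                           units = "rev", start_min = 0) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  if (bin_min <= 0) stop("bin_min must be > 0")
  structure(list(counts = counts, bin_min = bin_min, start_min = start_min,
                 schedule = schedule, units = units),
            class = "activity_trace")
}

#' @rdname activity_trace
#' @param flags per-second 0/1 immobility flags.
#' @param start_s absolute start time, seconds.
#' @export
immobility_trace <- function(flags, schedule = NULL, start_s = 0) {
  flags <- as.integer(flags)
  if (any(!flags %in% c(0L, 1L) & !is.na(flags)))
    stop("immobility flags must be 0/1")
  structure(list(flags = flags, schedule = schedule, start_s = start_s),
            class = "immobility_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("activity_trace: %d bins of %g min (%.1f days), units %s\n",
              length(x$counts), x$bin_min,
              length(x$counts) * x$bin_min / 1440, x$units))
  if (anyNA(x$counts))
    cat(sprintf("  %d missing bins\n", sum(is.na(x$counts))))
  invisible(x)
}

#' @export
print.immobility_trace <- function(x, ...) {
  cat(sprintf("immobility_trace: %d s (%.1f days), %.1f%% immobile\n",
              length(x$flags), length(x$flags) / 86400,
              100 * mean(x$flags, na.rm = TRUE)))
  invisible(x)
}

#' Trace duration in days
#' @param trace an `activity_trace` or `immobility_trace`.
#' @export
trace_days <- function(trace) {
  if (inherits(trace, "activity_trace"))
    length(trace$counts) * trace$bin_min / 1440
  else length(trace$flags) / 86400
}

#' Re-bin an activity trace
#'
#' Aggregates counts into wider bins (sum); the new width must be a
#' multiple of the old.  NA propagates into any bin containing it.
#' @param trace an `activity_trace`.
#' @param bin_min new bin width, minutes.
#' @export
rebin <- function(trace, bin_min) {
  stopifnot(inherits(trace, "activity_trace"))
  if (bin_min == trace$bin_min) return(trace)
  r <- bin_min / trace$bin_min
  if (r != round(r) || r < 1)
    stop("new bin width must be a multiple of the old")
  n <- floor(length(trace$counts) / r)
  idx <- rep(seq_len(n), each = r)
  counts <- rowsum(trace$counts[seq_len(n * r)], idx)[, 1]
  activity_trace(counts, bin_min = bin_min, schedule = trace$schedule,
                 units = trace$units, start_min = trace$start_min)
}

#' Write / read traces as headered CSV
#'
#' Dialect: comment header lines `# key: value` (`type`, `start`,
#' `bin_min` or `hz`, `units`), then a `timestamp,value` body.  Missing
#' values are written as empty fields.  `read_trace` rejects malformed
#' rows with their line numbers.
#'
#' @param trace an `activity_trace` or `immobility_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(trace, "activity_trace")) {
    writeLines(c("# type: activity",
                 sprintf("# start: %.10g", trace$start_min),
                 sprintf("# bin_min: %.10g", trace$bin_min),
                 sprintf("# units: %s", trace$units),
                 "t_min,count"), con)
    ts <- trace$start_min + (seq_along(trace$counts) - 1) * trace$bin_min
    vals <- ifelse(is.na(trace$counts), "",
                   formatC(trace$counts, format = "fg"))
    writeLines(paste(formatC(ts, format = "fg"), vals, sep = ","), con)
  } else if (inherits(trace, "immobility_trace")) {
    writeLines(c("# type: immobility",
                 sprintf("# start: %.10g", trace$start_s),
                 "# hz: 1",
                 "t_s,immobile"), con)
    ts <- trace$start_s + seq_along(trace$flags) - 1
    vals <- ifelse(is.na(trace$flags), "", as.character(trace$flags))
    writeLines(paste(ts, vals, sep = ","), con)
  } else stop("unsupported trace type")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(kv$type)) stop("missing 'type' header")
  if (is.null(kv$start)) stop("missing 'start' header")
  body_start <- max(hdr_idx) + 2   # skip the column-name row
  body <- lines[seq(body_start, length(lines))]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) < 1 |
                 vapply(parts, function(p) is.na(suppressWarnings(
                   as.numeric(p[1]))), logical(1)))
  if (length(bad))
    stop("malformed rows at lines: ",
         paste(bad + body_start - 1, collapse = ", "))
  ts <- vapply(parts, function(p) as.numeric(p[1]), 0)
  val_chr <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  vals <- suppressWarnings(as.numeric(val_chr))
  bad_val <- which(nzchar(val_chr) & is.na(vals))
  if (length(bad_val))
    stop("non-numeric values at lines: ",
         paste(bad_val + body_start - 1, collapse = ", "))
  if (any(diff(ts) <= 0))
    stop("non-monotone timestamps at line ",
         which(diff(ts) <= 0)[1] + body_start)
  if (kv$type == "activity") {
    if (is.null(kv$bin_min)) stop("missing 'bin_min' header")
    neg <- which(vals < 0)
    if (length(neg))
      stop("negative counts at lines: ",
           paste(neg + body_start - 1, collapse = ", "))
    activity_trace(vals, bin_min = as.numeric(kv$bin_min),
                   units = kv$units %||% "a.u.",
                   start_min = as.numeric(kv$start))
  } else if (kv$type == "immobility") {
    if (any(!vals %in% c(0, 1) & !is.na(vals)))
      stop("immobility values must be 0/1")
    immobility_trace(vals, start_s = as.numeric(kv$start))
  } else stop("unknown trace type: ", kv$type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert absolute time to Zeitgeber time
#'
#' ZT0 is lights-on.  During DD the schedule's projected ZT (carried from
#' the last lit segment) is used only when `projected = TRUE`; otherwise
#' querying a DD epoch is an error, since ZT is undefined without a light
#' cycle.
#'
#' @param t_min absolute time(s), minutes.
#' @param schedule a `light_schedule`.
#' @param projected allow projected ZT during DD epochs.
#' @return ZT in hours, in `[0, 24)`.
#' @export
to_zt <- function(t_min, schedule, projected = FALSE) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(t_min < 0 | t_min >= schedule$total_min))
    stop("timestamp outside schedule span")
  d <- pmin(floor(t_min / 1440) + 1, schedule$n_days)
  if (!projected && any(schedule$days$type[d] == "dd"))
    stop("ZT queried during a DD epoch (use projected = TRUE)")
  ((t_min - schedule$days$zt0_min[d]) / 60) %% 24
}

#' Convert absolute time to circadian time
#'
#' CT12 is the regression-predicted activity onset for the covering cycle;
#' one circadian hour is 1/24 of the fitted period.
#'
#' @param t_min absolute time(s), minutes.
#' @param onsets an `onset_series` (see [detect_onsets()]) with a fitted
#'   line.
#' @return CT in hours, in `[0, 24)`.
#' @export
to_ct <- function(t_min, onsets) {
  stopifnot(inherits(onsets, "onset_series"))
  cf <- onsets$fit_coef
  if (is.null(cf) || anyNA(cf)) stop("no onset fit available for CT")
  period_min <- 1440 + cf[2]
  # absolute predicted onset on calendar day d: a + b d + 1440 (d - 1)
  d <- floor((t_min - cf[1] + 1440) / period_min)
  o_abs <- cf[1] + cf[2] * d + 1440 * (d - 1)
  (12 + 24 * (t_min - o_abs) / period_min) %% 24
}

#' Fold a trace into an average daily waveform
#'
#' Folds an activity trace (or the per-minute series of a
#' [score_sleep()] result) at a trial period and returns the per-bin mean
#' and SEM across the folded cycles.
#'
#' @param trace an `activity_trace`.
#' @param period_h folding period, hours.
#' @param out_bin_min output bin width, minutes; the period must be a
#'   whole number of output bins.
#' @param n_days number of complete cycles to use (default: all).
#' @return data.frame with `bin_start_h`, `mean`, `sem`, `n`.
#' @export
fold_daily <- function(trace, period_h = 24, out_bin_min = 60,
                       n_days = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  tr <- rebin(trace, out_bin_min)
  nb_cycle <- period_h * 60 / out_bin_min
  if (nb_cycle != round(nb_cycle))
    stop("period is not a multiple of the output bin width")
  nb_cycle <- as.integer(round(nb_cycle))
  n_cycles <- floor(length(tr$counts) / nb_cycle)
  if (!is.null(n_days)) n_cycles <- min(n_cycles, n_days)
  if (n_cycles < 1) stop("need at least one complete cycle")
  x <- tr$counts[seq_len(n_cycles * nb_cycle)]
  if (mean(is.na(x)) > 0.1)
    warning("more than 10% missing data in the folding window")
  m <- matrix(x, nrow = nb_cycle)
  mu <- rowMeans(m, na.rm = TRUE)
  n_ok <- rowSums(!is.na(m))
  sem <- apply(m, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  sem[n_ok < 2] <- 0
  data.frame(bin_start_h = (seq_len(nb_cycle) - 1) * out_bin_min / 60,
             mean = mu, sem = sem, n = n_ok)
}
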