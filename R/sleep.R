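#' Score immobility-defined sleep
#'
#' A second is scored as sleep when it lies inside at least one
#' immobility run of length >= `min_run_s` seconds whose immobile
#' fraction is >= `immobile_frac`: a run is a window that begins and ends
#' on an immobile second (so brief movements inside a long immobile
#' stretch are tolerated, but immobility shorter than the threshold can
#' never be promoted by padding it with mobile seconds).  This is the
#' behavioral-sleep surrogate: sustained (>= 40 s) near-total
#' immobility.  The scored seconds are aggregated to a per-minute sleep
#' count, one count per `count_unit_s` scored-sleep seconds (so with the
#' 10-s default the count ranges 0-6 per minute and "count > 3" means
#' more than 30 s of sleep in that minute).
#'
#' The scorer is exact: using prefix sums of the mobile indicator, a
#' window `[i, j]` meets the fraction rule iff `f(j) <= f(i - 1)` where
#' `f(k) = mobile(1..k) - (1 - immobile_frac) * k`; for each immobile
#' start `i` the union of qualifying runs is `[i, J(i)]` with `J(i)` the
#' largest immobile index with `f(J) <= f(i - 1)`, found by sorting `f`
#' over the immobile positions.
#'
#' @param im an [immobility_trace()] (>= 1 min of 1-Hz data).
#' @param min_run_s minimum window length, seconds.
#' @param immobile_frac minimum immobile fraction within the window.
#' @param count_unit_s scored-sleep seconds per sleep count.
#' @return an object of class `sleep_series`: list with `counts` (per
#'   minute), `sleep_sec` (per-second 0/1 scored sleep), `params`,
#'   `schedule`.
#' @export
score_sleep <- function(im, min_run_s = 40, immobile_frac = 0.95,
                        count_unit_s = 10) {
  stopifnot(inherits(im, "immobility_trace"))
  x <- im$flags
  if (anyNA(x)) stop("immobility trace contains missing values")
  if (any(!x %in% c(0L, 1L))) stop("non-binary immobility input")
  n <- length(x)
  asleep <- logical(n)
  imm <- which(x == 1L)
  if (n >= min_run_s && length(imm)) {
    mobile <- 1L - x
    f <- c(0, cumsum(mobile)) - (1 - immobile_frac) * (0:n)  # f[k+1] = f(k)
    eps <- 1e-9
    fj <- f[-1]
    # runs start and end on immobile seconds: search ends among `imm`
    ordi <- imm[order(fj[imm], imm)]      # immobile ends by ascending f
    fsort <- fj[ordi]
    maxidx <- cummax(ordi)
    # for each immobile start i, the largest immobile j with f(j) <= f(i-1)
    p <- findInterval(f[imm] + eps, fsort)
    J <- ifelse(p >= 1, maxidx[pmax(p, 1)], 0L)
    valid <- J >= imm + min_run_s - 1
    cover <- cummax(ifelse(valid, J, 0L))
    k <- findInterval(seq_len(n), imm)    # last immobile start <= t
    asleep <- k >= 1 & cover[pmax(k, 1)] >= seq_len(n)
  }
  n_min <- floor(n / 60)
  sec_per_min <- unname(rowsum(as.integer(asleep[seq_len(n_min * 60)]),
                               rep(seq_len(n_min), each = 60))[, 1])
  counts <- floor(sec_per_min / count_unit_s)
  structure(list(counts = counts, sleep_sec = as.integer(asleep),
                 params = list(min_run_s = min_run_s,
                               immobile_frac = immobile_frac,
                               count_unit_s = count_unit_s),
                 schedule = im$schedule),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf(
    "sleep_series: %d min scored (%.1f days), %.0f min of sleep\n",
    length(x$counts), length(x$counts) / 1440, sum(x$counts) / 6))
  cat(sprintf("  scoring: >= %d s runs at >= %g%% immobility, %d s/count\n",
              x$params$min_run_s, 100 * x$params$immobile_frac,
              x$params$count_unit_s))
  invisible(x)
}

#' Detect sleep bouts
#'
#' A sleep bout is a maximal run of consecutive minutes whose sleep count
#' strictly exceeds `min_count`; runs shorter than `min_duration_min` are
#' discarded.
#'
#' @param series a `sleep_series` from [score_sleep()].
#' @param min_count per-minute count that must be exceeded (default 3,
#'   i.e. more than 30 s asleep with the 10-s count unit).
#' @param min_duration_min minimum bout duration, minutes.
#' @return data.frame with `start`, `end` (minute indices, 1-based,
#'   inclusive) and `duration_min`.
#' @export
detect_sleep_bouts <- function(series, min_count = 3,
                               min_duration_min = 1) {
  stopifnot(inherits(series, "sleep_series"))
  above <- series$counts > min_count
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_duration_min
  data.frame(start = starts[keep], end = ends[keep],
             duration_min = r$lengths[keep])
}

#' Sleep duration and fragmentation metrics
#'
#' Computes, per day and averaged across the complete days of the record,
#' the total sleep duration, the number of sleep bouts, the mean bout
#' length, and the maximum bout length, in a ZT window.  Bouts are
#' assigned to a window by their start minute; bouts spanning the
#' day/night boundary are not split.
#'
#' @param series a `sleep_series` (must carry a schedule, or supply one).
#' @param window `"day"` (ZT0-12), `"night"` (ZT12-24) or `"24h"`.
#' @param schedule optional `light_schedule` overriding the one stored in
#'   the series.
#' @return list with `duration_min`, `n_bouts`, `mean_bout_min`,
#'   `max_bout_min` (per-day averages), `n_days`, and `empty` flag (TRUE
#'   when no bouts fell in the window; bout means are then reported as 0).
#' @export
sleep_metrics <- function(series, window = c("day", "night", "24h"),
                          schedule = series$schedule) {
  window <- match.arg(window)
  stopifnot(inherits(series, "sleep_series"))
  n_min <- length(series$counts)
  n_days <- floor(n_min / 1440)
  if (n_days < 1) stop("window outside record: need >= 1 complete day")
  used <- seq_len(n_days * 1440)
  if (window == "24h") {
    in_win <- rep(TRUE, length(used))
  } else {
    if (is.null(schedule)) stop("a schedule is required for day/night windows")
    zt <- to_zt((used - 1) + 0.5, schedule, projected = TRUE)
    in_win <- if (window == "day") zt < 12 else zt >= 12
  }
  dur <- sum(series$counts[used][in_win]) / 6
  bouts <- detect_sleep_bouts(series)
  bouts <- bouts[bouts$start <= max(used), , drop = FALSE]
  bw <- bouts[in_win[bouts$start], , drop = FALSE]
  empty <- nrow(bw) == 0
  list(duration_min = dur / n_days,
       n_bouts = nrow(bw) / n_days,
       mean_bout_min = if (empty) 0 else mean(bw$duration_min),
       max_bout_min = if (empty) 0 else max(bw$duration_min),
       n_days = n_days, empty = empty)
}
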