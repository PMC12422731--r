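#' Relative integrated density
#'
#' Mean gray value times ROI area, the standard ImageJ-style relative
#' integrated density of a fixed ROI.
#'
#' @param mean_gray mean gray value(s), arbitrary units (>= 0).
#' @param roi_area ROI area(s), square micrometres (>= 0).
#' @return integrated density, a.u. * um^2 (vectorised).
#' @export
integrated_density <- function(mean_gray, roi_area) {
  if (any(mean_gray < 0) || any(roi_area < 0)) stop("inputs must be >= 0")
  mean_gray * roi_area
}

#' Per-animal integrated density from a section table
#'
#' Averages left/right ROI integrated densities within each section, then
#' across sections, to a single value per animal.
#'
#' @param sections data.frame with columns `animal`, `section`, `side`
#'   (`"left"`/`"right"`), `mean_gray`, `roi_area`.
#' @return data.frame with one row per animal and its mean integrated
#'   density.
#' @export
integrated_density_batch <- function(sections) {
  stopifnot(all(c("animal", "section", "side", "mean_gray", "roi_area")
                %in% names(sections)))
  sections$id <- integrated_density(sections$mean_gray,
                                    sections$roi_area)
  per_sec <- stats::aggregate(id ~ animal + section, sections, mean)
  out <- stats::aggregate(id ~ animal, per_sec, mean)
  names(out)[2] <- "integrated_density"
  out
}

# peak of a degree-5 polynomial fit, located on an oversampled grid;
# returns NA when the fit is degenerate (constant profile)
poly5_peak <- function(y, oversample = 10) {
  n <- length(y)
  if (stats::sd(y) == 0) return(NA_real_)
  xn <- seq(-1, 1, length.out = n)          # normalised x for conditioning
  fit <- stats::lm(y ~ stats::poly(xn, 5, raw = TRUE))
  if (anyNA(stats::coef(fit))) return(NA_real_)
  grid <- seq(-1, 1, length.out = (n - 1) * oversample + 1)
  pred <- cbind(1, stats::poly(grid, 5, raw = TRUE)) %*% stats::coef(fit)
  k <- which.max(pred)
  1 + (grid[k] + 1) / 2 * (n - 1)           # back to bin coordinates
}

#' Align intensity profiles on their fitted peaks and average
#'
#' For each 1-D profile a fifth-order polynomial is fit to estimate the
#' intensity-peak position; each profile's original y values are then
#' shifted by an integer number of bins (no interpolation) so the peaks
#' coincide at the median peak position, and the shifted profiles are
#' averaged arithmetically.  Edge bins without full overlap are dropped
#' symmetrically from both ends of the common support.
#'
#' Degenerate profiles (constant, no polynomial peak) leave the input
#' unshifted and set the `degenerate` flag; peaks landing on the profile
#' boundary are flagged in `boundary_peaks`.
#'
#' @param profiles list of numeric vectors (>= 2, equal length, same
#'   side), e.g. from [simulate_profiles()].
#' @param oversample peak-location grid refinement relative to the bin
#'   spacing.
#' @return object of class `aligned_profiles`: list with `x` (bin indices
#'   of the common support in aligned coordinates), `mean`, `sd`,
#'   `peaks` (fitted per-profile peak positions), `shifts` (integer bin
#'   shifts applied), `degenerate`, `boundary_peaks`.
#' @export
align_and_average <- function(profiles, oversample = 10) {
  if (length(profiles) < 2) stop("need >= 2 profiles")
  n <- unique(lengths(profiles))
  if (length(n) != 1) stop("profiles must have equal length")
  sides <- unique(unlist(lapply(profiles, attr, "side")))
  if (length(sides) > 1)
    stop("profiles from both sides: process left and right separately")
  ys <- lapply(profiles, as.numeric)
  peaks <- vapply(ys, poly5_peak, 0, oversample = oversample)
  degenerate <- anyNA(peaks)
  boundary <- !is.na(peaks) & (peaks <= 1 + 1e-9 | peaks >= n - 1e-9)
  shifts <- if (degenerate) rep(0L, length(ys))
            else as.integer(round(stats::median(peaks) - peaks))
  lo <- 1 + max(c(0, shifts))        # common support after shifting
  hi <- n + min(c(0, shifts))
  if (hi <= lo) stop("no overlapping support after alignment")
  mat <- vapply(seq_along(ys), function(i) {
    idx <- (lo:hi) - shifts[i]
    ys[[i]][idx]
  }, numeric(hi - lo + 1))
  structure(list(x = lo:hi, mean = rowMeans(mat),
                 sd = apply(mat, 1, stats::sd),
                 peaks = peaks, shifts = shifts,
                 degenerate = degenerate,
                 boundary_peaks = which(boundary)),
            class = "aligned_profiles")
}

#' @export
print.aligned_profiles <- function(x, ...) {
  cat(sprintf(
    "aligned_profiles: %d profiles, support %d-%d, peak at bin %.1f\n",
    length(x$peaks), min(x$x), max(x$x), x$x[which.max(x$mean)]))
  if (x$degenerate) cat("  flagged: degenerate (unaligned average)\n")
  if (length(x$boundary_peaks))
    cat("  flagged: boundary peaks in profiles",
        paste(x$boundary_peaks, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.aligned_profiles <- function(x, ...) {
  graphics::plot(x$x, x$mean, type = "l", xlab = "Position (bins)",
                 ylab = "Intensity (a.u.)", ...)
  graphics::polygon(c(x$x, rev(x$x)),
                    c(x$mean + x$sd, rev(x$mean - x$sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$x, x$mean)
  invisible(x)
}
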