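#' Chi-squared (Sokolove-Bushell) periodogram
#'
#' For each trial period of `P` bins the series is folded into `P`
#' columns; with column means `M_h` (over the actual, possibly unequal,
#' column counts `n_h`, the incomplete final row being included), grand
#' mean `M` and `N` points,
#' \deqn{Q_p = N \sum_h n_h (M_h - M)^2 / \sum_h n_h / \sum_i (x_i - M)^2}
#' i.e. `Qp = N * SSB / SST`, compared to the chi-squared quantile with
#' `P - 1` degrees of freedom.  The peak period `tau` is the trial period
#' maximising `Qp` among those exceeding the `alpha = 0.001` significance
#' line.  The percentage of variance is `%V(P) = 100 Qp / N`, and the
#' rhythmic power is the peak `%V` corrected by the `p = 0.05`
#' significance level: `%V(tau) - 100 * chisq(0.95, P - 1) / N`.
#'
#' Records with no supra-threshold peak (or zero variance) are flagged
#' arrhythmic and report `tau = NA`, `rhythmic_power = 0`.
#'
#' @param trace an [activity_trace()].
#' @param range_h trial-period search range, hours.
#' @param bin_min analysis bin width, minutes (input is re-binned); the
#'   trial-period grid is every integer number of bins in `range_h`, i.e.
#'   0.1-h resolution at 6-min bins.
#' @param n_days number of days of data used.
#' @param start_day first day (1-based) of the analysis window.
#' @param alpha peak-detection significance threshold.
#' @param correct multiplicity correction of the peak-detection line
#'   across the trial-period grid: `"bonferroni"` (default; keeps the
#'   familywise false-peak rate at about `alpha` over the whole grid) or
#'   `"none"` (test-wise line).  The `p = 0.05` line used for the
#'   rhythmic-power normalisation is always the test-wise quantile.
#' @return object of class `chi2_periodogram`: data frame fields
#'   `period_h`, `Qp`, `df`, `sig001`, `sig05`, `pV`, plus `tau_h`,
#'   `rhythmic_power`, `arrhythmic`, `n`.
#' @references Sokolove, P.G. & Bushell, W.N. (1978) The chi square
#'   periodogram: its utility for analysis of circadian rhythms.
#'   J. Theor. Biol. 72, 131-160.
#' @export
chi2_periodogram <- function(trace, range_h = c(20, 28), bin_min = 6,
                             n_days = 10, start_day = 1, alpha = 0.001,
                             correct = c("bonferroni", "none")) {
  correct <- match.arg(correct)
  stopifnot(inherits(trace, "activity_trace"))
  tr <- rebin(trace, bin_min)
  per_day <- 1440 / bin_min
  avail_days <- floor(length(tr$counts) / per_day)
  if (avail_days < n_days)
    stop(sprintf("need %d days of data, have %d", n_days, avail_days))
  idx <- seq((start_day - 1) * per_day + 1, length.out = n_days * per_day)
  x <- tr$counts[idx]
  if (anyNA(x)) {
    if (mean(is.na(x)) > 0.1)
      warning("more than 10% missing data in the periodogram window")
    x <- x[!is.na(x)]
  }
  N <- length(x)
  p_bins <- seq(ceiling(range_h[1] * 60 / bin_min),
                floor(range_h[2] * 60 / bin_min))
  if (!length(p_bins) || p_bins[1] < 2 || p_bins[length(p_bins)] > N / 2)
    stop("trial-period range empty or beyond half the record span")
  M <- mean(x)
  SST <- sum((x - M)^2)
  period_h <- p_bins * bin_min / 60
  a_eff <- if (correct == "bonferroni") alpha / length(p_bins) else alpha
  if (SST == 0) {
    res <- list(period_h = period_h, Qp = rep(0, length(p_bins)),
                df = p_bins - 1,
                sig001 = stats::qchisq(1 - a_eff, p_bins - 1),
                sig05 = stats::qchisq(0.95, p_bins - 1),
                pV = rep(0, length(p_bins)),
                tau_h = NA_real_, rhythmic_power = 0,
                arrhythmic = TRUE, n = N, alpha = alpha)
    class(res) <- "chi2_periodogram"
    return(res)
  }
  Qp <- vapply(p_bins, function(P) {
    g <- (seq_len(N) - 1L) %% P
    nh <- tabulate(g + 1L, nbins = P)
    Mh <- rowsum(x, g)[, 1] / nh
    N * sum(nh * (Mh - M)^2) / SST
  }, 0)
  sig001 <- stats::qchisq(1 - a_eff, p_bins - 1)
  sig05 <- stats::qchisq(0.95, p_bins - 1)
  pV <- 100 * Qp / N
  supra <- Qp > sig001
  if (any(supra)) {
    k <- which.max(ifelse(supra, Qp, -Inf))
    tau_h <- period_h[k]
    power <- pV[k] - 100 * sig05[k] / N
    arr <- FALSE
    if (power < 0) { power <- 0; arr <- TRUE }
  } else {
    tau_h <- NA_real_; power <- 0; arr <- TRUE
  }
  res <- list(period_h = period_h, Qp = Qp, df = p_bins - 1,
              sig001 = sig001, sig05 = sig05, pV = pV,
              tau_h = tau_h, rhythmic_power = power,
              arrhythmic = arr, n = N, alpha = alpha)
  class(res) <- "chi2_periodogram"
  res
}

#' @export
print.chi2_periodogram <- function(x, ...) {
  cat("Chi-squared periodogram\n")
  cat(sprintf("  trial periods %.2f-%.2f h (%d), N = %d\n",
              min(x$period_h), max(x$period_h), length(x$period_h), x$n))
  if (x$arrhythmic && is.na(x$tau_h)) {
    cat(sprintf("  arrhythmic: no peak above the alpha = %g line\n",
                x$alpha))
  } else {
    cat(sprintf("  tau = %.2f h, rhythmic power = %.1f %%V%s\n",
                x$tau_h, x$rhythmic_power,
                if (x$arrhythmic) " (flagged arrhythmic)" else ""))
  }
  invisible(x)
}

#' @export
plot.chi2_periodogram <- function(x, ...) {
  graphics::plot(x$period_h, x$Qp, type = "l", xlab = "Period (h)",
                 ylab = expression(Q[p]), ...)
  graphics::lines(x$period_h, x$sig001, lty = 2, col = "red")
  graphics::lines(x$period_h, x$sig05, lty = 3, col = "grey40")
  if (!is.na(x$tau_h))
    graphics::abline(v = x$tau_h, col = "blue", lty = 3)
  graphics::legend("topleft", bty = "n", lty = c(2, 3),
                   col = c("red", "grey40"),
                   legend = c("alpha = 0.001", "alpha = 0.05"))
  invisible(x)
}

#' Qp-curve as a data frame
#' @param x a `chi2_periodogram`.
#' @param ... unused.
#' @export
as.data.frame.chi2_periodogram <- function(x, ...) {
  data.frame(period_h = x$period_h, Qp = x$Qp, df = x$df,
             sig001 = x$sig001, sig05 = x$sig05, pV = x$pV)
}
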