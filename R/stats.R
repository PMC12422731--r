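#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak adjustment of a family of m p-values: with the raw
#' p-values sorted ascending, the k-th adjusted value is
#' `max over j <= k of 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1, and
#' adjusted values are returned in the original order.  Adjusted values
#' are monotone non-decreasing in rank and never smaller than the raw
#' values.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(cummax(1 - (1 - ps)^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Normality-gated two-group comparison
#'
#' The reporting rule used throughout the analysis layer: both groups are
#' tested for normality (Shapiro-Wilk) and the pair for equal variance
#' (Brown-Forsythe, i.e. Levene's test on deviations from the median).
#' When all gates pass at `alpha`, a two-sided two-sample t-test (pooled
#' variance) is used; otherwise the Mann-Whitney rank-sum test.  With
#' `welch = TRUE` a variance-gate failure with normal groups routes to
#' Welch's t-test instead of Mann-Whitney.
#'
#' @param x,y numeric samples (>= 3 each).
#' @param alpha gate significance level.
#' @param welch route normal/unequal-variance data to Welch's t.
#' @return object of class `gated_test`: list with `test` (name),
#'   `statistic`, `df`, `p`, `gate` (the gate p-values and outcome) and
#'   the group summaries.
#' @export
gated_two_group_test <- function(x, y, alpha = 0.05, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per group")
  sw <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                             error = function(e) 0)  # constant input: fail
  sw_x <- sw(x); sw_y <- sw(y)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  bf_p <- tryCatch(
    car::leveneTest(c(x, y) ~ g, center = stats::median)[1, "Pr(>F)"],
    error = function(e) 0)
  if (is.na(bf_p)) bf_p <- 0
  normal <- sw_x > alpha && sw_y > alpha
  eqvar <- bf_p > alpha
  if (normal && eqvar) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "t"
  } else if (normal && welch) {
    ht <- stats::t.test(x, y)
    test <- "welch"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test <- "mann-whitney"
    if (is.nan(ht$p.value)) ht$p.value <- 1   # fully tied samples
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter) %||% NA_real_,
                 p = ht$p.value,
                 gate = list(shapiro_x = sw_x, shapiro_y = sw_y,
                             brown_forsythe = bf_p, normal = normal,
                             equal_variance = eqvar),
                 mean_x = mean(x), mean_y = mean(y),
                 n_x = length(x), n_y = length(y)),
            class = "gated_test")
}

#' @export
print.gated_test <- function(x, ...) {
  gate <- sprintf("normality %s, equal variance %s",
                  if (x$gate$normal) "passed" else "failed",
                  if (x$gate$equal_variance) "passed" else "failed")
  cat(sprintf("%s test (%s): statistic = %.3f%s, p = %.4g\n",
              switch(x$test, t = "Two-sample t", welch = "Welch t",
                     "mann-whitney" = "Mann-Whitney U"),
              gate, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p))
  cat(sprintf("  means: %.3f (n=%d) vs %.3f (n=%d)\n",
              x$mean_x, x$n_x, x$mean_y, x$n_y))
  invisible(x)
}

#' Factorial ANOVA with Holm-Sidak step-down follow-ups
#'
#' Fits a fully crossed fixed-effects ANOVA (2 or 3 factors, all
#' interactions) and runs pairwise follow-up contrasts of one factor
#' within each combination of the remaining factors ("slices"), using the
#' pooled residual mean square; the family of contrast p-values is
#' adjusted with [holm_sidak()].
#'
#' @param table data.frame with the response and factor columns.
#' @param response name of the response column.
#' @param factors character vector of 2 or 3 factor column names.
#' @param contrast_factor factor whose levels are compared within slices
#'   of the others (default: the first factor).
#' @param alpha significance level recorded on each contrast.
#' @return object of class `factorial_anova`: list with `anova`
#'   (data.frame of effects: term, df, F, p) and `contrasts` (data.frame
#'   with slice, levels compared, difference, t, df, raw and adjusted p).
#' @export
factorial_anova <- function(table, response, factors,
                            contrast_factor = factors[1], alpha = 0.05) {
  stopifnot(length(factors) %in% c(2, 3),
            all(c(response, factors) %in% names(table)),
            contrast_factor %in% factors)
  dat <- table
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  counts <- stats::aggregate(dat[[response]],
                             dat[factors], length)$x
  n_cells <- prod(vapply(dat[factors], nlevels, 0L))
  if (length(counts) < n_cells)
    stop("design has empty cells: factors must be fully crossed")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = "*")))
  fit <- stats::aov(fml, data = dat)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  keep <- terms != "Residuals"
  anova_tab <- data.frame(term = terms[keep], df = an$Df[keep],
                          F = an$`F value`[keep], p = an$`Pr(>F)`[keep])
  mse <- an$`Mean Sq`[!keep]
  df_res <- an$Df[!keep]
  others <- setdiff(factors, contrast_factor)
  slice_id <- if (length(others))
    interaction(dat[others], sep = ":", drop = TRUE)
  else factor(rep("all", nrow(dat)))
  lev <- levels(dat[[contrast_factor]])
  rows <- list()
  for (s in levels(slice_id)) {
    sub <- dat[slice_id == s, ]
    for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
      a <- sub[[response]][sub[[contrast_factor]] == lev[i]]
      b <- sub[[response]][sub[[contrast_factor]] == lev[j]]
      d <- mean(a) - mean(b)
      se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
      tt <- d / se
      rows[[length(rows) + 1]] <- data.frame(
        slice = s, level_1 = lev[i], level_2 = lev[j], diff = d,
        t = tt, df = df_res,
        p = 2 * stats::pt(-abs(tt), df_res))
    }
  }
  contr <- do.call(rbind, rows)
  contr$p_adj <- holm_sidak(contr$p)
  contr$significant <- contr$p_adj < alpha
  structure(list(anova = anova_tab, contrasts = contr,
                 response = response, factors = factors,
                 contrast_factor = contrast_factor),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("%d-way ANOVA on %s (%s)\n", length(x$factors),
              x$response, paste(x$factors, collapse = " x ")))
  print(x$anova, row.names = FALSE, digits = 4)
  cat(sprintf("Holm-Sidak follow-ups (%s within slices):\n",
              x$contrast_factor))
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pearson correlation matrix with per-cell tests
#'
#' Pairwise-complete Pearson correlations between two metric sets, with
#' two-sided p-values; cells with fewer than `min_n` paired observations
#' are set to NA and flagged.
#'
#' @param table data.frame of per-animal metrics.
#' @param row_metrics,col_metrics column names.
#' @param min_n minimum paired observations per cell.
#' @return object of class `correlation_matrix`: list of matrices `r`,
#'   `p`, `n`, and `flagged` (logical: underpowered or degenerate cells).
#' @export
correlation_matrix <- function(table, row_metrics, col_metrics,
                               min_n = 4) {
  stopifnot(all(c(row_metrics, col_metrics) %in% names(table)))
  r <- p <- nm <- matrix(NA_real_, length(row_metrics),
                         length(col_metrics),
                         dimnames = list(row_metrics, col_metrics))
  flagged <- matrix(FALSE, length(row_metrics), length(col_metrics),
                    dimnames = list(row_metrics, col_metrics))
  for (i in seq_along(row_metrics)) for (j in seq_along(col_metrics)) {
    x <- table[[row_metrics[i]]]; y <- table[[col_metrics[j]]]
    ok <- !is.na(x) & !is.na(y)
    nm[i, j] <- sum(ok)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0 ||
        stats::sd(y[ok]) == 0) {
      flagged[i, j] <- TRUE
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nm, flagged = flagged),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pearson correlation matrix (r):\n")
  print(round(x$r, 3))
  if (any(x$flagged))
    cat("flagged cells (n <", min(x$n[x$flagged]) + 1,
        "or zero variance):", sum(x$flagged), "\n")
  invisible(x)
}
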