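# Independent brute-force oracles used to validate the fast scorers.
# These enumerate every candidate window/run directly and must stay
# independent of the implementations they check.

# Brute-force sleep scorer: a second is asleep iff it lies in ANY run
# [i, j] that starts and ends on an immobile second, has length >=
# min_run, and immobile fraction >= frac.  Exact integer arithmetic
# (frac = p/q).
brute_sleep_seconds <- function(x, min_run = 40, frac_num = 19,
                                frac_den = 20) {
  n <- length(x)
  asleep <- logical(n)
  if (n < min_run) return(asleep)
  cs <- c(0, cumsum(x))
  for (i in seq_len(n - min_run + 1)) {
    if (x[i] != 1L) next
    j <- seq.int(i + min_run - 1, n)
    ok <- x[j] == 1L &
      frac_den * (cs[j + 1] - cs[i]) >= frac_num * (j - i + 1)
    if (any(ok)) asleep[i:max(j[ok])] <- TRUE
  }
  asleep
}

# Brute-force sleep-bout enumerator on a per-minute count series
brute_sleep_bouts <- function(counts, min_count = 3) {
  bouts <- NULL
  i <- 1; n <- length(counts)
  while (i <= n) {
    if (counts[i] > min_count) {
      j <- i
      while (j < n && counts[j + 1] > min_count) j <- j + 1
      bouts <- rbind(bouts, c(i, j, j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(bouts)) return(data.frame(start = integer(0),
                                        end = integer(0),
                                        duration_min = integer(0)))
  data.frame(start = bouts[, 1], end = bouts[, 2],
             duration_min = bouts[, 3])
}

# Brute-force activity-bout counter on a per-minute count series
brute_activity_bouts <- function(x, threshold = 3, max_gap = 21) {
  active <- which(x >= threshold)
  if (!length(active)) return(0L)
  n_bouts <- 1L
  for (k in seq_along(active)[-1]) {
    if (active[k] - active[k - 1] - 1 >= max_gap)
      n_bouts <- n_bouts + 1L
  }
  n_bouts
}

# Direct ANOVA-style periodogram fold for cross-checking Qp
brute_qp <- function(x, P) {
  g <- (seq_along(x) - 1) %% P
  M <- mean(x)
  ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - M)^2))
  length(x) * ss_between / sum((x - M)^2)
}

# quick random immobility trace (biased toward immobility runs)
random_immobility <- function(n, p_stay = 0.92, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- integer(n)
  x[1] <- rbinom(1, 1, 0.5)
  flips <- runif(n - 1) > p_stay
  for (i in seq_len(n - 1))
    x[i + 1] <- if (flips[i]) 1L - x[i] else x[i]
  x
}
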