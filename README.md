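# chronobehav

Behavioral chronobiology analysis for rodent home-cage recordings, with a
virtual-mouse simulator for end-to-end validation.

## What it does

Mouse models of neurodevelopmental and circadian disorders are phenotyped
with a fairly standard battery: immobility-defined sleep scoring from
video tracking, wheel-running or infrared activity rhythms, and a set of
light-response assays.  `chronobehav` implements that battery as tested,
reusable R code:

- **Sleep scoring** — a second counts as sleep when it lies in a
  sustained immobility run (>= 40 s at >= 95% immobility); per-minute
  sleep counts, bout detection (runs of minutes with count > 3), and
  duration/fragmentation metrics by light phase.
- **χ² periodogram** (Sokolove–Bushell) — for each trial period `P` the
  series is folded and `Qp = N·Σ n_h (M_h − M)² / Σ (x_i − M)²` is
  compared with χ²(P−1) significance lines; the peak gives the period τ
  and the *rhythmic power* %V(τ) − 100·χ²₀.₉₅(P−1)/N.
- **Activity onsets** — template-correlation onset detection, onset
  variability (SD of residuals about a 10-day regression line), activity
  bout counting (21-min gap rule, 3 counts/min threshold), ZT-windowed
  activity.
- **Photic assays** — negative masking (% suppression of activity during
  a 1-h nocturnal light pulse vs the previous-day baseline), days to
  re-entrain after a 6-h schedule advance, skeleton-photoperiod (SPP)
  rhythm metrics, and light-pulse phase shifts from pre/post onset
  regressions (delays negative).
- **Densitometry** — 1-D intensity-profile analysis: integrated density
  (mean gray × ROI area) and fifth-order-polynomial peak alignment with
  arithmetic averaging.
- **Statistics** — the field's reporting pipeline: Shapiro–Wilk /
  Brown–Forsythe gated t vs Mann–Whitney tests, factorial ANOVA with
  Holm–Šidák step-down follow-ups, Pearson correlation matrices.
- **Simulator** — a stochastic virtual mouse (Poisson activity on a
  square-wave active phase, exponential immobility bouts, first-order
  entrainment dynamics) with known ground truth under LD, DD, SPP,
  phase-shift, light-pulse and timed-feeding protocols, so every
  estimator above is validated by parameter recovery.

## Worked example

```r
library(chronobehav)

wt <- mouse_preset("wt", seed = 1)
act <- simulate_activity(wt, protocol(seg_ld(10)), bin_min = 1)

chi2_periodogram(act)
#> Chi-squared periodogram
#>   trial periods 20.00-28.00 h (81), N = 2400
#>   tau = 24.00 h, rhythmic power = 86.2 %V

detect_onsets(act, expected_period_h = 24)
#> onset_series: 10 days, 0 missing
#>   fit: onset = 722.3 +0.17 min/day (period 24.00 h), resid SD 4.3 min

im <- simulate_immobility(wt, protocol(seg_ld(2)), seed = 2)
unlist(sleep_metrics(score_sleep(im), "day")[1:4])
#>  duration_min       n_bouts mean_bout_min  max_bout_min
#>         492.8          17.5          28.7         157.0
```

The preset entrains to the 24-h light cycle with a strongly
significant periodogram peak; onsets sit near lights-off (minute 720)
with a residual SD close to the preset's 8-min jitter; daytime sleep is
long and consolidated (the ~29-min scored bouts exceed the 22-min
generating bouts because brief movements inside long immobile stretches
are absorbed by the 95% rule).  An end-to-end cohort comparison is one
call:

```r
run_pipeline(pipeline_config(n_per_group = 8, seed = 1))
```

which simulates wild-type-like and mutant-like groups, scores every
animal, and reports normality-gated group tests for each metric.

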