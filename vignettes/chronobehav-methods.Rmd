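---
title: "Models and methods behind chronobehav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronobehav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronobehav)
```

`chronobehav` packages the analysis battery used to phenotype sleep and
circadian behavior in rodent home-cage studies, together with a
stochastic virtual mouse that generates records with known ground truth.
This vignette explains the models, the parameters that matter, the
numerical choices, and what the validation suite does and does not
establish.

## The virtual mouse

The activity generator is deliberately simple — a descriptive model of a
nocturnal rodent's actogram, not a biophysical oscillator:

- **Square-wave rate model.** Each circadian cycle has a 12-h *active*
  phase starting at the predicted activity onset and a *rest* phase
  otherwise.  Counts per bin are Poisson with rate `active_rate` or
  `rest_rate` (counts/min).  Poisson is the simplest distribution
  matching non-negative integer counts; an overdispersed variant was
  deliberately left out because none of the validated estimators is
  sensitive to the count distribution beyond its mean (the periodogram
  statistic is scale-free, onsets depend on the rate step).
- **Onset dynamics.** The deterministic onset anchor advances by the
  free-running period `tau_hours` each cycle.  Under a light cycle it is
  pulled toward lights-off, limited to `reentrain_rate_h_per_day`; a
  stable 12:12 cycle therefore locks the anchor exactly whenever the
  daily pull covers `|24 − tau|`, and a schedule shift is followed at a
  bounded rate — a first-order transient that reproduces the
  days-to-re-entrain readout without modelling a phase-response curve.
  Under a skeleton photoperiod the pull is halved (two 1-h pulses are a
  much weaker zeitgeber than 12 h of light); with the shipped presets
  this makes the precise animal lock to 24.0 h while the impaired one
  free-runs through the skeleton, which is exactly the qualitative
  dissociation the assay is designed to expose.  A CT16 light pulse in
  constant darkness delays the next anchor by `phase_shift_delay_min`.
  Realised onsets add Gaussian noise (`onset_jitter_min`) to the anchor;
  jitter is applied to the onset only, with the active phase ending at
  a fixed 12 h, mirroring the assays' focus on onset precision.
- **Negative masking.** Light falling inside the active phase
  multiplies the active rate by `1 − masking_coeff`.  Rest-phase
  activity is not masked, so `rest_rate` keeps its meaning as the
  light-phase floor.
- **Immobility.** An alternating-renewal process: immobile and mobile
  bouts with exponential durations whose means differ between
  (subjective) day and night.  A fixed 2% / 5% per-second flip noise
  emulates tracker error.  There is no two-process sleep homeostasis;
  bout means are constant within a phase.

`mouse_params()` lists both `rest_rate` and `activity_frac_night`
because users think in either currency; when `rest_rate` is `NA` it is
derived as `active_rate (1 − f)/f`, which makes the expected fraction of
counts in the active phase equal `f`.

### Presets

`mouse_preset("wt")` and `mouse_preset("ko")` bracket a precise,
light-sensitive animal and a degraded counterpart: onset jitter 8 vs
25 min, light-phase activity floor 2.3 vs 6.1 counts/min, masking 0.78
vs 0.33, re-entrainment 1.0 vs 0.53 h/day, CT16 delay 136 vs 64 min,
free-running period 23.6 vs 23.4 h, and shorter, more fragmented daytime
immobility bouts in the degraded preset (13-min sleep / 9.5-min wake
bouts vs 22.4 / 12.4; day sleep fraction 0.58 vs 0.64).  These are
qualitative settings, not fits: they preserve the direction of the
group contrasts the validation suite checks and are separated by at
least ~2 pooled SD on every contrasted metric at the suite's sample
sizes (8 animals per group, 10-day activity records, 2-day sleep
records).  The day-time bout structure of the degraded preset was set by
that separation requirement rather than by any table of central
tendencies, and should not be read as an empirical estimate.

## Sleep scoring

A second is scored as sleep when it lies in an immobility *run* — a
window that starts and ends on an immobile second — of length at least
40 s with at least 95% immobility.  Requiring immobile endpoints
matters: without it, 39 s of immobility padded with one mobile second
would form a 40-s window at 97.5% immobility and defeat the 40-s
threshold.  The 95% criterion is interpreted temporally (fraction of
seconds immobile within the run); the tracker's spatial
95%-of-the-animal criterion operates upstream of the exported trace, and
only temporal information survives export.  The scorer is exact, not
heuristic: with prefix sums of the mobile indicator, a window `[i, j]`
satisfies the fraction rule iff `f(j) <= f(i−1)` where
`f(k) = mobile(1..k) − 0.05k`, and the union of qualifying runs is
computed in `O(n log n)`; the test suite proves equality with a direct
enumeration oracle on a thousand random traces.

Scored seconds aggregate to a per-minute sleep count at 10 s per count,
so counts run 0–6 and the bout rule "count > 3 per minute" means more
than 30 s of sleep in that minute.  The 10-s unit is a declared
convention recorded in the scoring metadata and configurable; trackers
differ and no universal unit exists.  Sleep bouts are maximal runs of
minutes with count > 3 (strict), and bouts are assigned to day or night
by their start minute without splitting at the boundary, so per-phase
bout counts need not sum exactly to the 24-h count.

One practical consequence of the window rule: scored bout lengths
exceed the generating immobile-bout means (brief movements inside long
immobile stretches are absorbed), so recovery checks compare against the
generator only directionally and within a 25% band.

## The χ² periodogram

For each trial period of `P` analysis bins the record is folded into `P`
columns and

`Qp = N · Σ_h n_h (M_h − M)² / Σ_i (x_i − M)²`

with column means `M_h` over the actual column counts `n_h` (the
incomplete final row is included; columns with one extra value simply
weigh accordingly), grand mean `M`, and `N` data points.  Under the
no-rhythm null `Qp` is approximately χ² with `P − 1` degrees of freedom.
The trial-period grid is every integer number of bins in the search
range — 0.1-h resolution at the default 6-min analysis bin.

Two numerical decisions:

- **Peak detection is familywise.** The grid spans ~81 correlated
  trial periods; a test-wise `p = 0.001` line yields a few percent of
  false peaks on pure noise.  The detection line is therefore
  Bonferroni-corrected across the grid by default (`correct =
  "bonferroni"`), keeping the familywise false-peak rate at the nominal
  level — the convention adopted by modern periodogram implementations.
  The measured false-peak rate on white noise is at or below 1% over
  hundreds of runs.
- **Rhythmic power** is reported as the peak percentage of variance
  corrected by the conventional significance level:
  `%V(τ) − 100·χ²₀.₉₅(P−1)/N`, with the `p = 0.05` quantile taken
  test-wise.  Records with no supra-threshold peak (or zero variance)
  report power 0 and τ = NA with an `arrhythmic` flag rather than
  erroring, so batch runs survive animals that fail to entrain.

`Qp` is invariant under affine rescaling of the counts, so wheel
revolutions and arbitrary infrared units are comparable.

## Onsets, variability, fragmentation

The onset detector scores each candidate minute by a step template
(6 h of −1, 6 h of +1) against the per-minute record, searching ±6 h
around the previous onset plus the expected period, then refines to the
first minute at ≥3 counts/min after ≥4 h below threshold when such a
point exists in the window (sparse records); on dense records the
template maximum stands.  Onset variability is the SD of residuals
about the least-squares onset-vs-day line with an `n − 2` denominator;
the mean absolute residual is available behind a flag
(`method = "mad"`), the SD being the default because it matches the
regression framing.  Days with no activity in the search window yield
missing onsets and are excluded with a flag.

Jitter recovery is validated in constant darkness: under a light cycle
the model's own masking suppresses activity before lights-off, censoring
the early half of the jitter distribution, so light-cycle onset
variability *underestimates* the injected SD for mechanistic reasons —
a property worth remembering when comparing entrained and free-running
variability on real data too.

Activity bouts follow the classic gap rule: minutes at ≥3 counts/min
belong to one bout unless separated by ≥21 sub-threshold minutes;
sub-threshold minutes inside a bout contribute their counts to the bout
total.  The bout count is invariant to rescaling supra-threshold counts
and monotone non-increasing in the gap parameter.

## Photic assays

- **Masking**: `100·(baseline − light)/baseline`, where baseline is the
  same clock hour on the previous day.  Positive values mean
  suppression — the sign is chosen so that reported percentages are
  positive for suppressed animals; note that the naive
  `(light − baseline)/baseline` fold change has the opposite sign.
  A zero baseline yields a flagged undefined result.
- **Re-entrainment**: first post-shift day from which the onset stays
  within 30 min of the new lights-off for 5 consecutive days.  The
  30-min tolerance is a package default (precise entrained animals
  show ~8-min onset variability, so 30 min is comfortably outside
  noise); it is configurable, and the day count is monotone
  non-increasing in it.  The tolerance is symmetric; nothing in the
  assay definition suggests treating advance and delay deviations
  differently.
- **Phase shift**: least-squares onset lines over the 10 days before
  and after the pulse, both evaluated on the day after the pulse;
  delays are negative.  The simulator applies the programmed delay on
  the cycle after the pulse, so no transient exclusion is needed by
  default; an exclusion flag exists for data with visible transients.
- **SPP metrics** delegate to the periodogram and activity modules with
  the subjective day (ZT0–12) spanned by the two 1-h pulses;
  "day activity %" is the fraction of counts in ZT0–12.

## Densitometry

Profiles are aligned on peaks estimated by a fifth-order polynomial fit
(least squares on x normalised to [−1, 1] for conditioning; peak located
on a 10× oversampled grid).  The *original* y values are then shifted by
integer bins to the median peak position and averaged arithmetically —
no interpolation, so the averaged curve is a true mean of measured
values.  Non-overlapping edge bins are dropped.  Degenerate (constant)
profiles flag the result and leave inputs unshifted; boundary peaks are
flagged.  No baseline subtraction is applied before averaging — none is
part of the stated procedure, and subtracting one would change the
integrated-density scale.  A quintic is a biased peak locator for narrow
bumps on long flat baselines (its tails are dragged by the baseline);
profiles whose intensity varies across most of the window — the intended
use — are located well, and the validation uses either
quintic-representable shapes (exactness) or jittered Gaussians
(recovery to ±2 bins under 8-bin jitter).

## Statistics layer

The two-group rule mirrors the field's reporting convention: Shapiro–
Wilk on each group and Brown–Forsythe (Levene on deviations from the
median, via `car::leveneTest`) across groups; all gates passing at 0.05
routes to a pooled-variance t test, anything else to Mann–Whitney.  A
`welch = TRUE` flag routes normal-but-heteroscedastic data to Welch's t
instead; the default follows the stricter convention of dropping to the
rank test.  Fully tied samples report p = 1.

Factorial ANOVA (2 or 3 fully crossed factors, all interactions) uses
`stats::aov`; follow-up pairwise contrasts compare one factor's levels
within each slice of the remaining factors, using the pooled residual
mean square — the slice family is the default because interaction
effects are what these designs are read for, and the family is
configurable by choosing the contrast factor.  Repeated-measures error
terms are not modelled; for time-course waveforms the package treats
time as a crossed fixed factor, a documented approximation.  The
Holm–Šidák step-down adjustment is computed directly: with raw p-values
sorted ascending, adjusted `p_(k) = max_{j<=k} 1 − (1 − p_(j))^(m−j+1)`,
clipped to 1 — verified against hand computation and monotone by
construction.  Correlation tables are pairwise-complete Pearson r with
two-sided tests; cells with under 4 pairs or zero variance are flagged,
not errors.

## Validation scale and what it shows

The acceptance-level suite runs, on one CPU in a few minutes: exact
oracle equivalence on 1000 random traces per scorer; 500 white-noise
periodograms for calibration and 100-seed recovery per injected period;
100–200-replicate recovery of jitter, masking, phase delay and
re-entrainment time; 100-replicate densitometric alignment; 2000-draw
null calibration of the gated test and ANOVA; and 100 end-to-end cohort
runs checking that the degraded preset yields lower rhythmic power,
higher onset variability, and more/shorter daytime sleep bouts at
p < 0.05.  Problem sizes (10-day records, 8 animals per group, 2-day
sleep records) match the sizes at which these assays are usually read.

Passing this suite shows the *estimators* are correct and well
calibrated under the generator's assumptions.  It does not show that
real mice obey those assumptions: real actograms have intra-night bout
structure, ultradian rhythms, tracker artifacts and inter-individual
parameter spread that the square-wave/renewal model deliberately omits.
The simulator is a test harness and a teaching tool, not a claim about
biology.
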