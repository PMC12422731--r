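Package: chronobehav
Title: Behavioral Chronobiology Analysis with a Virtual-Mouse Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing rodent sleep/wake and circadian behavior:
    immobility-defined sleep scoring and bout metrics, the chi-squared
    (Sokolove-Bushell) periodogram with rhythmic-power estimation, activity
    onset detection with regression-based onset-variability and
    phase-shift measures, photic response assays (negative masking,
    re-entrainment to schedule shifts, skeleton photoperiods, light-pulse
    phase shifts), one-dimensional densitometric profile alignment, and a
    normality-gated group-statistics layer with Holm-Sidak step-down
    follow-ups.  A stochastic virtual-mouse generator produces activity and
    immobility records with known ground truth under arbitrary lighting
    protocols, so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
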