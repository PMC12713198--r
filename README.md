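# rotastig

Quantifying how static ocular rotation (cyclotorsion) degrades astigmatism
correction in corneal refractive surgery.

When a patient lies down for surgery the eye rotates about its visual axis,
so lasers without torsion tracking deliver the cylindrical correction at a
meridian rotated by the cyclotorsion angle θ. `rotastig` is for refractive
surgeons and outcome researchers who want to analyze (or simulate) what
that misalignment does to postoperative astigmatism. It provides:

* **Alpins vector analysis** in the double-angle plane
  (X = C·cos 2α, Y = C·sin 2α): per-eye TIA, SIA, DV, angle of error,
  magnitude of error, correction index (|SIA|/|TIA|) and index of success
  (|DV|/|TIA|), plus cohort scalar means and centroids.
* **The cross-cylinder misalignment model**: a full-power correction
  rotated by θ leaves residual astigmatism of magnitude **2C·sin θ** at
  axis α + θ/2 − 45°·sign(θ) — about 14% of the treated cylinder at θ = 4°,
  the whole cylinder at θ = 30°.
* **A seeded synthetic cohort generator** calibrated to a published
  153-eye SMILE cohort (zero-inflated truncated-gamma rotations with mean
  2.44° and SD 1.93°, sphere −4.26 ± 1.46 D, cylinder floor 0.75 D,
  per-visit measurement noise, clinical 0.25 D quantization).
* **The statistical pipeline**: covariate correlation screen, multiple
  regression with standardized β, rotation-vs-vector-parameter tables,
  linear fits, and ROC analysis of rotation predicting dichotomized
  residual astigmatism with the Youden-optimal cutoff.

## Worked example

```r
library(rotastig)

undercorrection_fraction(4)          # 0.1395 -> ~14% undercorrection at 4 deg
residual_after_rotation(2, 0, 10)    # 0.695 D at 140 deg

coh <- generate_cohort(cohort_config(seed = 2026))
fit <- analyze_cohort(coh)
print(fit)
```

```
Rotation vs residual astigmatism analysis: 153 eyes, visits 1m, 3m
Residual (3m) ~ rotation: r = 0.193 (p = 0.0168)
Regression: std beta(rotation) = 0.160 (p = 0.0397), R^2 = 0.121
ROC 1m (residual >= 0.50 D): AUC 0.600, Youden cutoff 1.27 deg
ROC 3m (residual >= 0.50 D): AUC 0.641, Youden cutoff 3.35 deg
```

Reading this: on a simulated 153-eye cohort, rotation magnitude correlates
positively with 3-month residual astigmatism (r = 0.19), remains a
significant predictor after adjusting for IOP and preoperative cylinder
(standardized β = 0.16), and discriminates eyes left with ≥ 0.50 D of
residual cylinder with AUC 0.64; the Youden-optimal rotation cutoff on this
draw is 3.35°. `summary(fit)` prints the full tables, `plot(fit)` draws the
rotation–residual scatter with its fit line and the ROC curve, and
`write_report(fit, dir)` exports every table as CSV.

File-based workflows mirror the same stages:

```r
sim <- run_simulate("out", cohort_config(), seed = 1)   # cohort.csv + manifest
run_alpins(sim$cohort_file, "out", visit = "3m")        # per-eye Alpins table
run_analyze(sim$cohort_file, "out")                     # all report CSVs
```

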