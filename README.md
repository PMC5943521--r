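# centiloidr

Level-2 Centiloid calibration for amyloid-PET SUVR harmonization.

## The problem

Amyloid PET measurements are reported as standardized uptake value ratios
(SUVR): tracer uptake in a cortical target volume of interest (VOI) divided
by uptake in a reference VOI. Different sites acquire at different
post-injection windows (e.g. PiB 40–60 min vs the standard 50–70 min) and
quantify with different pipelines (mean over standard VOIs vs median over
tissue-masked in-house VOIs), so raw SUVRs are not comparable across sites.
The Centiloid scale solves this with a common 0–100 unit anchored at the
young-control (YC) group mean (0 CL) and the Alzheimer's-disease (AD) group
mean (100 CL) of a reference cohort:

```
CL(v) = 100 * (v - SUVR_YC) / (SUVR_AD - SUVR_YC)
```

A site whose method differs from the standard must first map its SUVRs onto
the standard scale with a site-specific ("level-2") linear calibration,
`S ≈ a * M + b`, estimated by regressing paired measurements. `centiloidr`
implements that calibration machinery and the questions that come with it:

* **One-step vs two-step pathways** — regress the non-standard method
  directly on the standard (`lm(MM40 ~ S)`), or chain an
  acquisition-window correction (`lm(MM40 ~ MM50)`) and a processing
  correction (`lm(MM50 ~ S)`) and compose the two fitted maps. Each step
  uses the method nearer the standard as the predictor; fitted maps are
  inverted to point toward the standard before composition.
* **Ordinary least squares vs Deming regression** — OLS assumes an
  error-free predictor, which paired SUVR data violates (both methods are
  noisy), attenuating the fitted slope by the predictor's reliability
  `σ²_x / (σ²_x + σ²_e)`. Deming regression models error on both axes
  (error-variance ratio λ, default 1) and is symmetric: fitting `y ~ x`
  with λ and `x ~ y` with 1/λ gives exact inverse transforms.

The package also covers the steps around the regression: windowing 4D
dynamic PET series into late-uptake static images (frame selection by time
window plus voxel-wise averaging), VOI statistics under the mean-based
standard and median-based tissue-masked conventions, Centiloid conversion,
tolerance-checked calibration reports (2% / 1 CL defaults), and a synthetic
data module (two-group cohorts observed through noisy linear method maps,
and dynamic phantoms with closed-form windowed values) so the whole pipeline
is testable end to end without any image downloads.

## Worked example

Simulate a reference-like cohort (34 YC near 1.01 SUVR, 45 AD near 2.08
SUVR) measured by the standard method `S` and two non-standard methods
`MM50` and `MM40`, each a latent linear map of the true signal plus 0.05
SUVR noise; then calibrate `MM40` onto the standard scale:

```r
library(centiloidr)

d <- generate_suvr_dataset(cohort_spec(seed = 42))
fit <- run_pathway(d$table, "1step-deming")
fit$transform
#> <linear_transform> MM40 -> S  [deming-inverted]
#>   S = 0.827646 * MM40 + -0.0272763
```

The slope ~0.83 is the inverse of the latent `MM40` map slope 1.18 with a
little sampling noise, i.e. the calibration recovered the map that generated
the data. The full three-variant report in the shape of a published
comparison table (per group: mean transformed SUVR, difference from the
standard, percent difference, Centiloid values):

```r
calibration_report(d$table)
#> Calibration report (anchors: YC-0 1.0195, AD-100 2.0548 SUVR)
#>   variant      group mean_suvr mean_diff_suvr mean_pct_diff mean_cl mean_cl_diff
#> 1 S            YC         1.02        0                0      0            0
#> 2 S            AD         2.05        0                0    100            0
#> 3 1step-linear YC         1.02       -0.00129         -0.13  -0.124       -0.124
#> 4 1step-linear AD         2.06        0.00097          0.05 100.           0.094
#> 5 1step-deming YC         1.02        0.00273          0.27   0.264        0.264
#> 6 1step-deming AD         2.05       -0.00207         -0.1   99.8         -0.2
#> 7 2step-linear YC         1.02       -0.00322         -0.32  -0.311       -0.311
#> 8 2step-linear AD         2.06        0.00244          0.12 100.           0.235
#> Best variant: 1step-linear
```

Every variant's group means sit within 1 CL and 2% of the reference values
(`pass` is `TRUE` for all rows): with a wide YC/AD dynamic range the choice
among the three calibration variants matters little. `autoplot()` methods
draw the fits and the report; `tidy()`/`glance()` summarise fitted objects.

A thin command-line front end over the same functions is installed at
`inst/cli/centiloid.R` (subcommands `window`, `suvr`, `calibrate`,
`convert`, `report`, `simulate-suvr`, `simulate-phantom`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/centiloid.R", package = "centiloidr"))')" \
  report --table suvr.csv --out report.csv
```

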