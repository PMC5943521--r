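---
title: "Level-2 Centiloid calibration: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-2 Centiloid calibration: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centiloidr)
```

## The calibration model

Amyloid-PET SUVR values from different acquisition windows and
quantification pipelines live on different linear scales. The working model
of this package is that each measurement method $m$ observes a subject's
latent amyloid burden $T_i$ (expressed on the standard scale) through an
affine map with independent noise:

$$ M_{i} = \alpha_m T_i + \beta_m + \varepsilon_{im}, \qquad
   \varepsilon_{im} \sim N(0, \sigma_m^2). $$

Level-2 calibration estimates, from paired measurements, the affine map
taking a non-standard method onto the standard scale $S$, after which the
anchored Centiloid conversion

$$ \mathrm{CL}(v) = 100\,\frac{v - \bar S_{YC}}{\bar S_{AD} - \bar S_{YC}} $$

places the young-control group mean at 0 and the Alzheimer's-disease group
mean at 100. Everything in the package is in the currency of
`linear_transform` objects — slope/intercept pairs with direction labels —
which can be fitted, inverted, composed and applied.

Two modelling questions shape the API:

**Regression family.** Ordinary least squares (`fit_ols()`) assumes the
predictor is error-free. In method-comparison data both variables are
noisy, so the OLS slope is attenuated by the predictor's reliability
$\sigma_x^2 / (\sigma_x^2 + \sigma_e^2)$ and the fit depends on which
variable is called the predictor. Deming regression (`fit_deming()`)
models error on both axes with variance ratio $\lambda =
\sigma^2_{e,y}/\sigma^2_{e,x}$ and uses the closed-form moment solution

$$ \hat\beta = \frac{(s_{yy} - \lambda s_{xx}) +
   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}}, $$

with the intercept fixed by the centroid. It is symmetric: fitting
`y ~ x` with $\lambda$ and `x ~ y` with $1/\lambda$ returns exact inverse
transforms, verified numerically in the test suite.

**Pathway structure.** `pathway_spec()` encodes a calibration as an ordered
chain of regression steps, each declaring its response, predictor and
family. The convention — encoded as data, not code — is that the method
nearer the standard is the predictor of each step. `run_pathway()` fits
each step, inverts it so it points toward the standard, and composes the
chain. The built-in variants are the direct one-step fits (`MM40 ~ S`, OLS
or Deming) and the two-step chain (`MM40 ~ MM50` then `MM50 ~ S`, both
OLS), whose composite estimates more parameters than it finally uses —
which is exactly the comparison the report machinery is built to quantify.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `lambda` | `fit_deming()`, `run_pathway()` | 1 | Error-variance ratio of response to predictor; 1 (orthogonal regression) is the conventional choice when both methods are comparably noisy, and no better value is identifiable from paired data alone. The axis-swap symmetry holds for any λ under the reciprocal swap. |
| `rule`, `edge_tol` | `select_frames()` | `"full"`, 1 s | A frame is selected when its interval lies inside the window up to a 1-second tolerance for timing jitter; on schedules that tile the window exactly the tolerance is inert. A midpoint rule is available for schedules that straddle window edges. |
| `weighting` | `average_frames()` | `"uniform"` | Plain voxel-wise averaging of the selected frames; duration weighting is opt-in for unequal frame lengths. |
| `statistic` | `voi_statistic()` | profile-dependent | Mean over standard VOIs (standard profile) vs median over tissue-masked VOIs (median-based profile); the median of an even voxel count is the midpoint of the central pair. |
| `max_mean_percent_diff`, `max_mean_cl_diff` | `tolerance_config()` | 2%, 1 CL | The conventional acceptability thresholds for group-mean agreement of a level-2 transform. |
| anchors | `centiloid_anchors()` | derived from data | By default `anchors_from_table()` uses the standard method's YC/AD group means, so the reference rows of a report land at exactly 0 and 100 CL; fixed published anchors can be supplied instead. |

## The synthetic-data module

`generate_suvr_dataset()` draws a latent value per subject from its group
distribution and observes it through every method's map with independent
noise. The defaults define the simulated study conditions: 34 YC and 45 AD
subjects (the size of the public reference cohort), group means 1.0095 and
2.0761 SUVR (the anchor values), within-group SDs 0.06 and 0.35 SUVR
(plausible spreads for an amyloid-negative and a clinically diagnosed AD
group; no published within-group SDs exist for the reference table, so
these are package choices), method maps $S = T$,
$MM50 = 1.25T + 0.10$, $MM40 = 1.18T + 0.07$ (non-standard processing
yields larger values; the earlier acquisition window slightly smaller ones
than the later window), and 0.05 SUVR noise on every method. Because the
standard method is itself noisy, regressions on these data have errors in
both variables by construction.

The generator emulates the *statistical* structure the calibration assumes
— bimodal dynamic range, affine inter-method maps, independent
homoscedastic noise — and deliberately not the imaging reality behind it:
no anatomy, no registration or segmentation error (spatial normalization is
out of scope; masks are supplied in image space), no shared-frame
correlation between overlapping acquisition windows, and no
uptake-dependent noise unless the proportional mode is switched on.
Passing tests therefore demonstrate that the machinery is correct under its
own model, not that any particular site's data satisfy that model.

`generate_dynamic_phantom()` builds 4D series whose two regions carry
piecewise-constant time-activity values, so windowed averages and SUVRs
have closed forms against which the windowing and VOI code are checked
exactly.

## Numerical conventions and degenerate inputs

* Deming fitting uses the closed form above for determinism and speed; the
  test suite keeps an independent numerical minimizer of the weighted
  orthogonal loss as an oracle (agreement to 1e-8).
* A zero-slope fit (constant response) is flagged non-invertible and
  rejected by `invert_transform()` and `run_pathway()`; `fit_deming()`
  refuses zero-covariance samples, where the line orientation is undefined.
* Schedules must be non-overlapping and strictly positive in duration;
  sub-millisecond numeric jitter from unit conversion is tolerated.
  Millisecond-unit timing (the DICOM frame-reference-time convention) is
  converted on ingestion; the reference time is treated as the frame start,
  with a documented midpoint switch, keeping the core unambiguous and
  pushing dialect questions to the adapter.
* NaN voxels inside a mask are excluded with a reported count; an empty or
  all-NaN effective mask is an error naming the VOI.
* Report columns carry full precision; only `print()` rounds (4 decimals
  for SUVR, 2 for percent, 3 for CL). The Centiloid difference column is
  defined as the group-mean SUVR difference scaled by `100 / (ad - yc)` —
  differences of group means, not means of per-subject CL differences;
  the two agree algebraically but can diverge after display rounding.
* "Best variant" is the one minimising the maximum absolute group-mean
  percent difference across groups, ties broken by the YC value — a
  deterministic aggregate rule where per-cell bolding would be ambiguous.

## Problem sizes

The statistical tests use sizes chosen to make their Monte-Carlo bounds
sharp: 16 replicate cohorts of 5 000 subjects per group for the
consistency/attenuation comparison (replicate-mean slopes within 2 SEs of
their closed-form targets), 2 000 per group for mean-convergence checks,
and the default 34/45 cohort for the pathway-equivalence report. The whole
suite runs in well under a minute.

## Limitations

* Confidence intervals on transformed values are not propagated; residual
  SDs are exposed via `glance()` so users can do so externally.
* Weighted Deming, robust regression and bootstrap CIs are out of scope.
* The package does not reproduce any published fitted coefficients: that
  requires the original reference images and SPM-based spatial processing,
  which are intentionally outside the package boundary. VOI definitions,
  tissue segmentations and spatial normalization are inputs, not
  computations.
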