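---
title: "Regression method choice and its impact on bio-optical carbon estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression method choice and its impact on bio-optical carbon estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbpcarbon)
```

## The problem

Empirical ocean-colour algorithms are linear models fitted once to a
finite set of field match-ups and then applied to millions of float or
satellite observations. Two families of estimators exist for the line
`y = B·x + A`: type-I (OLS), which minimizes vertical deviations and is
the right tool when the aim is predicting a random `y` from an `x` that is
controlled or essentially error-free, and type-II (SMA, MA, RMA), which
treat the deviations on both axes symmetrically and are the right tool
when both variables are measured with comparable uncertainty and the
slope/intercept themselves are the quantities of interest. The package
implements both families, the carbon models built on their coefficients,
and the statistics that translate the method disagreement into carbon
units.

## Estimators and their numerical conventions

With centered sums `Sxx`, `Syy`, `Sxy`:

* OLS: `B = Sxy/Sxx`; standard errors from the classical residual-variance
  formulas (these match `stats::lm`, which the tests use as a
  cross-check).
* SMA: `B = sign(r)·sqrt(Syy/Sxx)`. The sign convention is taken from the
  correlation, since the standard-deviation ratio alone is magnitude-only;
  consequently the identity linking the families is `B_SMA = B_OLS/|r|`
  (equal to `B_OLS/r` for positive correlation).
* MA: `B = [(Syy − Sxx) + sqrt((Syy − Sxx)² + 4·Sxy²)]/(2·Sxy)`, the
  perpendicular-distance minimizer; undefined orientation when `Sxy = 0`.
* RMA: MA on range-normalized data, slope back-transformed by
  `range(y)/range(x)`. The normalization makes mixed units workable but
  also makes single outliers stretch the ranges, so outliers must be
  screened first; a test documents the sensitivity.

All four lines pass through the centroid, and `r`/`r²` are properties of
the data, not of the method.

Three conventions were genuinely open and are fixed as follows:

* **Type-II standard errors.** The slope standard error of SMA/MA/RMA is
  set to the OLS slope standard error (standard model-II practice), and
  the intercept error is propagated through the centroid constraint as
  `se_A² = se_B²·x̄² + s_res²/n`, with `s_res²` the vertical residual
  variance about the method's own line. Printed ± values on intercepts
  are treated as standard errors throughout, not confidence half-widths.
* **Significance gate.** An SMA slope cannot itself be tested for
  significance, so `fit_sma()` is gated on the two-tailed correlation
  t-test `t = r·sqrt(n−2)/sqrt(1−r²)` at `alpha = 0.05` by default
  (overridable). A perfect correlation is significant by convention and
  flagged degenerate.
* **Missing data.** Rows with non-finite values are dropped at ingestion
  and counted (listwise deletion); no imputation. Variables are fitted in
  linear space; any transformation is the caller's responsibility.

## Carbon models

`C_phyto = (b_bp − b^k_bp)·SF`. The background `b^k_bp` is the intercept
of the TChla→b_bp fit with the orientation fixed — chlorophyll independent,
backscattering dependent — and `derive_bbpk()` refuses a dataset whose
labels indicate the reverse, because for this asymmetric
parameter-estimation problem the variables cannot be interchanged. `SF`
(mg C m⁻²) is calibrated once so the mean Chl:C over the match-ups equals
a target of 0.010, and then shared by the OLS and SMA branches of any
comparison, so that every C_phyto difference is attributable to `b^k_bp`
alone. Calibration uses the mean of per-sample ratios
`TChla/(b_bp − b^k_bp)` (a ratio-of-means variant is available); samples
with `b_bp ≤ b^k_bp` are excluded and counted. Note that the mean of
ratios is sensitive to samples whose backscattering excess is barely
positive — their ratios are huge — so on noisy match-ups it lands above
the ratio-of-means value; this is a property of the chosen statistic, not
a bug, and both variants are exposed. Negative C_phyto values (b_bp below
the background) are retained and flagged by default, because clamping
silently changes depth-integrated budgets; `clamp_negative = TRUE` is
available. `b^k_bp` is treated as constant in space and time, a deliberate
simplification; spatially varying backgrounds are out of scope.

`POC = B·b_bp + A` is the symmetric case: SMA is the recommended default,
OLS the comparator. The mean C_phyto/POC ratio over match-ups is reported
as a plausibility diagnostic (phytoplankton is canonically a ~30%
contributor to POC) but never enforced in any fit.

## Profile quality control

Despiking follows the residual-against-running-median rule: residual =
value − running median (5-sample window), threshold = 2 × the 90th
quantile of the residual signal, points above the threshold removed as
positive spikes. Numerical choices:

* Quantiles use linear interpolation between order statistics (type 7),
  configurable; the quantile is computed over the full signed residual
  signal by default (a positive-only option exists).
* The window shrinks symmetrically (staying odd) at profile ends, so a
  locally linear profile has exactly zero residual everywhere and the
  finest-resolution near-surface points are never discarded for lack of
  filter support. The window is counted in samples, not meters, because
  float resolution varies with depth.
* A non-positive threshold — which arises exactly on noise-free or
  constant profiles, where at least 90% of residuals are identically
  zero — removes nothing; the literal rule would otherwise flag the
  curvature extrema of a perfectly smooth profile.
* Removed points are dropped, not interpolated; the budget integrator
  handles irregular grids natively. Negative excursions are never
  removed.

Binning averages a closed interval ±halfwidth (default ±0.5 m) around
each nominal depth, omitting and counting empty bins; it is idempotent at
fixed centers. Bottle matching picks the nearest binned depth within a
tolerance (default 0.5 m), breaking exact ties toward the shallower
depth. Dark-offset subtraction flags points driven negative.

## Budgets and impact statistics

Per-cast depth integrals are trapezoidal on the native grid, restricted
to the requested range with no extrapolation beyond the sampled span
(coverage is recorded); casts with fewer than two points in range yield a
missing value. Cast integrals are then accumulated trapezoidally over
cast time, which makes the total additive over contiguous chunks that
share a boundary cast. Default ranges: 0–250 m for float budgets,
0–400 m for cruise casts, both configurable and echoed in reports.
Depth-less satellite series are compared as time-mean differences and as
that difference relative to the suitable-method mean.

`RPD = 100·(unsuitable − suitable)/suitable`, signed, with the
overestimate-by-the-unsuitable-method case positive. The statistic is
asymmetric: `rpd(a, b) = −rpd(b, a)·a/b`. For the C_phyto model the
anomaly field is the constant `Δb^k_bp·SF`, so the budget RPD has the
closed form `100·Δb^k_bp·SF·(depth span)·(time span)/integral_suitable`
— an identity the tests verify to 1e-8 — and its magnitude is governed by
how much low-signal deep water the integration range contains.

## What the synthetic data emulate — and what they do not

Generators are deterministic functions of an integer seed.

* **Match-ups** (`gen_matchups()`): latent `x*` lognormal for
  chlorophyll-like variables (strictly positive, right-skewed) or
  Gaussian for abstract scenarios; `x = x* + e_x`, `y = B·x* + A + e_y`
  with independent Gaussian errors, optional inflated-error outliers, and
  reject-and-redraw positivity for physical variables (redraws counted).
  The cruise conditions are n = 300 pairs (about 27 monthly cruises × 12
  bottle depths, minus losses); TChla lognormal around 0.3 mg m⁻³
  (sdlog 0.9, range ≈ 0.03–3); TChla→b_bp truth slope 6.1×10⁻³ m⁻¹ per
  mg m⁻³ and intercept 5.5×10⁻⁴ m⁻¹ — the slope is set so the calibrated
  SF lands in the ~16,000 mg C m⁻² regime of recalibrated 700 nm scaling
  factors, since SF ≈ 1/(slope·0.010) when noise is small; error sds
  0.05 mg m⁻³ (pigment analysis plus sampling mismatch) and 8×10⁻⁴ m⁻¹
  (backscatter methodological plus biogeochemical scatter). The b_bp→POC
  truth is B = 4×10⁴ mg C m⁻³ per m⁻¹, A = 10 mg C m⁻³, error sds
  1×10⁻⁴ m⁻¹ and 10 mg C m⁻³ — coefficients in the range reported for
  open-ocean POC–backscattering fits.
* **Float series** (`gen_profile_series()`): 87 casts at 5.4-day cadence
  (~15 months) on the three-segment grid (10 m for 1000–250 m, 1 m for
  250–10 m, 0.2 m for 10–0 m); baseline = deep background 6×10⁻⁴ m⁻¹
  (slightly above the non-algal intercept, as deep particle fields are)
  plus a seasonally modulated surface-intensified exponential layer and a
  Gaussian subsurface maximum; white noise sd 5×10⁻⁵ m⁻¹; positive spikes
  at ~1.5% of samples with shifted-exponential amplitudes of 5–50× the
  noise sd. Spikes are placed with a minimum separation of 3 samples and
  never at a cast's first or last sample: an endpoint spike is invisible
  to any shrinking median filter, and overlapping spikes would
  contaminate each other's median reference, making the recorded truth
  unusable for scoring recall.
* **Gridded series** (`gen_gridded_series()`): monthly chlorophyll with a
  seasonal cycle and lognormal variability, `b_bp = B·TChla + A + e`.
  When a target r² is requested the noise is residualized against the
  realized chlorophyll and rescaled so the in-sample r² equals the target
  exactly — the clean way to "tune noise into a band" — and the request
  is refused as infeasible when the deterministic signal has no variance
  (zero true slope). A side effect worth knowing: because the tuned noise
  is orthogonal to x in-sample, the OLS fit of the generated series
  recovers the generating coefficients exactly.

These generators reproduce the statistical structure the method
comparison depends on — errors on both axes, attenuation, irregular
grids, positive spikes, moderate gridded correlation — but not optical
physics: no spectral shapes, no radiative transfer, no satellite merging
artifacts, no bio-fouling drift, and measurement errors are independent
Gaussian. Passing tests therefore demonstrate the correctness and
internal consistency of the estimators, QC and budget machinery under
those assumptions, not the field accuracy of any particular coefficient
value on real archives.

## Problem sizes and reference conditions

The shipped reference analysis (`run_reference_analysis()`) uses 300
match-ups per relationship, 87 float casts, 27 cruise casts (0–400 m at
1 m) and 216 months tuned to r² = 0.56, with the satellite branch applying
the original 443 nm scaling factor of 13,000 mg C m⁻². The test suite
exercises reduced versions (10–120 match-ups, 5–10 casts, 60 months) plus
50 × n = 10,000 replicates for the attenuation recovery (OLS → 2/1.0625 ≈
1.8824, SMA → 2.000) and 100 single-cast profiles for despiking
performance. Sub-seeds are derived from the master seed per stage so the
stages are independently reproducible.

## Known limitations

* Uncertainties (`se_A`, `se_B`) are reported but not propagated into
  budgets; no bootstrap or permutation intervals.
* The correlation gate is the only significance machinery; no slope
  tests for type-II fits, by construction.
* `b^k_bp` constant in space/time; single wavelength per analysis (no
  spectral conversion of b_bp between bands).
* Budget comparisons quantify method impact; they are not a statistical
  test of whether two budgets differ.
* The satellite branch works on an averaged series per time step; no
  per-pixel mapping or regridding.
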