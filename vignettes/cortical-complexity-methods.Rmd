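---
title: "Methods: box-counting fractal dimension and the cohort battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-counting fractal dimension and the cohort battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticalfd)
```

## The estimator

The box-counting dimension of a bounded set is defined through the scaling
of covering numbers: if N(r) boxes of edge r are needed to cover the set,
then N(r) ∝ r^−D as r → 0. For a voxelized cortical ribbon we can only probe
a finite range of scales, so the package implements the estimator as three
explicit, separately testable steps:

1. **`count_filled_boxes(mask, r)`** overlays a *single fixed grid* of
   non-overlapping r×r×r boxes and counts boxes containing at least one
   foreground voxel. The grid is anchored at the minimal corner of the tight
   foreground bounding box. Anchoring is a genuine degree of freedom —
   nothing in the counting rule itself pins the grid origin — and the
   bounding-box anchor was chosen because it makes counts deterministic and
   exactly translation invariant (a mask shifted inside a larger empty
   volume produces the identical curve, which the test suite asserts). No
   multi-offset minimum or average is taken. Partial boxes at the far
   boundary count like any other box: every foreground voxel must belong to
   some box.
2. **`box_count_curve(mask, r_min, r_max)`** evaluates N(r) at every integer
   r in the window, increasing the edge one voxel at a time.
3. **`estimate_fd(curve)`** fits log N(r) on log r by unweighted OLS
   (natural logs; the slope magnitude is base invariant) and reports
   |slope|, the intercept, and R² of the fit.

Hemisphere ribbons use the window r = 2…30 voxels, lobar masks r = 2…14
(`region_fd()` dispatches these and records the window in the estimate).
r is measured in voxels throughout: the intended inputs are 1 mm isotropic
conformed volumes, and `voxel_size_mm` is carried as metadata only, with a
warning when voxels are anisotropic.

### The linear-r fitting convention and its cost

Because r advances linearly, the fitted points are *not* equally spaced on
the log axis: small scales are sparsely represented and the crowded large-r
points — exactly the ones most distorted by ceiling effects on a finite
grid — dominate the fit. The package keeps this convention deliberately (it
is the convention the pipeline is meant to reproduce, and lobar windows on
real ribbons sit in a regime where it is serviceable), but the vignette must
be explicit about what it does to small analytic phantoms, because the test
suite measures it:

* a filled 64³ cube reads FD ≈ 2.71 at the hemisphere window. This is not a
  counting bug: any valid covering forces N(2) = 32768 and
  N(30) = ceil(64/30)³ = 27, which already pins the end-to-end slope near
  −2.62; the OLS over all 29 points lands at −2.71. The oracle-validated
  counts are exact; the window is simply wide relative to the object.
* a level-4 Menger sponge (81³) reads FD ≈ 2.549 against the theoretical
  log 20 / log 3 ≈ 2.7268 at the lobe window, a −0.18 bias with the same
  origin (at r ∈ {3, 9} the counts equal the exact self-similar values;
  intermediate r are inflated by ceiling effects). The dimension-recovery
  tolerance for the sponge was therefore frozen at ±0.20 from an oracle run
  before the tests were written.
* exact power-law *curves* — inputs with no quantization — recover their
  exponents to machine precision, which isolates the bias to the counting
  geometry, not the fit.

Consequently FD values produced by this package are comparable with each
other and with pipelines sharing the convention, but not directly with
estimators that resample to equal log spacing.

Degenerate inputs are flagged rather than hidden: estimates outside (0, 3]
carry a `fd_out_of_range` flag (downstream outlier screening is the intended
consumer), and three or more identical trailing counts — the signature of a
window exceeding the structure size — set `flat_tail`. Empty masks, windows
with fewer than two points, and zero counts (log undefined) are errors.

## Parcellation

Lobar masks select DK label codes: 11 frontal, 9 temporal, 5 parietal and
4 occipital labels per hemisphere, with right-hemisphere codes equal to the
left codes plus 1000. That grouping covers 29 of the 34 DK cortical regions;
the insula and the four cingulate regions are intentionally assigned to no
lobe, so lobar masks exclude them while hemisphere masks (ribbons, or the
union of all 1001–1035 / 2001–2035 codes when no ribbon volume exists) still
contain them. The fallback from ribbons to label unions is recorded in the
per-subject provenance field. The grouping ships both in code
(`labels_for_region()`) and as `inst/extdata/dk_lobe_labels.csv` for users
with alternative label dialects.

## The cohort battery

All models are ordinary least squares on complete cases of the involved
columns, with sex coded female = 0 / male = 1 (a negative sex estimate means
lower FD in males) and TBV in mm³.

* **Outlier screening** precedes all modelling: per FD measure, values
  outside [Q1 − 3·IQR, Q3 + 3·IQR] become missing. The rule is per data
  point — a subject's other measures survive — and quartiles use the
  linear-interpolation quantile definition (R type 7), which is the one
  documented convention; other environments' defaults differ slightly.
* **Age models**: `FD ~ age + sex + tbv`, optionally with `I(age^2)`. Age
  enters raw (uncentered) so the reported age and age² estimates are on the
  natural scale; the resulting collinearity is tolerated and the design
  condition number is attached to quadratic fits. AIC uses the Gaussian
  likelihood with the residual variance counted as a parameter (the `stats::AIC`
  convention); only differences between models on identical rows are
  meaningful, and `compare_models_aic()` refuses anything else. Ties prefer
  the simpler linear model. `delta_aic` is reported so callers may apply the
  conventional "differences below ~2 are indistinguishable" materiality
  rule; the package encodes no significance claim from AIC alone.
* **Asymmetry**: AI = 2(L − R)/(L + R), positive = leftward. The three-way
  models regress each side's FD on age, sex, the *subject-level* AI and all
  interactions up to age × sex × AI; TBV is excluded from this model set by
  default (it reports exactly the seven interaction-battery terms) but can
  be added with `include_tbv = TRUE`. The AI main-effects model
  (`AI ~ age + sex + tbv`) does include TBV. Both choices are deliberate
  and overridable.
* **Subgroups**: half-open five-year bins [45, 50), …, with the final bin
  closed [75, 80], so a subject aged exactly 50 belongs to 50–55. The bin
  edges are a documented decision; bins below the minimum n (default 10
  complete rows, the same floor as all fits) are skipped and flagged.
* **Thresholds**: plain Bonferroni constants .05/10 = .005 (FD models),
  .05/5 = .01 (asymmetry models) and .05/20 = .0025 (sex-stratified simple
  regressions), exposed by `fd_alpha_levels()`. No FDR machinery.

## What the synthetic data emulates — and what it does not

**Phantoms** (`make_phantom()`) exist to validate the estimator against
known dimensions: solid cube (3), one-voxel slab (2), one-voxel line (1),
Menger sponge (log 20/log 3), and Mandelbrot percolation, whose box
dimension is log(m³p)/log m conditional on survival. Percolation is the
workhorse because retention p tunes the dimension continuously; extinct
draws are regenerated up to a retry cap.

**Cohorts** (`generate_cohort_table()`) draw age uniformly over [45, 79]
years, sex with 52.46% females, TBV from sex-specific normals
(female 1,051,176 ± 79,038 mm³; male 1,159,948 ± 92,742 mm³), and each
regional FD from
`b0 + beta_age*age + beta_age2*age^2 + beta_sex*sex + beta_tbv*tbv + noise`.
Default coefficients sit at the magnitudes reported for large ageing
cohorts: age slopes around −1e-4 to −3e-4 per year, sex effects of a few
1e-3, quadratic terms (~1e-5) only in the bilateral frontal and right
temporal regions, residual SDs of 0.01–0.023, and a small positive TBV slope
(2e-8 per mm³) reflecting the positive FD–TBV correlation. Extreme outliers
are injected at rate 0.0052 per data point (the reported screening removed
roughly half a percent of points), displaced by 8 residual SDs. Every
generating parameter is returned in `attr(, "truth")` so recovery tests are
automatic. The uniform age distribution is a simplification — real imaging
cohorts are bell-shaped with thin tails — chosen to give every age bin
support.

**Subject volumes** (`generate_subject_volume()`) are an anatomical
caricature, not brains: eight disjoint 24³ compartments (left/right split on
x, lobes in fixed octants of each half) filled with percolation phantoms,
DK codes assigned cyclically within each lobe so exactly the 58 lobe-grouped
labels occur, hemispheres = unions of each side's compartments. The
compartment generator subdivides 24 = 3·2·2·2 with per-level retention
m^(d−3), which preserves the target dimension d at every level. Because the
measured FD at the lobe window sits systematically below the theoretical
dimension at this resolution, the generator carries a frozen calibration
table (mean measured FD over 60 seeded phantoms at each of 25 dimension grid
points) and inverts it monotonically to choose d for a requested target FD
(`target_to_dimension()`; targets outside the calibrated measured range
[≈1.36, 2.72] are clamped). All randomness flows from per-subject,
per-compartment sub-seeds derived from one master seed, so any subject is
regenerable in isolation, and an exact x-mirror mode produces symmetric
subjects for asymmetry validation (mirrored subjects read |AI| < 0.005; the
residue comes from the bounding-box grid anchor, which is not
reflection-symmetric).

Passing tests on these fixtures therefore demonstrate: correct counting
(oracle equivalence), correct fitting (power-law recovery), correct
bookkeeping (labels, AI identities, outlier rule), calibrated inference
(type-I error of the interaction test at the .005 threshold inside its exact
binomial band), parameter recovery at realistic effect sizes, and monotone
tracking of regional complexity differences through the whole volume
pipeline. They do *not* demonstrate anything about partial-volume effects,
scanner noise, segmentation quality, spatial correlation between regions, or
non-Gaussian residuals in real cohorts.

## Problem sizes and runtime choices

The shipped test suite validates the oracle on 50 random masks up to 16³
(all r in 2…8), measures phantoms at 64³/81³, runs recovery and AIC
preference on cohorts of n = 2000 (100 replicates for the preference rate),
calibrates the null interaction test on 200 replicates of n = 2000, and
runs the end-to-end pipeline twice on a 30-subject, 48³ synthetic cohort.
The acceptance script repeats the battery with the null calibration at its
full 2000 replicates. These sizes keep a full run in the tens of seconds on
one CPU while leaving the binomial acceptance bands meaningful.

## Known limitations

* The linear-r log–log fit biases FD downward on small grids (quantified
  above); results are convention-bound.
* Lobar windows (r = 2…14) span less than one decade of scale, so "fractal
  dimension" is an effective, window-relative descriptor rather than a
  limit statement.
* Statistical preference by minimum AIC at these effect sizes
  (β_age² = 1e-5, σ = 0.015, n = 2000) has a true success probability of
  roughly 0.88–0.90 per replicate; rates near that boundary fluctuate
  between runs.
* The percolation compartments at 24³ carry measurement noise of
  0.07–0.12 FD units; rank correlations between target and measured FD
  across 30 subjects are typically 0.85–0.95 per region and occasionally
  dip below 0.8 for a single region by sampling alone.
* Voxel anisotropy is ignored (warned, not corrected); inputs are expected
  in conformed 1 mm space, already voxel-aligned.
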