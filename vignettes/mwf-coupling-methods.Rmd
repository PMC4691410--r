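---
title: "Methods: trajectories, adjacent-WM masks, and residual coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectories, adjacent-WM masks, and residual coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwfcoupling)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunables and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The measurement model

Each scan of each child yields, per cortical region and hemisphere, three
measures: cortical thickness (mm), mean cortical MWF (a fraction,
typically 0.03–0.13 in early childhood), and mean MWF of the white matter
directly adjacent to the region (typically 0.05–0.15). Development over
the studied window (363–2198 days of age, corrected to a 40-week
gestation) is modelled per measure as a logarithmic function of age in
days,

$$ y = a \,\ln(\mathrm{age\ days}) + b + \varepsilon,$$

which captures the fast-then-slowing growth of myelin content and the
analogous (mostly decreasing) trajectory of apparent cortical thickness.
Two alternative forms, linear and quadratic in age (days), are fitted for
model comparison only. All fits are ordinary least squares
(`growth_fit()`), treating the pooled scans as independent observations;
a child-level random intercept can be switched on in the generator to
probe how much the pooling assumption matters, but the analysis stage
deliberately mirrors the pooled design (n = 177 scans) whose degrees of
freedom the downstream p-values assume.

### BIC convention

`BIC()` on a `growth_fit` uses the least-squares form
$n\ln(\mathrm{RSS}/n) + k\ln n$ with $k$ the number of regression
coefficients (2 or 3). Additive constants that do not depend on the model
cancel in BIC *differences*, which is all `select_growth_model()` uses, so
the selected form is identical under any full-likelihood convention;
absolute magnitudes, however, are convention-dependent, and the packaged
reference BIC table (`ref_thickness_bic()`) should be compared
qualitatively (which form wins, and by how much relative to the tie band),
not digit by digit. Competing forms within ΔBIC < 2 of the winner — the
conventional "barely worth mentioning" band — are reported as ties; exact
ties break deterministically in the fixed order logarithmic, quadratic,
linear. A fit whose residual sum of squares is numerical dust relative to
the measure's total variance is flagged as perfect (BIC −∞) rather than
fed to `log()`.

## Age-residualized coupling

Because every measure trends with age, raw cross-measure correlations
mostly restate that children grow. The coupling analysis therefore removes
the fitted logarithmic trend from each measure (`age_residuals()`) and
correlates the residuals per region for three pairs: thickness vs adjacent
MWF, thickness vs cortical MWF, and cortical vs adjacent MWF. Two-sided
p-values use the exact null transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with
$n-2$ degrees of freedom; taking $(r, n)$ directly also lets published
correlation tables be re-assessed (`pearson_p()`).

Family-wise correction is Holm–Bonferroni at α = 0.05. The family is the
set of regional tests within one hemisphere for one measure pair —
m = 33 for a full parcellation — matching a design that corrects across
regions but not across the three scientifically distinct questions.
`family_size` is configurable (e.g. 66 to pool hemispheres); the packaged
reference significance flags are broadly, but not perfectly, reproducible
from the printed r values under m = 33 (e.g. a middle-temporal
thickness–adjacent p of 0.00133 clears the m = 33 Holm threshold yet is
not flagged), so the exact family used for the reference flags is treated
as unrecoverable and the flags as data.

A measure that is constant, or so perfectly age-determined that its
residuals are numerical dust (residual SD below 1e−10 of the raw SD), is
surfaced as a degeneracy — the region is skipped with a warning in
`coupling_analysis()` and reported as `NA` in `contrast_coupling()` —
rather than silently correlated.

## Adjacent white matter by blur-and-subtract

The sampling region for "adjacent" white matter is built from the cortical
parcel itself: the binary parcel mask is convolved slice-wise with a 2-D
Gaussian kernel of FWHM 4 mm (σ = FWHM/(2√(2 ln 2)) ≈ 1.70 mm), after
which every voxel whose tissue class is not white matter is zeroed. What
remains is a weight field on the WM penumbra of the parcel, and the
regional adjacent-WM value is the weighted mean of the quantitative map
under those weights.

Numerical choices: the discrete kernel is truncated at 4σ per axis and
renormalized to unit sum, so in-plane mass is conserved exactly away from
the volume edge; convolution is direct (not FFT) so that voxels beyond the
kernel reach carry exactly zero weight; weights are used as-is (no
binarization), since the blurred mask is superimposed directly — a
binarize-at-threshold option (`binarize_threshold`, e.g. 0.05) exists for
sensitivity analysis. Two genuinely open choices are surfaced as
configuration with documented defaults: the anatomical plane of the 2-D
kernel (default axial, i.e. in-plane of a typical acquisition) and the
binarization just mentioned. Voxel-to-world geometry is a diagonal affine
at 1.2 mm isotropic on phantoms; registration between maps and labels is
assumed already done, and no resampling is implemented.

## The synthetic generator

`simulate_cohort()` emulates the cohort structure the analysis assumes:
134 children and 177 scans (36 children scanned at least twice, 7 of them
three times), ages 363–2198 days with repeat gaps of 365 ± 60 days,
33 bilateral regions whose three measures follow the packaged reference
logarithmic coefficients (`ref_trajectories()`), and per-region trivariate
residuals drawn from a zero-mean normal with the packaged reference
correlation structure (`ref_couplings()`) — all 33 reference correlation
matrices are comfortably positive-definite. Defaults chosen where no
reference value exists, fixed once and documented here:

* **Baseline ages** are uniform on the age range (the age histogram is not
  available in machine-readable form); a truncated-normal option matching
  mean 1044 / SD 523 days is provided.
* **Residual SDs** are 0.1 mm for thickness and 0.01 for both MWF
  measures — the scales at which the reference BIC magnitudes and
  correlation p-values are internally consistent.
* **Regional T₁** defaults are flat at 1400 ms (GM) and 900 ms (WM) with
  25 ms noise — order-of-magnitude 3T early-childhood values; no regional
  reference T₁ exists, so these are deliberately generic, with an optional
  slow logarithmic drift.
* **Right hemisphere** mirrors the left-hemisphere reference coefficients,
  which are the only printed ones.
* **Within-child dependence** is off by default (pooled-scan analysis); a
  child-level random intercept is available.

What the generator does *not* emulate: spatial autocorrelation of maps
beyond piecewise-constant parcels plus voxel noise, registration and
segmentation error, motion artifacts, missing data, or any temporal offset
between cortical and myelin development. Passing tests therefore show that
the *pipeline* is correct and calibrated under its own statistical
assumptions — not that those assumptions hold in real cohort MRI.

`simulate_phantom()` builds the geometric companion: a cuboidal WM core
wrapped in a GM ribbon cut into angular-sector parcels, so every parcel
has a WM-adjacent border, on a 24³ grid at 1.2 mm by default. It exists to
make the mask geometry exactly checkable (piecewise-constant maps
round-trip their generating values bit-for-bit through extraction).

## Ideal T₁ contrast

`ideal_signal()` evaluates the proton-density-free inversion-recovery
signal $1 - 2e^{-TI/T_1}$ at TI = 950 ms (a typical pediatric MP-RAGE
inversion time; configurable). Contrast is the signed difference
$S_{WM}-S_{GM}$ — positive for the usual bright-WM appearance, and
antisymmetric under tissue exchange; a Michelson-style normalized variant
is available. The contrast–thickness correlation is age-residualized on
both sides by default, consistent with the other couplings; a raw mode
exists because the convention is ambiguous in the field.

## Monte-Carlo and seeding practice

All simulation entry points accept a single seed and then consume one
continuous RNG stream; multi-replicate studies (the test suite's
calibration checks, `scripts/acceptance.R`) seed **once** and let the
stream run rather than reseeding each replicate, because Mersenne–Twister
streams initialized from consecutive small integers are not guaranteed
independent — a failure mode we observed directly as spurious
between-replicate structure in one consecutive-seed family while disjoint
seeds reproduced the theoretical family-wise error rate.

Problem sizes used by the packaged studies, chosen to give decisive
Monte-Carlo error while keeping a laptop run comfortable: parameter
recovery uses 100 cohorts of 177 scans; model-selection and family-wise
error calibration use 200 replicates; geometry oracles run on ≤ 20³
grids where direct-sum convolution is exact and fast.

## Known limitations

* The analysis inherits the pooled-scans independence assumption; its
  p-values are mildly optimistic for children contributing repeat scans.
* BIC magnitudes are convention-dependent (above); only differences are
  interpreted.
* The blur plane and mask binarization are conventions, not estimates;
  conclusions that depend on them should be checked under the alternative
  settings.
* Reference coefficients are left-hemisphere only and carry printed
  precision (3 decimals); quantities derived from them — notably p-values
  recomputed from rounded r — agree with reference values only to within
  that rounding.
* The phantom geometry is deliberately minimal; it validates the mask
  algebra, not anatomical realism.
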