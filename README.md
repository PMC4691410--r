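# mwfcoupling

Region-wise analysis of the coupling between cortical thickness, cortical
myelin water fraction (MWF), and the MWF of white matter directly adjacent
to the cortex across early childhood (roughly 1–6 years of age).

## The problem

Cortical thickness is usually measured from T₁-weighted MRI, whose
gray–white contrast is itself a function of white-matter myelination. In
rapidly myelinating young brains it is therefore unclear whether apparent
cortical thinning reflects cortical architecture or merely adjacent
white-matter maturation. The analysis this package implements separates the
two by (i) fitting each regional measure's age trajectory, (ii) removing
the age trend, and (iii) asking whether the age-independent residuals of
thickness and myelin are still coupled — per region, with family-wise
correction — and by checking how ideal T₁ image contrast relates to
thickness.

For whom: imaging scientists who have regional measures (from a
Freesurfer-style parcellation plus quantitative MWF/T₁ maps) and want a
tested, reproducible implementation of the trajectory/residual-coupling
pipeline, including the adjacent-white-matter mask construction — plus a
synthetic cohort and phantom generator so every stage can be exercised and
validated without access to cohort MRI.

## The model

For a region–hemisphere–measure series *y* against age *t* (days, corrected
to a 40-week gestation), growth is modelled as

- logarithmic: *y = a* ln *t* + *b*
- linear: *y = a t + b*
- quadratic: *y = c₂t² + c₁t + c₀*

fitted by OLS and compared with BIC = *n* ln(RSS/*n*) + *k* ln *n*.
Residuals from the logarithmic trend are correlated between measure pairs
with Pearson's *r*; two-sided p-values use *t = r√(n−2)/√(1−r²)* on *n−2*
df, and significance is flagged by Holm–Bonferroni step-down over the
*m* = 33 regional tests per hemisphere and pair at α = 0.05.

Adjacent white matter for a cortical parcel is defined geometrically: the
binary parcel mask is blurred slice-wise with a 2-D Gaussian kernel
(FWHM 4 mm, σ = FWHM/(2√(2 ln 2))), all non-white-matter voxels are then
zeroed, and the remaining weights are used for a weighted regional mean of
the quantitative map. Ideal T₁-weighted signal is *S* = 1 − 2e^(−TI/T₁)
with TI = 950 ms, and gray/adjacent-WM contrast is *S*(WM) − *S*(GM).

## Worked example

Simulate a 177-scan cohort for one region from the packaged reference
coefficients, fit its thickness trajectory, and test the residual
couplings:

```r
library(mwfcoupling)
set.seed(42)
cohort <- simulate_cohort(
  cohort_spec(),                                   # 134 children, 177 scans
  trajectory_specs(regions = "caudal_middle_frontal", hemispheres = "left"),
  coupling_specs(regions = "caudal_middle_frontal", hemispheres = "left"))

fit_growth_models(cohort$age_days, cohort$thickness_mm)
#> BIC model selection:
#> logarithmic   quadratic      linear 
#>     -822.37     -816.31     -814.57 
#> best: logarithmic 

coupling_analysis(cohort, family_size = 33)
#> Coupling analysis: 1 regions x 3 pair(s), n = 177 scans
#>   thickness_adjacent    1/ 1 significant (alpha 0.05, Holm m = 33), r in [-0.289, -0.289]
#>   thickness_cortical    1/ 1 significant (alpha 0.05, Holm m = 33), r in [-0.326, -0.326]
#>   cortical_adjacent     1/ 1 significant (alpha 0.05, Holm m = 33), r in [0.524, 0.524]
```

The fitted logarithmic slope (−0.217 mm per ln-day here) estimates the
generating reference slope −0.23 for this region; the recovered residual
correlations (−0.289, −0.326, 0.524) estimate the generating structure
(−0.274, −0.27, 0.556): thinning is only weakly coupled to adjacent myelin,
while the two MWF measures travel together. The ideal-contrast helper
returns, e.g., `t1_contrast(t1_gm_ms = 1400, t1_wm_ms = 900)` → `0.3186844`.

`run_pipeline(pipeline_config())` chains simulation, phantom extraction,
fitting, coupling and contrast and writes seed- and config-stamped TSVs;
`inst/cli/mwfcoupling.R` exposes the same stages as shell subcommands.

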