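Package: mwfcoupling
Title: Coupling of Cortical Thickness and Myelin Water Fraction in Early Childhood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-wise analysis of the coupling between cortical thickness,
    cortical myelin water fraction (MWF), and adjacent white-matter MWF across
    early childhood (1-6 years). Builds adjacent white-matter sampling masks
    from cortical parcellations by 2-D Gaussian blurring and mask subtraction,
    extracts regional means from quantitative NIfTI maps, fits logarithmic,
    quadratic and linear growth trajectories with BIC model selection,
    computes age-residualized Pearson couplings with Holm-Bonferroni
    family-wise correction, and evaluates ideal inversion-recovery T1 contrast
    between gray matter and adjacent white matter. Ships a synthetic cohort
    and phantom generator parameterized by reference regional growth
    coefficients so the full pipeline is testable without access to cohort MRI.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
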