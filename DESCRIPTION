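Package: prfcss
Title: Population Receptive Field Modelling with Compressive Spatial Summation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population receptive field (pRF) analysis of visual
    cortex with the compressive spatial summation (CSS) model. Generates
    wide-field bar-aperture stimulus sequences, predicts BOLD responses by
    Gaussian spatial summation, a compressive exponent and HRF convolution,
    estimates pRF parameters per voxel by grid search plus bounded nonlinear
    refinement, and derives eccentricity, polar angle and pRF size. Downstream
    analytics include visual field coverage maps, density-by-eccentricity
    curves with linear and generalized-logistic fits, laterality and vertical
    bias indices, eccentricity-band summaries of pRF centers and sizes,
    streamline filtering and ensemble concatenation, ROI intersection, and
    track-density-weighted eccentricity-band proportions of white-matter tract
    endpoints in early visual cortex. A synthetic-data module produces
    ground-truth voxel populations, noisy BOLD, eccentricity surfaces and
    endpoint sets for parameter-recovery studies, and a statistics module wraps
    repeated-measures linear mixed models with Satterthwaite degrees of
    freedom, Tukey HSD post-hocs, paired tests and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    withr,
    yaml,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
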