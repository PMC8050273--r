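# prfcss

Population receptive field (pRF) analysis of visual cortex with the
compressive spatial summation (CSS) model, in R.

## The scientific problem

High-level visual regions — for example the face-selective regions of the
ventral and lateral processing streams — differ in how they sample visual
space. Ventral populations concentrate their pRFs around the center of gaze
(a foveal bias), while lateral populations place pRF centers far into the
periphery and have much larger pRFs; these functional differences are
mirrored by how each region's white-matter tracts distribute across the
eccentricity map of early visual cortex. Asking such questions requires a
chain of quantitative tools: a bar-sweep stimulus model, a voxelwise pRF
forward model and estimator, visual-field-coverage analytics, eccentricity-
band summaries, tract-endpoint quantification, and group statistics. `prfcss`
implements that chain end to end, together with a seeded synthetic-data
module so every stage can be validated against known ground truth.

## The model

Each voxel is a compressive spatial summation pRF: an isotropic 2-D Gaussian
with center (x, y) and SD σ (degrees of visual angle) whose overlap with the
binarized stimulus aperture S_t is passed through a static compressive
nonlinearity before HRF convolution:

    r_t   = ( Σ_pixels S_t · G_{x,y,σ} )^n ,   0 < n ≤ 1
    BOLD  = β · (r ∗ h)(t)  sampled at the TR

The pRF size is σ/√n; eccentricity and polar angle are √(x²+y²) and
atan2(y, x). Parameters are estimated per voxel by a coarse grid search
(gain solved in closed form) followed by bounded nonlinear refinement
minimizing the sum of squared errors; voxels are retained when the model
explains more than 20% of variance and σ did not stick at the 0.21° floor.
Visual field coverage is the proportion of an ROI's pRFs — binary disks of
radius σ/√n — covering each point of the field; tract endpoints are assigned
the eccentricity of their nearest surface vertex and summarized as
track-density-weighted proportions across the 0–5°, 5–10°, 10–20° and
20–40° bands.

## Worked example

Simulate a foveally-biased ("ventral-like") voxel population, fit the CSS
model to its noisy BOLD responses, and summarize the surviving pRFs:

```r
library(prfcss)

design <- buildBarDesign()        # 40° field, 5.7° bar, 4 orientations
design
#> BarDesign: 40 deg field, 5.7 deg bar, 4 orientations x 2 directions,
#>   12 steps of 2 s; baseline 12 s
scheduleDuration(design)
#> [1] 204

aperture <- generateAperture(design, gridResolution = 51)
hrf <- canonicalHRF(dt = 1)

truth <- samplePopulation(ventralProfile(nVoxels = 30), seed = 1)
bold <- generateBold(truth, aperture, hrf, tr = 2,
                     noiseSd = "targetVE", targetVE = 0.6, seed = 2)
fits <- fitPRFSet(bold, aperture, hrf, tr = 2)
fits
#> PRFFitSet: 30 voxel fit(s); median VE 0.616

roi <- applyInclusion(fits, veMin = 0.20, minVoxels = 10,
                      roiLabel = "ventral-like", hemisphere = "right")
roi
#> ROIVoxelSet: ventral-like ( right ), 28 voxels after inclusion

round(centerBandProportions(roi)$fractions, 3)
#> [1] 0.786 0.179 0.036 0.000
round(medianSizeByBand(roi), 2)
#> [1] 3.48 5.33 9.66   NA

map <- computeVFC(roi, gridResolution = 51, fieldExtent = 40)
lin <- fitDensityLinear(densityVsEccentricity(map))
round(c(slope = lin$slope, intercept = lin$intercept, adjR2 = lin$adjR2), 4)
#>     slope intercept     adjR2
#>   -0.0317    0.5126    0.7593
round(lateralityIndex(map), 3)
#> [1] 0.724
```

Reading the numbers: the run schedule totals 204 s (3 min 24 s); noise was
calibrated so the median variance explained lands near the 0.6 target; 28 of
30 voxels pass inclusion; 78.6% of recovered pRF centers fall in the central
0–5° band (the generator's foveal concentration, recovered through the full
simulate–fit–summarize chain); median pRF size grows with eccentricity
(3.5° → 9.7°); coverage density falls with eccentricity (negative slope) and
is strongly lateralized toward the contralateral hemifield (laterality index
0.72).

The same chain runs for peripherally-extended ("lateral-like") populations
via `lateralProfile()`, for streamline sets via `synthStreamlines()` /
`filterStreamlines()` / `concatenateEnsemble()` / `endpointBandProportions()`,
and for group statistics via `simulateBandTable()` and `bandByStreamAnova()`.
`runPipeline(defaultRunConfig())` executes everything and writes a TSV/JSON
report bundle.

## Package tour

| Area | Entry points |
|---|---|
| Stimulus | `buildBarDesign`, `generateAperture`, `scheduleDuration` |
| Forward model | `prfParams`, `gaussianField`, `predictNeural`, `canonicalHRF`, `predictBold` |
| Fitting | `fitPRFSet`, `fitPRF`, `varianceExplained`, `derivedMetrics`, `applyInclusion`, `proportionModulated` |
| Synthetic data | `ventralProfile`, `lateralProfile`, `samplePopulation`, `generateBold`, `synthEVCSurface`, `synthEndpoints`, `synthStreamlines` |
| Coverage | `computeVFC`, `densityVsEccentricity`, `fitDensityLinear`, `fitDensityLogistic`, `lateralityIndex`, `verticalBiasIndex`, `centerBandProportions`, `medianSizeByBand` |
| Connectivity | `filterStreamlines`, `concatenateEnsemble`, `cullConnectome`, `intersectROI`, `fwmtPercentage`, `assignEndpointEccentricity`, `endpointBandProportions`, `makeDiskROI` |
| Statistics | `bandByStreamAnova`, `bandROIHemisphereAnova`, `tukeyPosthoc`, `pairedStreamTest`, `cohensD`, `partialEtaSq` |
| Pipeline & IO | `runPipeline`, `defaultRunConfig`, `writeTCK`/`readTCK`, `writeApertureNifti`/`readApertureNifti`, `writeSurfaceTSV`, `writeBandProportionsTSV`, `readRunConfig` |

The methods vignette (`vignettes/prfcss-methods.Rmd`) documents the model
conventions, the synthetic generators and what passing tests do and do not
establish, the numerical choices, and known limitations.
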