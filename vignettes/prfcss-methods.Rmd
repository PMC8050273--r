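---
title: "Population receptive field analysis with compressive spatial summation: models, conventions and design choices"
author: "prfcss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field analysis with compressive spatial summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfcss)
```

## The model

A population receptive field (pRF) summarizes the region of visual space that
drives the aggregate response of the neural population inside one fMRI voxel.
`prfcss` models each voxel with the compressive spatial summation (CSS)
variant: an isotropic 2-D Gaussian with center $(x, y)$ (degrees of visual
angle, x right-positive, y up-positive, fixation at the origin) and standard
deviation $\sigma$, followed by a static compressive output nonlinearity with
exponent $n \in (0, 1]$. For a binarized stimulus frame $S_t$ the neural
response is

$$ r_t = \left( \sum_{\text{pixels}} S_t \, G_{x,y,\sigma} \right)^{\,n}, $$

and the predicted BOLD series is $\beta \, (r * h)(t)$ sampled at the TR,
where $h$ is the hemodynamic response function and $\beta$ a non-negative
gain. The effective pRF size is $\sigma / \sqrt{n}$: compression ($n < 1$)
widens the region over which stimuli produce substantial responses, so size
exceeds $\sigma$ except in the linear case. Eccentricity and polar angle
derive from the center as $\sqrt{x^2 + y^2}$ and $\mathrm{atan2}(y, x)$.

Two ordering conventions in this model are easy to get wrong and are fixed
here deliberately:

* **Compression precedes convolution.** The exponent applies to the spatial
  sum frame by frame, before temporal convolution with the HRF. Applying it
  after convolution defines a different (and non-equivalent) model.
* **Unit-volume Gaussians without post-truncation renormalization.** The
  Gaussian is scaled analytically by $\mathrm{pixel~area} / (2\pi\sigma^2)$
  so its untruncated continuous integral is 1. A full-field stimulus then
  yields $r_t = 1$ for any $n$, and predictions are independent of grid
  resolution. Renormalizing after truncation by the display would instead
  inflate responses of peripheral pRFs in a resolution-dependent way; pRFs
  far outside the aperture are flagged (`outOfAperture`) rather than
  rescaled.

The HRF is a double-gamma impulse response (peak near 5 s, undershoot near
15 s, truncated at 32 s, unit peak). The data this pipeline emulates do not
pin down a subject-specific HRF, so a canonical shape is used and recorded;
any `HRFModel` can be substituted.

## The stimulus

`buildBarDesign()` encodes a wide-field bar-mapping design: a 40° × 40°
field, bars of width 5.7° in four orientations (0°, 45°, 90°, 135°), each
swept in the two directions orthogonal to the bar, 12 steps of 2 s per 24 s
sweep. Blank periods *replace* the final six steps (12 s) of each diagonal
sweep, and a 12 s blank baseline leads the run; with eight sweeps this
totals $12 + 8 \times 24 = 204$ s, i.e. 3 min 24 s. Where exactly the extra
12 s of blank sits (leading baseline, trailing, or split) is not determined
by the arithmetic alone; the leading-baseline convention adopted here is a
documented package convention, exposed through `blank_rule`-style
configuration rather than asserted as the only reading.

The aperture is rendered as a binary movie on an odd-sized square grid (one
pixel centered at fixation). The bar always lies fully inside the field, so
every non-blank cardinal frame switches on a fraction of pixels close to
`barWidth / fieldExtent`; diagonal sweeps traverse the projected extent of
the square. Generation is deterministic, opposite sweep directions are
time-reversals of one another, and the per-pixel sum of all frames is
invariant under 90° rotation of the design — all three properties are under
test. Carrier imagery (the cartoon content and its 8 Hz update rate) is
deliberately not rendered: the forward model consumes only the binarized
aperture, so the carrier is metadata.

## Fitting

`fitPRFSet()` estimates $(x, y, \sigma, n)$ per voxel in two stages:

1. **Grid search.** Candidate centers on a polar grid of eccentricities from
   0 to 1.25 × the field extent (centers beyond the stimulated field occur
   in real populations and must be representable), log-spaced $\sigma$ from
   0.21° to 40°, and $n \in \{0.25, 0.5, 1\}$. At each candidate the gain is
   solved in closed form by least squares (clipped at zero), so the search
   only scores shape parameters.
2. **Bounded refinement.** The best candidate seeds an L-BFGS-B refinement
   of all four shape parameters minimizing the sum of squared errors, with
   bounds $x, y \in [-60, 60]°$, $\sigma \in [0.21, 60]°$,
   $n \in [0.01, 1]$. A refinement step that fails to improve on the grid
   seed is discarded, so refinement can never worsen the fit.

Variance explained is $1 - SS_{res}/SS_{tot}$ about the observed mean,
clipped to $[0, 1]$ for reporting (the unclipped value is available).
Zero-variance series are returned unconverged with VE 0 rather than fitted.

Inclusion criteria mirror standard practice for these analyses: voxels are
kept when VE strictly exceeds 0.20 (the threshold is strict because the
defining wording is "greater than"; 0.10 is available for robustness
re-analyses and by construction can only add voxels), when $\sigma$ did not
stick at the optimizer floor of 0.21° (detected as exact equality with the
bound — L-BFGS-B returns the bound itself when pinned), and when at least
10 voxels survive per ROI, otherwise the ROI is dropped.

## The synthetic-data module

Synthetic generators define the ground-truth conditions for every recovery
test; all are pure functions of (configuration, seed).

* **Populations.** `ventralProfile()` draws center eccentricities from an
  exponential with scale 3°, truncated at 40°: just over 80% of centers fall
  below 5°, the strong foveal concentration characteristic of ventral
  face-selective populations. `lateralProfile()` draws uniformly by
  visual-field area out to 35°, placing about 2% below 5° — peripherally
  extended, as in lateral populations. Polar angles concentrate in the
  contralateral hemifield via a wrapped-normal ("von-Mises-like") law; sizes
  follow a linear size–eccentricity model with Gaussian jitter
  (ventral: $2 + 0.4\,ecc$; lateral: $8 + 0.6\,ecc$, echoing the much larger
  sizes of lateral populations); exponents are uniform on $[0.2, 1]$.
* **BOLD.** White Gaussian noise by default (an AR(1) option exists; no
  noise model is dictated by the emulated data). `noiseSd = "targetVE"`
  chooses, per voxel, $\mathrm{sd}(signal)\sqrt{(1 - v)/v}$ so the expected
  variance explained is $v$; the recovery studies use $v = 0.6$, a mid-range
  value for retinotopically driven voxels in high-level regions.
* **Surface.** A flat 1 mm-spaced sheet carrying a log-spaced eccentricity
  gradient from 2.5° to 40° ($ecc = 2.5 \cdot 2^{4u}$ along the sheet), so
  the four bands 0–5/5–10/10–20/20–40° occupy equal sheet area — emulating
  the roughly equal cortical expanse those bands cover under cortical
  magnification. It is not a folded cortical mesh: distances are Euclidean
  on the sheet, which affects disk ROIs only through this stand-in geometry.
* **Streamlines and endpoints.** Random 1 mm-step polylines with bounded
  per-step turning exercise length filtering and ensemble concatenation;
  they model no diffusion physics. Endpoint generators place endpoints on
  surface vertices with band membership drawn from specified weights and
  gamma-distributed track-density (TDI) weights of unit mean and chosen
  coefficient of variation.

Because the generators draw from idealized laws, passing recovery tests
demonstrates correctness of the estimation machinery under the stated noise
model — not robustness to the many untreated features of real data
(physiological noise structure, HRF variability, partial-volume effects,
folded cortical geometry, tracking biases).

## Coverage analytics

Visual field coverage treats each surviving pRF as a binary disk of radius
$\sigma/\sqrt{n}$ centered at $(x, y)$; the map value at a grid point is the
proportion of pRFs covering it. Group maps average per-subject maps
point-wise. The density-by-eccentricity curve averages the map over 1°-wide
annuli (width configurable; 1° is a convention, not a prescribed value)
restricted to the contralateral hemifield. Two summary fits are provided:

* ordinary least squares $y = ax + b$, with adjusted $R^2$ using the
  two-parameter correction; and
* the generalized logistic
  $y = a + (b - a) / (1 + 10^{(c - x)d})$, fitted by Levenberg–Marquardt
  with multistart initialization over steepness signs and magnitudes. The
  roles of $a$ and $b$ as low- and high-eccentricity asymptotes swap with
  the sign of $d$, so results also report `asymptoteLow`/`asymptoteHigh`
  explicitly. Constant curves are flagged degenerate ($c$, $d$
  unidentifiable) instead of fitted.

Laterality is $(contra - ipsi)/(contra + ipsi)$ of mean coverage; vertical
bias is $(upper - lower)/(upper + lower)$ within the contralateral
hemifield. Both return exact ±1/0 identities on one-sided and symmetric
maps, and are flagged undefined on empty maps.

Eccentricity bands are half-open $[lo, hi)$ with the final band closed at
40° — a tie-break convention this package fixes explicitly (a center at
exactly 5° counts toward 5–10°). Centers beyond 40° are excluded from band
denominators and reported as a count, since real populations do contain
such centers and silently folding them into the last band would bias the
proportions.

## Connectivity quantification

Tractography itself (spherical deconvolution, probabilistic tracking,
anatomically constrained seeding, linear fascicle evaluation) is a contract
boundary: the module consumes streamline sets from files or the synthetic
generator, and the validation step is a pass-through stub with a pluggable
retention predicate. The package's own computations are downstream:

* length filtering with inclusive bounds (4–200 mm defaults; inclusivity is
  a package convention),
* multiset ensemble concatenation preserving per-candidate provenance
  (five candidates of 500,000 streamlines concatenate to 2,500,000 —
  always, by construction),
* ROI intersection by endpoint capture within 2 mm (half the typical
  gray-white-interface voxel scale; configurable, as no capture distance is
  dictated),
* nearest-vertex eccentricity assignment with a capture distance, dropped
  endpoints counted, and
* TDI-weighted band proportions: per-band sums of endpoint weights over the
  total. Weighting by per-endpoint track-density values is mathematically
  equivalent at the surface-vertex level to re-rasterized track-density
  volumes; an unweighted (count) mode is provided for comparison since the
  emulated methodology can be read either way.

## Group statistics

Band-proportion tables are analyzed with linear mixed models
(`value ~ band * stream + (1 | subject)`, REML) and Type III F tests with
Satterthwaite degrees of freedom; partial $\eta^2$ is reported as
$F \cdot df_1 / (F \cdot df_1 + df_2)$. Proportions enter on the raw scale
(no logit transform), matching the emulated analysis. A three-way
`band * roi * hemisphere` variant supports lateralization questions. Tukey
HSD post-hocs run through `emmeans` at family-wise confidence 0.95, with
Satterthwaite degrees of freedom by default to match the omnibus tests (the
asymptotic variant is available for comparison, since published analyses do
not always say which was used). Paired stream comparisons use the paired
$t$ with Cohen's $d = \bar{d}/s_d$; zero-variance differences are flagged
degenerate rather than tested.

**A calibration caveat that shapes the test design.** Band proportions are
compositional: the four values per (subject, stream) cell sum to 1, so
residuals are negatively correlated across bands, and their binomial
variance differs by band. Simulation shows the raw-scale interaction test is
mildly anti-conservative under a purely multinomial null (~0.14 at nominal
0.05) and, conversely, strongly conservative once realistic subject-level
heterogeneity shared across streams dominates (rejection near 0, because
subject × band effects inflate the residual without touching the
interaction contrast). No compositional generator makes the p-values
uniform. The package therefore calibrates the machinery on its own terms:
`simulateNullTable()` draws from the model the LMM assumes (Gaussian
residuals, subject intercepts, equal stream means), where the interaction
test is exact, and the type-I rate sits at the nominal level. The
population-based generator `simulateBandTable()` — which includes lognormal
per-subject profile jitter (SD 0.5 on the log scale, shared across streams,
motivated by the large between-subject scatter such group data show) — is
used for power: the built-in ventral/lateral contrast is detected
essentially always at $\alpha = 0.01$ with 20 subjects. Users analyzing
real compositional proportions should know the raw-scale test inherits this
approximation.

## Numerical choices

* Refinement tolerance: `factr = 1e4` (SSE-scale ~1e-6 relative), iteration
  cap 150, parameter scaling 0.2 on the exponent.
* Bar-pixel inclusion uses a 1e-9 tolerance on the band inequality so
  boundary pixels resolve identically across orientations (without it,
  floating-point noise at exactly half a bar width breaks the 90° rotation
  symmetry).
* Band assignment uses `findInterval` with the rightmost edge closed.
* Logistic fits report `converged = FALSE` with diagnostics instead of
  erroring when all starts fail.
* The sigma floor flag tests exact equality with the optimizer bound, which
  L-BFGS-B guarantees for pinned parameters.
* Streamlines are stored as one coordinate matrix plus per-streamline
  counts (the layout of streamline file formats), keeping 2.5-million-track
  ensembles cheap to concatenate and filter.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run entirely on synthetic data
at sizes chosen to exercise every code path at full fidelity where it
matters: parameter recovery uses 100 voxels on the full 101 × 101 aperture
grid (noise at target VE 0.6) plus a noise-free triplet; unit tests use a
51 × 51 grid with 20–40 voxels; the ensemble check runs the full
5 × 500,000 streamline budget with short (10 ± 2 mm) synthetic streamlines;
LMM power and calibration use 100 and 200 seeded replicates of 20-subject
tables. All randomness flows from explicit seeds.

## Known limitations

* The eccentricity surface is flat; geodesic and Euclidean distances
  coincide, unlike on folded cortex.
* The HRF is fixed and canonical; HRF mis-specification is not simulated.
* The CSS fit assumes isotropic Gaussians; elongated or
  difference-of-Gaussian pRFs are out of scope.
* Raw-scale proportion ANOVAs carry the compositional approximation
  discussed above.
* Hemispheric asymmetries (e.g. stronger right-hemisphere foveal bias) are
  not generated by default; profiles are hemisphere-symmetric with
  asymmetry available through configuration.
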