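#' Construct a pRF parameter set
#'
#' @param x,y pRF center coordinates, degrees.
#' @param sigma Gaussian SD, degrees (> 0).
#' @param n compressive exponent, in (0, 1].
#' @param gain response gain (>= 0).
#' @return a [PRFParams-class]; arguments are recycled to a common length.
#' @examples
#' prfParams(x = 4, y = -2, sigma = 3, n = 0.5)
#' @export
prfParams <- function(x, y, sigma, n = 1, gain = 1) {
  len <- max(lengths(list(x, y, sigma, n, gain)))
  p <- new("PRFParams",
    x = rep_len(as.numeric(x), len), y = rep_len(as.numeric(y), len),
    sigma = rep_len(as.numeric(sigma), len),
    n = rep_len(as.numeric(n), len),
    gain = rep_len(as.numeric(gain), len))
  validObject(p)
  p
}

#' Number of voxels in a parameter set
#' @param params a [PRFParams-class].
#' @return integer count.
#' @export
nVoxels <- function(params) length(params@x)

#' Derived pRF metrics
#'
#' Eccentricity `sqrt(x^2 + y^2)`, polar phase `atan2(y, x)` and pRF size
#' `sigma / sqrt(n)`; the size is the SD of the equivalent linear Gaussian
#' and exceeds sigma whenever n < 1.
#'
#' @param params a [PRFParams-class].
#' @return data.frame with columns `ecc` (degrees), `phase` (radians,
#'   (-pi, pi]) and `size` (degrees), one row per voxel.
#' @examples
#' derivedMetrics(prfParams(3, 4, sigma = 2, n = 0.25))  # ecc 5, size 4
#' @export
derivedMetrics <- function(params) {
  stopifnot(is(params, "PRFParams"))
  data.frame(
    ecc = sqrt(params@x^2 + params@y^2),
    phase = atan2(params@y, params@x),
    size = params@sigma / sqrt(params@n)
  )
}

#' Evaluate a unit-volume Gaussian pRF on an aperture grid
#'
#' Isotropic Gaussian centered at the pRF position, scaled by
#' `pixelArea / (2 pi sigma^2)` so the untruncated continuous integral is 1.
#' No renormalization is applied after truncation by the grid, keeping
#' response amplitude independent of grid resolution; pRFs far outside the
#' aperture simply contribute near-zero mass (flagged by the returned
#' attribute `outOfAperture` when the in-grid mass falls below 0.01).
#'
#' @param params a single-voxel [PRFParams-class] (or index `which` into a
#'   larger set).
#' @param gridX,gridY pixel-center coordinates in degrees (as from
#'   [apertureGrid()]).
#' @param which voxel index when `params` holds several voxels.
#' @return `H x W` weight matrix (rows = gridY).
#' @export
gaussianField <- function(params, gridX, gridY, which = 1L) {
  stopifnot(is(params, "PRFParams"))
  x0 <- params@x[which]; y0 <- params@y[which]; sg <- params@sigma[which]
  if (!is.finite(sg) || sg <= 0) stop("sigma must be positive")
  dx <- mean(diff(gridX)); dy <- mean(diff(gridY))
  gx <- (gridX - x0)^2
  gy <- (gridY - y0)^2
  g <- exp(-(outer(gy, gx, "+")) / (2 * sg^2)) * (dx * dy / (2 * pi * sg^2))
  attr(g, "outOfAperture") <- sum(g) < 0.01
  g
}

#' Per-frame neural response under compressive spatial summation
#'
#' For every aperture frame S_t the response is the stimulus-Gaussian overlap
#' raised to the compressive exponent: `r_t = (sum(S_t * G))^n`. Blank frames
#' give 0; a full-field frame gives 1 for any n (unit-volume Gaussian); n = 1
#' reduces to linear summation.
#'
#' @param params a single-voxel [PRFParams-class] (or `which` selects one).
#' @param aperture an [ApertureSequence-class].
#' @param which voxel index.
#' @return numeric vector, one response per frame (gain not applied).
#' @export
predictNeural <- function(params, aperture, which = 1L) {
  stopifnot(is(params, "PRFParams"), is(aperture, "ApertureSequence"))
  g <- gaussianField(params, aperture@gridX, aperture@gridY, which = which)
  S <- matrix(aperture@frames, nrow = dim(aperture@frames)[1])
  overlap <- as.vector(S %*% as.vector(g))
  overlap[overlap < 0] <- 0
  overlap^params@n[which]
}

#' Canonical double-gamma HRF
#'
#' Difference of two gamma densities (peak near 5 s, undershoot near 15 s),
#' truncated at 32 s and normalized to unit peak. The shape is a standard
#' canonical choice recorded in output metadata and overridable by supplying
#' any [HRFModel-class] downstream.
#'
#' @param dt sample spacing in seconds, in (0, 1] or any positive value that
#'   divides the frame duration and TR in use.
#' @param peak1,peak2 peak times of response and undershoot, seconds.
#' @param ratio undershoot amplitude ratio.
#' @return an [HRFModel-class].
#' @examples
#' h <- canonicalHRF(dt = 1)
#' @export
canonicalHRF <- function(dt = 1, peak1 = 5, peak2 = 15, ratio = 6) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, 32, by = dt)
  a1 <- peak1 + 1; a2 <- peak2 + 1    # gamma shape with rate 1 peaks at a - 1
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    stats::dgamma(t, shape = a2, rate = 1) / ratio
  h <- h / max(h)
  new("HRFModel", samples = h, dt = dt)
}

# discrete convolution of a dt-sampled series with an HRF kernel, truncated
# to the input length (causal)
convolveHRF <- function(x, kernel) {
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_along(x)]
}

#' Predicted BOLD time series for a CSS pRF
#'
#' The per-frame neural response is upsampled to the HRF sampling grid,
#' convolved with the HRF, sampled at volume onsets (multiples of `tr`) and
#' scaled by the gain. A zero stimulus yields an all-zero (mean-removed)
#' series; doubling the gain exactly doubles the output.
#'
#' @param params single-voxel [PRFParams-class] (or `which`).
#' @param aperture an [ApertureSequence-class].
#' @param hrf an [HRFModel-class]; `hrf@dt` must divide both the frame
#'   duration and `tr` (within 1e-9).
#' @param tr repetition time, seconds.
#' @param which voxel index.
#' @return numeric vector of length `nFrames * frameDuration / tr`.
#' @export
predictBold <- function(params, aperture, hrf, tr, which = 1L) {
  r <- predictNeural(params, aperture, which = which)
  pred <- boldFromNeural(r, aperture@frameDuration, hrf, tr)
  params@gain[which] * pred
}

# shared sampling-rate machinery: neural per-frame response -> BOLD at tr
boldFromNeural <- function(r, frameDuration, hrf, tr) {
  stopifnot(is(hrf, "HRFModel"))
  dt <- hrf@dt
  upf <- frameDuration / dt
  upt <- tr / dt
  if (abs(upf - round(upf)) > 1e-9 || abs(upt - round(upt)) > 1e-9)
    stop("hrf dt must divide both the frame duration and tr")
  upf <- round(upf); upt <- round(upt)
  dense <- rep(r, each = upf)
  conv <- convolveHRF(dense, hrf@samples)
  conv[seq(1L, length(conv), by = upt)]
}
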