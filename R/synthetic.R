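#' Describe a synthetic voxel population
#'
#' A generative profile for ground-truth pRF populations. Center eccentricity
#' follows either a truncated exponential (foveally concentrated,
#' "ventral-like") or a uniform-by-area law (peripherally extended,
#' "lateral-like"); polar angle is concentrated in the contralateral
#' hemifield with a wrapped-normal (von-Mises-like) spread; pRF size grows
#' linearly with eccentricity plus Gaussian jitter, and the compressive
#' exponent is uniform over a range.
#'
#' @param label population name.
#' @param eccDistribution `"texp"` (truncated exponential) or
#'   `"uniform_area"`.
#' @param eccScale exponential scale, degrees (texp only).
#' @param maxEcc truncation / maximum eccentricity, degrees.
#' @param hemisphere cortical hemisphere; centers concentrate in the opposite
#'   (contralateral) visual hemifield.
#' @param polarKappa angular concentration (wrapped-normal SD is
#'   `1/sqrt(polarKappa)`); 0 gives uniform angles.
#' @param sizeIntercept,sizeSlope linear size model `size = s0 + m * ecc`,
#'   degrees and degrees/degree.
#' @param sizeJitterSd SD of Gaussian size jitter, degrees.
#' @param nRange range of the compressive exponent.
#' @param nVoxels population size.
#' @return named list profile consumed by [samplePopulation()].
#' @seealso [ventralProfile()], [lateralProfile()]
#' @export
populationProfile <- function(label, eccDistribution = c("texp", "uniform_area"),
                              eccScale = 3, maxEcc = 40, hemisphere = "right",
                              polarKappa = 2, sizeIntercept = 2,
                              sizeSlope = 0.4, sizeJitterSd = 1,
                              nRange = c(0.2, 1), nVoxels = 200L) {
  eccDistribution <- match.arg(eccDistribution)
  stopifnot(eccScale > 0, maxEcc > 0, hemisphere %in% c("left", "right"),
            polarKappa >= 0, sizeJitterSd >= 0, nVoxels >= 1,
            length(nRange) == 2L, nRange[1] > 0, nRange[2] <= 1)
  list(label = label, eccDistribution = eccDistribution, eccScale = eccScale,
       maxEcc = maxEcc, hemisphere = hemisphere, polarKappa = polarKappa,
       sizeIntercept = sizeIntercept, sizeSlope = sizeSlope,
       sizeJitterSd = sizeJitterSd, nRange = nRange,
       nVoxels = as.integer(nVoxels))
}

#' Default ventral-like population profile
#'
#' Foveally concentrated centers (truncated exponential, scale 3 degrees,
#' truncated at 40): just over 80 percent of centers fall below 5 degrees,
#' echoing the strong foveal bias of ventral face-selective populations.
#' Sizes grow modestly with eccentricity.
#'
#' @param nVoxels population size.
#' @param hemisphere cortical hemisphere.
#' @return a population profile list.
#' @export
ventralProfile <- function(nVoxels = 200L, hemisphere = "right") {
  populationProfile("ventral-like", "texp", eccScale = 3, maxEcc = 40,
                    hemisphere = hemisphere, sizeIntercept = 2,
                    sizeSlope = 0.4, nVoxels = nVoxels)
}

#' Default lateral-like population profile
#'
#' Peripherally extended centers, uniform by visual-field area out to
#' 35 degrees (fraction below 5 degrees is (5/35)^2, about 2 percent), with
#' larger sizes, echoing lateral face-selective populations.
#'
#' @inheritParams ventralProfile
#' @return a population profile list.
#' @export
lateralProfile <- function(nVoxels = 200L, hemisphere = "right") {
  populationProfile("lateral-like", "uniform_area", maxEcc = 35,
                    hemisphere = hemisphere, sizeIntercept = 8,
                    sizeSlope = 0.6, sizeJitterSd = 2, nVoxels = nVoxels)
}

#' Analytic fraction of centers below an eccentricity for a profile
#'
#' Closed-form CDF of the profile's eccentricity law, used as the ground
#' truth in recovery checks.
#'
#' @param profile a population profile.
#' @param ecc eccentricity threshold, degrees.
#' @return expected fraction of centers with eccentricity below `ecc`.
#' @export
profileEccCDF <- function(profile, ecc) {
  if (profile$eccDistribution == "texp") {
    (1 - exp(-pmin(ecc, profile$maxEcc) / profile$eccScale)) /
      (1 - exp(-profile$maxEcc / profile$eccScale))
  } else {
    pmin(ecc / profile$maxEcc, 1)^2
  }
}

#' Sample a ground-truth pRF population
#'
#' Draws `nVoxels` parameter sets from a population profile. Sampling is a
#' pure function of (profile, seed); sampled sigma is floored at 0.3 degrees.
#'
#' @param profile a profile from [populationProfile()] and friends.
#' @param seed integer seed.
#' @return a [PRFParams-class] of ground-truth parameters (gain 1).
#' @examples
#' truth <- samplePopulation(ventralProfile(50), seed = 1)
#' @export
samplePopulation <- function(profile, seed = 1L) {
  nv <- profile$nVoxels
  withr::with_seed(seed, {
    ecc <- if (profile$eccDistribution == "texp") {
      u <- stats::runif(nv)
      # inverse-CDF of the exponential truncated at maxEcc
      -profile$eccScale *
        log(1 - u * (1 - exp(-profile$maxEcc / profile$eccScale)))
    } else {
      profile$maxEcc * sqrt(stats::runif(nv))
    }
    mu <- if (profile$hemisphere == "right") pi else 0  # contralateral field
    theta <- if (profile$polarKappa > 0)
      mu + stats::rnorm(nv, 0, 1 / sqrt(profile$polarKappa))
    else stats::runif(nv, -pi, pi)
    size <- profile$sizeIntercept + profile$sizeSlope * ecc +
      stats::rnorm(nv, 0, profile$sizeJitterSd)
    n <- stats::runif(nv, profile$nRange[1], profile$nRange[2])
    sigma <- pmax(size * sqrt(n), 0.3)
    prfParams(x = ecc * cos(theta), y = ecc * sin(theta),
              sigma = sigma, n = n, gain = 1)
  })
}

#' Simulate noisy BOLD responses for a ground-truth population
#'
#' Forward-models every voxel with [predictBold()] and adds i.i.d. Gaussian
#' noise (optionally AR(1)-correlated). `noiseSd = 0` reproduces the forward
#' model exactly. `noiseSd = "targetVE"` picks, per voxel, the noise SD that
#' sets the expected variance explained to `targetVE`
#' (`sd(signal) * sqrt((1 - v) / v)`).
#'
#' @param truth a [PRFParams-class] of ground-truth parameters.
#' @param aperture an [ApertureSequence-class].
#' @param hrf an [HRFModel-class].
#' @param tr repetition time, seconds.
#' @param noiseSd noise standard deviation in signal units, or the string
#'   `"targetVE"`.
#' @param targetVE expected variance explained when `noiseSd = "targetVE"`.
#' @param ar1 AR(1) coefficient of the noise (0 = white).
#' @param seed integer seed.
#' @return numeric matrix, voxels x volumes, with attribute `tr`.
#' @export
generateBold <- function(truth, aperture, hrf, tr, noiseSd = 0,
                         targetVE = 0.6, ar1 = 0, seed = 1L) {
  stopifnot(is(truth, "PRFParams"))
  nv <- nVoxels(truth)
  signal <- t(vapply(seq_len(nv), function(v)
    predictBold(truth, aperture, hrf, tr, which = v),
    numeric(round(dim(aperture@frames)[1] * aperture@frameDuration / tr))))
  if (identical(noiseSd, "targetVE")) {
    stopifnot(targetVE > 0, targetVE < 1)
    noiseSd <- apply(signal, 1, stats::sd) * sqrt((1 - targetVE) / targetVE)
  } else {
    stopifnot(is.numeric(noiseSd), all(noiseSd >= 0))
    noiseSd <- rep_len(noiseSd, nv)
  }
  Y <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(signal)), nrow = nv)
    if (ar1 != 0)
      noise <- t(apply(noise, 1, function(e)
        as.vector(stats::filter(e, ar1, method = "recursive")))) *
        sqrt(1 - ar1^2)
    signal + noise * noiseSd
  })
  attr(Y, "tr") <- tr
  Y
}

#' Synthetic early-visual-cortex eccentricity surface
#'
#' A flat rectangular sheet of vertices (1 mm spacing, z = 0) carrying a
#' smooth log-spaced eccentricity gradient from 2.5 to 40 degrees along its
#' long axis, emulating cortical magnification: each of the four default
#' eccentricity bands occupies an equal share of the sheet, echoing the
#' roughly equal cortical expanse of those bands. A small smooth transverse
#' ripple (< 1 degree) keeps the map non-degenerate without violating the
#' 2-degree neighbor-smoothness invariant.
#'
#' @param nVertices total vertex count (>= 100); the sheet is near-square.
#' @param seed integer seed (ripple phase).
#' @return an [EccSurface-class].
#' @export
synthEVCSurface <- function(nVertices = 10000L, seed = 1L) {
  stopifnot(nVertices >= 100L)
  nx <- floor(sqrt(nVertices))
  ny <- ceiling(nVertices / nx)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))[seq_len(nVertices), ]
  u <- (grid$ix - 1) / max(nx - 1, 1)          # 0..1 along the ecc gradient
  phase <- withr::with_seed(seed, stats::runif(1, 0, 2 * pi))
  ripple <- 0.02 * sin(2 * pi * (grid$iy - 1) / max(ny - 1, 1) + phase)
  ecc <- pmin(pmax(2.5 * 2^(4 * pmin(pmax(u + ripple, 0), 1)), 0), 40)
  new("EccSurface",
      vertices = cbind(grid$ix - 1, grid$iy - 1, 0),
      eccentricity = as.numeric(ecc), spacing = 1)
}

#' Synthetic tract-endpoint sets with controlled band weights
#'
#' Places endpoints on surface vertices with eccentricity-band membership
#' drawn from `bandWeights`, and draws positive track-density (TDI) weights
#' with a given dispersion (gamma with unit mean and CV = dispersion;
#' dispersion 0 gives equal weights).
#'
#' @param bandWeights fractions per band, summing to 1 (tolerance 1e-9).
#' @param nEndpoints number of endpoints.
#' @param surface an [EccSurface-class].
#' @param bands an [EccBands-class] defining band membership.
#' @param weightDispersion coefficient of variation of the TDI weights.
#' @param seed integer seed.
#' @return data.frame of endpoint records: `x`, `y`, `z` (mm),
#'   `eccentricity` (degrees), `tdiWeight`.
#' @export
synthEndpoints <- function(bandWeights, nEndpoints, surface,
                           bands = eccBands(), weightDispersion = 0,
                           seed = 1L) {
  stopifnot(is(surface, "EccSurface"), nEndpoints >= 1)
  if (abs(sum(bandWeights) - 1) > 1e-9)
    stop("bandWeights must sum to 1")
  nBands <- length(bands@edges) - 1L
  if (length(bandWeights) != nBands)
    stop("need one weight per band")
  vertBand <- bandAssign(surface@eccentricity, bands)
  withr::with_seed(seed, {
    band <- sample.int(nBands, nEndpoints, replace = TRUE, prob = bandWeights)
    idx <- integer(nEndpoints)
    for (b in seq_len(nBands)) {
      sel <- band == b
      if (!any(sel)) next
      cand <- which(vertBand == b)
      if (!length(cand)) stop("surface has no vertices in band ", b)
      idx[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE)]
    }
    w <- if (weightDispersion == 0) rep(1, nEndpoints)
    else stats::rgamma(nEndpoints, shape = 1 / weightDispersion^2,
                       rate = 1 / weightDispersion^2)
    data.frame(x = surface@vertices[idx, 1], y = surface@vertices[idx, 2],
               z = surface@vertices[idx, 3],
               eccentricity = surface@eccentricity[idx], tdiWeight = w)
  })
}

#' Synthetic streamline sets
#'
#' Random 1 mm-step polylines whose per-step turning angle is bounded by
#' `maxStepAngle` and whose arc lengths follow a truncated normal law; used
#' to exercise streamline filtering and ensemble concatenation (not a model
#' of diffusion physics).
#'
#' @param n number of streamlines.
#' @param lengthMean,lengthSd arc-length distribution, mm (truncated so every
#'   streamline has at least one 1 mm step).
#' @param maxStepAngle maximum per-step turning angle, degrees.
#' @param seed integer seed.
#' @param origin,spread seeding box: start points uniform in
#'   `origin +/- spread` per axis, mm.
#' @return a [Connectome-class] with `stepSize = 1` metadata.
#' @export
synthStreamlines <- function(n, lengthMean = 40, lengthSd = 15,
                             maxStepAngle = 45, seed = 1L,
                             origin = c(0, 0, 0), spread = 50) {
  n <- as.integer(n)
  if (n == 0L)
    return(new("Connectome", points = matrix(numeric(), 0, 3),
               counts = integer(),
               metadata = list(stepSize = 1, maxStepAngle = maxStepAngle)))
  withr::with_seed(seed, {
    len <- pmax(stats::rnorm(n, lengthMean, lengthSd), 1)
    nSeg <- pmax(round(len), 1L)
    counts <- as.integer(nSeg + 1L)
    total <- sum(counts)
    pts <- matrix(0, total, 3)
    off <- streamlineOffsets(counts)
    # start points and initial unit directions
    start <- matrix(stats::runif(3 * n, -spread, spread), n, 3) +
      rep(origin, each = n)
    dir <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pts[off, ] <- start
    cur <- start
    maxRad <- maxStepAngle * pi / 180
    for (s in seq_len(max(nSeg))) {
      act <- which(nSeg >= s)
      if (s > 1L) {
        # rotate each active direction by a random angle <= maxStepAngle
        # around a random axis perpendicular to it
        a <- stats::runif(length(act), 0, maxRad)
        r <- matrix(stats::rnorm(3 * length(act)), ncol = 3)
        d <- dir[act, , drop = FALSE]
        perp <- r - d * rowSums(r * d)
        perp <- perp / sqrt(rowSums(perp^2))
        dir[act, ] <- d * cos(a) + perp * sin(a)
      }
      cur[act, ] <- cur[act, , drop = FALSE] + dir[act, , drop = FALSE]
      pts[off[act] + s, ] <- cur[act, , drop = FALSE]
    }
    new("Connectome", points = pts, counts = counts,
        metadata = list(stepSize = 1, maxStepAngle = maxStepAngle))
  })
}
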