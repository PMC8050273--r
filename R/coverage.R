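#' Eccentricity band definitions
#'
#' The default four-band scheme 0-5, 5-10, 10-20, 20-40 degrees. Bands are
#' half-open `[lo, hi)` except the last, which is closed at 40.
#'
#' @param edges strictly increasing band edges, degrees.
#' @return an [EccBands-class].
#' @export
eccBands <- function(edges = c(0, 5, 10, 20, 40)) {
  b <- new("EccBands", edges = as.numeric(edges))
  validObject(b)
  b
}

#' Assign eccentricities to bands
#'
#' Half-open convention: band k covers `[edges[k], edges[k+1])`; the final
#' band is closed at the last edge. Values outside all bands get `NA`.
#'
#' @param ecc eccentricities, degrees.
#' @param bands an [EccBands-class].
#' @return integer band index per value (`NA` if out of range).
#' @examples
#' bandAssign(c(2, 5, 40, 41), eccBands())  # 1, 2, 4, NA
#' @export
bandAssign <- function(ecc, bands = eccBands()) {
  e <- bands@edges
  idx <- findInterval(ecc, e, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(e) - 1L] <- NA_integer_
  idx[ecc < e[1] | ecc > e[length(e)]] <- NA_integer_
  as.integer(idx)
}

#' Visual field coverage of an ROI's pRFs
#'
#' Each surviving pRF contributes the indicator of a disk centered at its
#' (x, y) with diameter `2 sigma / sqrt(n)` (radius = pRF size); the coverage
#' density at a grid point is the mean indicator over pRFs, i.e. the
#' proportion of pRFs covering that point.
#'
#' @param voxelset an [ROIVoxelSet-class] (or a [PRFFitSet-class] plus
#'   `hemisphere`).
#' @param gridResolution pixels per side of the square coverage grid.
#' @param fieldExtent grid side length, degrees.
#' @param hemisphere used when `voxelset` is a bare fit set.
#' @return a [CoverageMap-class].
#' @export
computeVFC <- function(voxelset, gridResolution = 101L, fieldExtent = 40,
                       hemisphere = NULL) {
  if (is(voxelset, "ROIVoxelSet")) {
    f <- voxelset@fits@fits
    hemisphere <- voxelset@hemisphere
  } else if (is(voxelset, "PRFFitSet")) {
    f <- voxelset@fits
    if (is.null(hemisphere)) stop("hemisphere required for a bare fit set")
  } else stop("voxelset must be an ROIVoxelSet or PRFFitSet")
  if (!nrow(f)) stop("empty voxel set")
  half <- fieldExtent / 2
  coords <- seq(-half, half, length.out = gridResolution)
  X <- matrix(coords, gridResolution, gridResolution, byrow = TRUE)
  Y <- matrix(coords, gridResolution, gridResolution)
  acc <- matrix(0, gridResolution, gridResolution)
  for (v in seq_len(nrow(f))) {
    r <- f$size[v]
    acc <- acc + ((X - f$x[v])^2 + (Y - f$y[v])^2 <= r^2)
  }
  new("CoverageMap", gridX = coords, gridY = coords,
      density = acc / nrow(f), hemisphere = hemisphere)
}

#' Group-average coverage map
#'
#' Per-subject coverage maps averaged point-wise (all maps must share grid
#' and hemisphere), the group-level aggregation used for ROI coverage
#' figures.
#'
#' @param maps list of [CoverageMap-class] objects.
#' @return a [CoverageMap-class].
#' @export
groupAverageCoverage <- function(maps) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, is, logical(1), "CoverageMap")))
  g1 <- maps[[1]]
  for (m in maps[-1])
    if (!identical(m@gridX, g1@gridX) || !identical(m@hemisphere, g1@hemisphere))
      stop("maps must share grid and hemisphere")
  dens <- Reduce(`+`, lapply(maps, coverageDensity)) / length(maps)
  new("CoverageMap", gridX = g1@gridX, gridY = g1@gridY, density = dens,
      hemisphere = g1@hemisphere)
}

# grid-point eccentricities and contralateral mask for a coverage map
.mapGeometry <- function(map) {
  X <- matrix(map@gridX, length(map@gridY), length(map@gridX), byrow = TRUE)
  Y <- matrix(map@gridY, length(map@gridY), length(map@gridX))
  contra <- if (map@hemisphere == "right") X < 0 else X > 0
  list(X = X, Y = Y, ecc = sqrt(X^2 + Y^2), contra = contra)
}

#' Coverage density as a function of eccentricity
#'
#' Mean coverage density over grid points within uniform eccentricity annuli,
#' restricted to the contralateral hemifield of the map's hemisphere.
#'
#' @param map a [CoverageMap-class].
#' @param binWidth annulus width, degrees.
#' @return data.frame with `ecc` (bin centers) and `density`.
#' @export
densityVsEccentricity <- function(map, binWidth = 1) {
  stopifnot(is(map, "CoverageMap"), binWidth > 0)
  geo <- .mapGeometry(map)
  maxEcc <- max(abs(c(map@gridX, map@gridY)))
  edges <- seq(0, maxEcc + binWidth, by = binWidth)
  idx <- findInterval(geo$ecc[geo$contra], edges)
  dens <- map@density[geo$contra]
  means <- tapply(dens, factor(idx, levels = seq_len(length(edges) - 1L)),
                  mean)
  keep <- !is.na(means)
  data.frame(ecc = (edges[-length(edges)] + binWidth / 2)[keep],
             density = as.numeric(means[keep]))
}

#' Laterality index of a coverage map
#'
#' `(contra - ipsi) / (contra + ipsi)` of mean coverage over the two
#' hemifields; 1 for purely contralateral coverage, 0 for mirror-symmetric
#' maps. Undefined (NA with a `degenerate` attribute) when total coverage is
#' zero.
#'
#' @param map a full-field [CoverageMap-class].
#' @return index in [-1, 1].
#' @export
lateralityIndex <- function(map) {
  stopifnot(is(map, "CoverageMap"))
  geo <- .mapGeometry(map)
  contra <- mean(map@density[geo$contra])
  ipsi <- mean(map@density[!geo$contra & geo$X != 0])
  if (contra + ipsi == 0) {
    out <- NA_real_; attr(out, "degenerate") <- TRUE
    return(out)
  }
  (contra - ipsi) / (contra + ipsi)
}

#' Vertical (upper-field) bias index of a coverage map
#'
#' `(upper - lower) / (upper + lower)` of mean coverage, computed over the
#' contralateral hemifield only.
#'
#' @param map a full-field [CoverageMap-class].
#' @return index in [-1, 1]; NA (degenerate) when contralateral coverage is
#'   zero.
#' @export
verticalBiasIndex <- function(map) {
  stopifnot(is(map, "CoverageMap"))
  geo <- .mapGeometry(map)
  upper <- mean(map@density[geo$contra & geo$Y > 0])
  lower <- mean(map@density[geo$contra & geo$Y < 0])
  if (upper + lower == 0) {
    out <- NA_real_; attr(out, "degenerate") <- TRUE
    return(out)
  }
  (upper - lower) / (upper + lower)
}

#' Band proportions of pRF centers
#'
#' Fraction of pRF-center eccentricities per band. Centers beyond the last
#' band edge are excluded from the denominator and reported in the
#' `nExcluded` field.
#'
#' @param voxelset an [ROIVoxelSet-class] or [PRFFitSet-class].
#' @param bands an [EccBands-class].
#' @return list with `fractions` (one per band, summing to 1), `nItems`
#'   (in-range count) and `nExcluded`.
#' @export
centerBandProportions <- function(voxelset, bands = eccBands()) {
  f <- fitTable(voxelset)
  if (!nrow(f)) stop("empty voxel set")
  idx <- bandAssign(f$ecc, bands)
  nIn <- sum(!is.na(idx))
  if (!nIn) stop("all pRF centers fall outside the band range")
  counts <- tabulate(idx, nbins = length(bands@edges) - 1L)
  list(fractions = counts / nIn, nItems = nIn,
       nExcluded = sum(is.na(idx)))
}

#' Median pRF size per eccentricity band
#'
#' Median of `sigma / sqrt(n)` among voxels whose center falls in each band;
#' empty bands are reported as `NA`.
#'
#' @param voxelset an [ROIVoxelSet-class] or [PRFFitSet-class].
#' @param bands an [EccBands-class].
#' @return numeric vector of per-band medians (degrees).
#' @export
medianSizeByBand <- function(voxelset, bands = eccBands()) {
  f <- fitTable(voxelset)
  idx <- bandAssign(f$ecc, bands)
  vapply(seq_len(length(bands@edges) - 1L), function(b) {
    s <- f$size[!is.na(idx) & idx == b]
    if (length(s)) stats::median(s) else NA_real_
  }, numeric(1))
}
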