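
# ---------------------------------------------------------------------------
# Stimulus containers
# ---------------------------------------------------------------------------

#' Bar-sweep stimulus design
#'
#' Describes a wide-field cartoon-carrier bar-mapping pRF stimulus: a bar
#' of fixed width swept across a square field in several orientations, two
#' opposed directions per orientation, with blank periods replacing the second
#' half of each diagonal sweep and a leading blank baseline. The carrier
#' imagery inside the bar is metadata only; the forward model consumes the
#' binarized aperture.
#'
#' @slot fieldExtent side of the square mapped field, degrees of visual angle.
#' @slot barWidth bar width, degrees.
#' @slot orientations bar orientations, degrees (bar long-axis angle).
#' @slot nDirections number of sweep directions (two per orientation).
#' @slot stepsPerSweep number of discrete bar steps per sweep.
#' @slot stepDuration duration of one bar step, seconds.
#' @slot blankRule blank convention; currently
#'   `"replace_second_half_of_diagonals"` only.
#' @slot baselineDuration leading blank baseline, seconds.
#' @slot carrierRate carrier image update rate, Hz (metadata only).
#'
#' @seealso [buildBarDesign()], [generateAperture()], [scheduleDuration()]
#' @exportClass BarDesign
setClass("BarDesign", representation(
  fieldExtent = "numeric",
  barWidth = "numeric",
  orientations = "numeric",
  nDirections = "numeric",
  stepsPerSweep = "numeric",
  stepDuration = "numeric",
  blankRule = "character",
  baselineDuration = "numeric",
  carrierRate = "numeric"
))

setValidity("BarDesign", function(object) {
  msg <- character()
  if (length(object@fieldExtent) != 1L || !is.finite(object@fieldExtent) ||
      object@fieldExtent <= 0)
    msg <- c(msg, "fieldExtent must be a single positive number")
  if (length(object@barWidth) != 1L || !is.finite(object@barWidth) ||
      object@barWidth <= 0)
    msg <- c(msg, "barWidth must be a single positive number")
  if (length(object@barWidth) == 1L && length(object@fieldExtent) == 1L &&
      is.finite(object@barWidth) && is.finite(object@fieldExtent) &&
      object@barWidth > object@fieldExtent)
    msg <- c(msg, "barWidth must not exceed fieldExtent")
  if (anyDuplicated(object@orientations))
    msg <- c(msg, "orientations must be distinct")
  if (length(object@nDirections) != 1L ||
      object@nDirections != 2L * length(object@orientations))
    msg <- c(msg, "nDirections must equal 2 * number of orientations")
  if (length(object@stepsPerSweep) != 1L || object@stepsPerSweep < 1 ||
      object@stepsPerSweep != round(object@stepsPerSweep))
    msg <- c(msg, "stepsPerSweep must be a positive integer")
  if (length(object@stepDuration) != 1L || object@stepDuration <= 0)
    msg <- c(msg, "stepDuration must be positive")
  if (!object@blankRule %in% "replace_second_half_of_diagonals")
    msg <- c(msg, "unknown blankRule")
  if (length(object@baselineDuration) != 1L || object@baselineDuration < 0)
    msg <- c(msg, "baselineDuration must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Binarized stimulus aperture sequence
#'
#' The stimulus movie seen by the forward model: one binary frame per bar step
#' (plus all-zero frames for the leading baseline and for steps blanked by the
#' design's blank rule) over a square grid of visual-field positions in
#' degrees. The origin is at fixation, x increases rightward, y upward.
#'
#' @slot frames numeric array, `T x H x W`, values 0/1; `frames[t, i, j]` is
#'   the aperture at row i (y coordinate `gridY[i]`) and column j
#'   (`gridX[j]`).
#' @slot gridX,gridY pixel-center coordinates in degrees.
#' @slot frameDuration seconds per frame.
#'
#' @exportClass ApertureSequence
setClass("ApertureSequence", representation(
  frames = "array",
  gridX = "numeric",
  gridY = "numeric",
  frameDuration = "numeric"
))

setValidity("ApertureSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a T x H x W array")
  else {
    if (d[2] != length(object@gridY) || d[3] != length(object@gridX))
      msg <- c(msg, "frame dimensions must match gridY/gridX lengths")
    if (!all(object@frames %in% c(0, 1)))
      msg <- c(msg, "frame values must be 0 or 1")
  }
  if (length(object@frameDuration) != 1L || object@frameDuration <= 0)
    msg <- c(msg, "frameDuration must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Model containers
# ---------------------------------------------------------------------------

#' pRF parameter set (CSS model)
#'
#' Vectorized container of compressive-spatial-summation pRF parameters, one
#' element per voxel: center (x, y) in degrees, Gaussian SD sigma in degrees,
#' compressive exponent n in (0, 1], and response gain. The derived pRF size
#' is `sigma / sqrt(n)`.
#'
#' @slot x,y pRF center coordinates, degrees (x right-positive, y up-positive).
#' @slot sigma Gaussian standard deviation, degrees; strictly positive.
#' @slot n compressive summation exponent, in (0, 1].
#' @slot gain response amplitude (signal units per unit neural response),
#'   non-negative.
#'
#' @seealso [prfParams()], [derivedMetrics()]
#' @exportClass PRFParams
setClass("PRFParams", representation(
  x = "numeric", y = "numeric", sigma = "numeric",
  n = "numeric", gain = "numeric"
))

setValidity("PRFParams", function(object) {
  len <- length(object@x)
  msg <- character()
  if (any(lengths(list(object@y, object@sigma, object@n, object@gain)) != len))
    msg <- c(msg, "all parameter slots must have equal length")
  if (any(!is.finite(object@sigma)) || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be positive")
  if (any(object@n <= 0) || any(object@n > 1))
    msg <- c(msg, "n must lie in (0, 1]")
  if (any(object@gain < 0))
    msg <- c(msg, "gain must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Hemodynamic response function
#'
#' Impulse response sampled at uniform spacing `dt`, normalized to unit peak.
#'
#' @slot samples impulse-response values.
#' @slot dt sample spacing, seconds.
#' @exportClass HRFModel
setClass("HRFModel", representation(samples = "numeric", dt = "numeric"))

setValidity("HRFModel", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be positive")
  if (!length(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite and non-empty")
  else if (sum(object@samples) <= 0)
    msg <- c(msg, "samples must sum to a positive value")
  if (length(msg)) msg else TRUE
})

#' Per-voxel pRF fit results
#'
#' One row per voxel: fitted CSS parameters, variance explained (clipped to
#' [0, 1] for reporting), a convergence flag and a flag marking fits whose
#' sigma stuck at the optimizer's lower bound (excluded downstream).
#'
#' @slot fits data.frame with columns `x`, `y`, `sigma`, `n`, `gain`, `ve`,
#'   `converged`, `atSigmaFloor` and derived `ecc`, `phase`, `size`.
#' @exportClass PRFFitSet
setClass("PRFFitSet", representation(fits = "data.frame"))

.fitCols <- c("x", "y", "sigma", "n", "gain", "ve", "converged",
              "atSigmaFloor", "ecc", "phase", "size")

setValidity("PRFFitSet", function(object) {
  msg <- character()
  miss <- setdiff(.fitCols, names(object@fits))
  if (length(miss))
    msg <- c(msg, paste("missing fit columns:", paste(miss, collapse = ", ")))
  else if (nrow(object@fits) && any(object@fits$ve > 1 + 1e-12))
    msg <- c(msg, "variance explained must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' ROI voxel set surviving inclusion criteria
#'
#' pRF fits for one region of interest after applying the inclusion rules
#' (variance explained above threshold, sigma off the optimizer floor, minimum
#' voxel count).
#'
#' @slot roiLabel region name (e.g. IOG, pFus, mFus, pSTS, mSTS, CoS or a
#'   synthetic label).
#' @slot hemisphere `"left"` or `"right"`.
#' @slot fits surviving fits as a [PRFFitSet-class].
#' @exportClass ROIVoxelSet
setClass("ROIVoxelSet", representation(
  roiLabel = "character", hemisphere = "character", fits = "PRFFitSet"
))

setValidity("ROIVoxelSet", function(object) {
  msg <- character()
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Coverage containers
# ---------------------------------------------------------------------------

#' Visual field coverage map
#'
#' Proportion of an ROI's pRFs (binary disks of diameter `2 sigma / sqrt(n)`)
#' covering each point of a square visual-field grid.
#'
#' @slot gridX,gridY grid coordinates, degrees.
#' @slot density `H x W` matrix of coverage proportions in [0, 1]; rows index
#'   `gridY`, columns `gridX`.
#' @slot hemisphere cortical hemisphere of the contributing ROI.
#' @exportClass CoverageMap
setClass("CoverageMap", representation(
  gridX = "numeric", gridY = "numeric", density = "matrix",
  hemisphere = "character"
))

setValidity("CoverageMap", function(object) {
  msg <- character()
  if (!identical(dim(object@density),
                 c(length(object@gridY), length(object@gridX))))
    msg <- c(msg, "density must be gridY x gridX")
  if (any(object@density < -1e-12) || any(object@density > 1 + 1e-12))
    msg <- c(msg, "density must lie in [0, 1]")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Eccentricity bands
#'
#' Strictly increasing band edges in degrees; bands are half-open `[lo, hi)`
#' except the last, which is closed. The default is the four-band scheme
#' 0-5, 5-10, 10-20, 20-40 degrees.
#'
#' @slot edges band edges, degrees.
#' @seealso [eccBands()], [bandAssign()]
#' @exportClass EccBands
setClass("EccBands", representation(edges = "numeric"))

setValidity("EccBands", function(object) {
  if (length(object@edges) < 2L || any(diff(object@edges) <= 0))
    "edges must be strictly increasing with at least two values" else TRUE
})

# ---------------------------------------------------------------------------
# Connectivity containers
# ---------------------------------------------------------------------------

#' Streamline set (connectome)
#'
#' Streamlines stored compactly as one point matrix plus per-streamline point
#' counts (the representation used by streamline file formats): streamline i
#' occupies rows `offsets[i] .. offsets[i] + counts[i] - 1` of `points`.
#'
#' @slot points numeric matrix, `N x 3`, coordinates in mm.
#' @slot counts integer vector of points per streamline (each >= 2).
#' @slot metadata list; typically `stepSize` (mm), `maxStepAngle` (degrees)
#'   and, after concatenation, per-streamline `candidate` provenance.
#' @seealso [synthStreamlines()], [filterStreamlines()],
#'   [concatenateEnsemble()]
#' @exportClass Connectome
setClass("Connectome", representation(
  points = "matrix", counts = "integer", metadata = "list"
))

setValidity("Connectome", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L)
    msg <- c(msg, "points must have 3 columns (mm coordinates)")
  if (length(object@counts) && any(object@counts < 2L))
    msg <- c(msg, "every streamline needs at least 2 points")
  if (sum(object@counts) != nrow(object@points))
    msg <- c(msg, "counts must sum to the number of point rows")
  if (length(msg)) msg else TRUE
})

#' Cortical-sheet eccentricity surface
#'
#' Abstract flat stand-in for an early-visual-cortex surface: vertex positions
#' on a 2-D sheet (embedded at z = 0, mm) with a smooth eccentricity value per
#' vertex spanning 0-40 degrees, emulating a cortical-magnification-like
#' log gradient.
#'
#' @slot vertices numeric matrix, `n x 3` (mm; z = 0).
#' @slot eccentricity degrees per vertex, in [0, 40].
#' @slot spacing nominal vertex spacing, mm.
#' @seealso [synthEVCSurface()], [assignEndpointEccentricity()]
#' @exportClass EccSurface
setClass("EccSurface", representation(
  vertices = "matrix", eccentricity = "numeric", spacing = "numeric"
))

setValidity("EccSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L)
    msg <- c(msg, "vertices must have 3 columns")
  if (nrow(object@vertices) != length(object@eccentricity))
    msg <- c(msg, "one eccentricity per vertex required")
  if (length(object@eccentricity) &&
      (min(object@eccentricity) < 0 || max(object@eccentricity) > 40))
    msg <- c(msg, "eccentricity must lie in [0, 40]")
  if (length(msg)) msg else TRUE
})

#' Surface region of interest
#'
#' A set of vertices on an [EccSurface-class], either a functional ROI or a
#' constant-size disk (used for the 5 mm size control and the 1 cm disk ROI).
#'
#' @slot vertexIndices indices into the surface's vertex table.
#' @slot label ROI name.
#' @slot kind `"functional"` or `"disk"`.
#' @slot center,radius disk geometry (mm); `NA` for functional ROIs.
#' @exportClass SurfaceROI
setClass("SurfaceROI", representation(
  vertexIndices = "integer", label = "character", kind = "character",
  center = "numeric", radius = "numeric"
))

setValidity("SurfaceROI", function(object) {
  msg <- character()
  if (!length(object@vertexIndices))
    msg <- c(msg, "ROI must contain at least one vertex")
  if (!object@kind %in% c("functional", "disk"))
    msg <- c(msg, "kind must be 'functional' or 'disk'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "BarDesign", function(object) {
  cat("BarDesign:", object@fieldExtent, "deg field,",
      object@barWidth, "deg bar,", length(object@orientations),
      "orientations x 2 directions,", object@stepsPerSweep, "steps of",
      object@stepDuration, "s; baseline", object@baselineDuration, "s\n")
})

setMethod("show", "ApertureSequence", function(object) {
  d <- dim(object@frames)
  cat("ApertureSequence:", d[1], "frames of", d[2], "x", d[3], "pixels,",
      object@frameDuration, "s/frame; field",
      signif(diff(range(object@gridX)), 4), "deg\n")
})

setMethod("show", "PRFParams", function(object) {
  cat("PRFParams:", length(object@x), "voxel(s); sigma range [",
      signif(min(object@sigma), 3), ",", signif(max(object@sigma), 3),
      "] deg\n")
})

setMethod("show", "HRFModel", function(object) {
  cat("HRFModel:", length(object@samples), "samples at dt =", object@dt,
      "s; peak at", (which.max(object@samples) - 1) * object@dt, "s\n")
})

setMethod("show", "PRFFitSet", function(object) {
  cat("PRFFitSet:", nrow(object@fits), "voxel fit(s)")
  if (nrow(object@fits))
    cat("; median VE", signif(stats::median(object@fits$ve), 3))
  cat("\n")
})

setMethod("show", "ROIVoxelSet", function(object) {
  cat("ROIVoxelSet:", object@roiLabel, "(", object@hemisphere, "),",
      nrow(object@fits@fits), "voxels after inclusion\n")
})

setMethod("show", "CoverageMap", function(object) {
  cat("CoverageMap:", nrow(object@density), "x", ncol(object@density),
      "grid (", object@hemisphere, "hemisphere ), mean density",
      signif(mean(object@density), 3), "\n")
})

setMethod("show", "EccBands", function(object) {
  cat("EccBands:", paste(object@edges, collapse = " | "), "deg\n")
})

setMethod("show", "Connectome", function(object) {
  cat("Connectome:", length(object@counts), "streamlines,",
      nrow(object@points), "points\n")
})

setMethod("show", "EccSurface", function(object) {
  cat("EccSurface:", nrow(object@vertices), "vertices, eccentricity [",
      signif(min(object@eccentricity), 3), ",",
      signif(max(object@eccentricity), 3), "] deg\n")
})

setMethod("show", "SurfaceROI", function(object) {
  cat("SurfaceROI:", object@label, "(", object@kind, "),",
      length(object@vertexIndices), "vertices\n")
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' Accessors for package containers
#'
#' Small accessor helpers so downstream code never touches slots directly.
#'
#' @param object a package container object.
#' @return `apertureFrames()` the frame array; `apertureGrid()` a list with
#'   `x` and `y` coordinate vectors; `fitTable()` the per-voxel fit
#'   data.frame; `nStreamlines()` the streamline count;
#'   `streamlineEndpoints()` a list of two `n x 3` matrices (`first`,
#'   `last`); `surfaceVertices()` the vertex matrix;
#'   `surfaceEccentricity()` the per-vertex eccentricities; `bandEdges()` the
#'   band-edge vector; `coverageDensity()` the density matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
apertureFrames <- function(object) object@frames

#' @rdname accessors
#' @export
apertureGrid <- function(object) list(x = object@gridX, y = object@gridY)

#' @rdname accessors
#' @export
fitTable <- function(object) {
  if (is(object, "ROIVoxelSet")) object@fits@fits else object@fits
}

#' @rdname accessors
#' @export
nStreamlines <- function(object) length(object@counts)

#' @rdname accessors
#' @export
streamlineEndpoints <- function(object) {
  off <- streamlineOffsets(object@counts)
  list(first = object@points[off, , drop = FALSE],
       last = object@points[off + object@counts - 1L, , drop = FALSE])
}

#' @rdname accessors
#' @export
surfaceVertices <- function(object) object@vertices

#' @rdname accessors
#' @export
surfaceEccentricity <- function(object) object@eccentricity

#' @rdname accessors
#' @export
bandEdges <- function(object) object@edges

#' @rdname accessors
#' @export
coverageDensity <- function(object) object@density

# start row index of each streamline in the point matrix
streamlineOffsets <- function(counts) {
  if (!length(counts)) return(integer())
  cumsum(c(1L, counts[-length(counts)]))
}
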