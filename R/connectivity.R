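#' Arc lengths of streamlines
#'
#' Sum of segment lengths per streamline, mm.
#'
#' @param connectome a [Connectome-class].
#' @return numeric vector, one length per streamline.
#' @export
streamlineLengths <- function(connectome) {
  stopifnot(is(connectome, "Connectome"))
  counts <- connectome@counts
  if (!length(counts)) return(numeric())
  pts <- connectome@points
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  segLen <- sqrt(rowSums(d^2))
  # rows crossing from one streamline into the next are not segments
  ends <- cumsum(counts)
  boundary <- ends[-length(ends)]
  segId <- rep.int(seq_along(counts), counts - 1L)
  keep <- rep(TRUE, length(segLen))
  keep[boundary] <- FALSE
  as.numeric(rowsum(segLen[keep], segId, reorder = TRUE))
}

# subset a connectome to a logical/integer streamline selection
subsetConnectome <- function(connectome, keep) {
  counts <- connectome@counts
  if (!is.logical(keep)) {
    keepLog <- rep.int(FALSE, length(counts))
    keepLog[keep] <- TRUE
    keep <- keepLog
  }
  rowKeep <- rep.int(keep, counts)
  md <- connectome@metadata
  if (!is.null(md$candidate)) md$candidate <- md$candidate[keep]
  new("Connectome", points = connectome@points[rowKeep, , drop = FALSE],
      counts = counts[keep], metadata = md)
}

#' Filter streamlines by arc length
#'
#' Retains streamlines whose arc length lies within `[minLen, maxLen]`
#' (bounds inclusive). Filtering is idempotent.
#'
#' @param connectome a [Connectome-class].
#' @param minLen,maxLen length bounds, mm (defaults 4 and 200).
#' @return the filtered [Connectome-class].
#' @export
filterStreamlines <- function(connectome, minLen = 4, maxLen = 200) {
  stopifnot(is(connectome, "Connectome"))
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  if (!length(connectome@counts)) return(connectome)
  len <- streamlineLengths(connectome)
  subsetConnectome(connectome, len >= minLen & len <= maxLen)
}

#' Concatenate candidate connectomes into an ensemble
#'
#' Multiset union: all streamlines of all candidates are retained (no
#' deduplication) and per-candidate provenance is recorded in
#' `metadata$candidate`. The ensemble count is always the sum of candidate
#' counts.
#'
#' @param candidates list of [Connectome-class] objects.
#' @return the ensemble [Connectome-class].
#' @export
concatenateEnsemble <- function(candidates) {
  stopifnot(all(vapply(candidates, is, logical(1), "Connectome")))
  if (!length(candidates))
    return(new("Connectome", points = matrix(numeric(), 0, 3),
               counts = integer(), metadata = list()))
  pts <- do.call(rbind, lapply(candidates, function(c) c@points))
  counts <- do.call(c, lapply(candidates, function(c) c@counts))
  prov <- rep.int(seq_along(candidates),
                  vapply(candidates, nStreamlines, integer(1)))
  new("Connectome", points = pts, counts = counts,
      metadata = list(
        candidate = prov,
        maxStepAngle = vapply(candidates, function(c) {
          a <- c@metadata$maxStepAngle
          if (is.null(a)) NA_real_ else a
        }, numeric(1))))
}

#' Streamline validation stub (pluggable retention predicate)
#'
#' Stand-in for connectome validation against diffusion data (an external
#' tool's job): applies a caller-supplied retention predicate to the
#' ensemble, or passes every streamline through when none is given.
#'
#' @param connectome a [Connectome-class].
#' @param retain `NULL` (keep all) or a function mapping the connectome to a
#'   logical vector, one flag per streamline.
#' @return the culled [Connectome-class].
#' @export
cullConnectome <- function(connectome, retain = NULL) {
  stopifnot(is(connectome, "Connectome"))
  if (is.null(retain)) return(connectome)
  keep <- retain(connectome)
  stopifnot(is.logical(keep), length(keep) == nStreamlines(connectome))
  subsetConnectome(connectome, keep)
}

# minimum distance from each query point to any target vertex (chunked
# brute force; fine at the sizes used here)
.nearestVertex <- function(query, targets, chunk = 2000L) {
  nq <- nrow(query)
  dist <- numeric(nq); idx <- integer(nq)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(targets^2), "+") -
      2 * q %*% t(targets)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, dist = dist)
}

#' Intersect a connectome with surface ROIs
#'
#' Keeps streamlines with an endpoint within `captureDist` of the ROI's
#' vertices; when an `evc` ROI is also given, the *other* endpoint must fall
#' within `captureDist` of it (the functionally-defined-tract reading: one
#' end at the functional ROI, one end in early visual cortex).
#'
#' @param connectome a [Connectome-class].
#' @param roi a [SurfaceROI-class].
#' @param surface the [EccSurface-class] both ROIs live on.
#' @param evc optional second [SurfaceROI-class].
#' @param captureDist endpoint capture distance, mm (default 2).
#' @return the intersected [Connectome-class].
#' @export
intersectROI <- function(connectome, roi, surface, evc = NULL,
                         captureDist = 2) {
  stopifnot(is(connectome, "Connectome"), is(roi, "SurfaceROI"),
            is(surface, "EccSurface"))
  if (!length(connectome@counts)) return(connectome)
  ep <- streamlineEndpoints(connectome)
  rv <- surface@vertices[roi@vertexIndices, , drop = FALSE]
  firstAtROI <- .nearestVertex(ep$first, rv)$dist <= captureDist
  lastAtROI <- .nearestVertex(ep$last, rv)$dist <= captureDist
  if (is.null(evc)) {
    keep <- firstAtROI | lastAtROI
  } else {
    ev <- surface@vertices[evc@vertexIndices, , drop = FALSE]
    firstAtEVC <- .nearestVertex(ep$first, ev)$dist <= captureDist
    lastAtEVC <- .nearestVertex(ep$last, ev)$dist <= captureDist
    keep <- (firstAtROI & lastAtEVC) | (lastAtROI & firstAtEVC)
  }
  subsetConnectome(connectome, keep)
}

#' Percentage of an ROI's tracts reaching EVC
#'
#' `100 * roiToEvcTracts / roiTracts`: of all tracts starting at a
#' functional ROI, the share whose other end reaches early visual cortex.
#'
#' @param roiTracts count of tracts intersecting the ROI.
#' @param roiToEvcTracts count of those also reaching EVC.
#' @return percentage in [0, 100]; NA with a `degenerate` attribute when
#'   `roiTracts` is 0.
#' @export
fwmtPercentage <- function(roiTracts, roiToEvcTracts) {
  stopifnot(roiToEvcTracts >= 0, roiTracts >= roiToEvcTracts)
  if (roiTracts == 0) {
    out <- NA_real_; attr(out, "degenerate") <- TRUE
    return(out)
  }
  100 * roiToEvcTracts / roiTracts
}

#' Assign eccentricities to tract endpoints
#'
#' Each endpoint takes the eccentricity of its nearest surface vertex within
#' `maxDist`; endpoints farther than `maxDist` from every vertex are dropped
#' and counted in the `nDropped` attribute.
#'
#' @param endpoints numeric matrix, `n x 3` positions (mm), or a data.frame
#'   with `x`, `y`, `z`.
#' @param surface an [EccSurface-class].
#' @param maxDist capture distance, mm.
#' @param tdiWeights optional positive weight per endpoint (default 1).
#' @return data.frame of endpoint records (`x`, `y`, `z`, `eccentricity`,
#'   `tdiWeight`) with attribute `nDropped`.
#' @export
assignEndpointEccentricity <- function(endpoints, surface, maxDist = 2,
                                       tdiWeights = NULL) {
  stopifnot(is(surface, "EccSurface"))
  if (is.data.frame(endpoints))
    endpoints <- as.matrix(endpoints[, c("x", "y", "z")])
  if (is.null(tdiWeights)) tdiWeights <- rep(1, nrow(endpoints))
  stopifnot(length(tdiWeights) == nrow(endpoints), all(tdiWeights > 0))
  nn <- .nearestVertex(endpoints, surface@vertices)
  keep <- nn$dist <= maxDist
  out <- data.frame(
    x = endpoints[keep, 1], y = endpoints[keep, 2], z = endpoints[keep, 3],
    eccentricity = surface@eccentricity[nn$index[keep]],
    tdiWeight = tdiWeights[keep])
  attr(out, "nDropped") <- sum(!keep)
  out
}

#' Band proportions of tract endpoints
#'
#' Per-band sums of track-density (TDI) weights divided by the total weight;
#' `weighted = FALSE` counts endpoints instead (all weights treated as 1).
#' Proportions are invariant to uniform scaling of the weights.
#'
#' @param records endpoint record data.frame with `eccentricity` and
#'   `tdiWeight`.
#' @param bands an [EccBands-class].
#' @param weighted use the TDI weights?
#' @return list with `fractions` (per band, summing to 1) and `nItems`.
#' @export
endpointBandProportions <- function(records, bands = eccBands(),
                                    weighted = TRUE) {
  if (!nrow(records)) stop("no endpoint records")
  w <- if (weighted) records$tdiWeight else rep(1, nrow(records))
  idx <- bandAssign(records$eccentricity, bands)
  ok <- !is.na(idx)
  total <- sum(w[ok])
  if (total <= 0) stop("total endpoint weight is zero")
  sums <- vapply(seq_len(length(bands@edges) - 1L),
                 function(b) sum(w[ok & idx == b]), numeric(1))
  list(fractions = sums / total, nItems = sum(ok))
}

#' Constant-size disk ROI on a surface
#'
#' All vertices within `radius` (sheet distance, mm) of a center position;
#' used for the 5 mm size-control disks and the 1 cm disk ROI.
#'
#' @param center position, mm (length-3; z ignored on the flat sheet).
#' @param radius disk radius, mm (> 0).
#' @param surface an [EccSurface-class].
#' @param label ROI name.
#' @return a [SurfaceROI-class]; error if no vertex is captured.
#' @export
makeDiskROI <- function(center, radius, surface, label = "disk") {
  stopifnot(is(surface, "EccSurface"), radius > 0)
  center <- rep_len(as.numeric(center), 3L)
  d <- sqrt(colSums((t(surface@vertices) - center)^2))
  idx <- which(d <= radius)
  if (!length(idx))
    stop("disk of radius ", radius, " mm captures no vertices")
  new("SurfaceROI", vertexIndices = as.integer(idx), label = label,
      kind = "disk", center = center, radius = radius)
}

#' Functional ROI from explicit vertices
#'
#' @param vertexIndices indices into the surface vertex table.
#' @param label ROI name.
#' @return a [SurfaceROI-class].
#' @export
makeFunctionalROI <- function(vertexIndices, label = "fROI") {
  new("SurfaceROI", vertexIndices = as.integer(vertexIndices), label = label,
      kind = "functional", center = rep(NA_real_, 3), radius = NA_real_)
}
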