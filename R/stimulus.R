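#' Build a bar-sweep stimulus design
#'
#' Validates a configuration into a [BarDesign-class]. The defaults reproduce
#' the wide-field cartoon-carrier bar-mapping design: a 40 x 40 degree field,
#' 5.7 degree bars in four orientations (0, 45, 90, 135 degrees) each swept in
#' two opposed directions, 12 steps of 2 s per 24 s sweep, blanks replacing
#' the final six steps of each diagonal sweep, and a 12 s leading blank
#' baseline; the carrier updates at 8 Hz (metadata only).
#'
#' @param config named list overriding any of `fieldExtent`, `barWidth`,
#'   `orientations`, `stepsPerSweep`, `stepDuration`, `blankRule`,
#'   `baselineDuration`, `carrierRate`, `sweepOrder`.
#' @return a validated [BarDesign-class].
#' @examples
#' buildBarDesign()                        # paper-scale defaults, 204 s run
#' buildBarDesign(list(fieldExtent = 20, barWidth = 20))  # full-field bar
#' @export
buildBarDesign <- function(config = list()) {
  defaults <- list(
    fieldExtent = 40, barWidth = 5.7, orientations = c(0, 45, 90, 135),
    stepsPerSweep = 12L, stepDuration = 2, baselineDuration = 12,
    blankRule = "replace_second_half_of_diagonals", carrierRate = 8
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown design field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  design <- new("BarDesign",
    fieldExtent = as.numeric(cfg$fieldExtent),
    barWidth = as.numeric(cfg$barWidth),
    orientations = as.numeric(cfg$orientations),
    nDirections = 2 * length(cfg$orientations),
    stepsPerSweep = as.integer(cfg$stepsPerSweep),
    stepDuration = as.numeric(cfg$stepDuration),
    blankRule = cfg$blankRule,
    baselineDuration = as.numeric(cfg$baselineDuration),
    carrierRate = as.numeric(cfg$carrierRate)
  )
  validObject(design)
  design
}

#' Total run duration of a bar-sweep design
#'
#' Baseline plus `nDirections * stepsPerSweep * stepDuration`. Blanks that
#' replace bar steps occupy the same time and do not change the total; the
#' default design totals 204 s (3 min 24 s).
#'
#' @param design a [BarDesign-class].
#' @return run duration in seconds.
#' @export
scheduleDuration <- function(design) {
  stopifnot(is(design, "BarDesign"))
  validObject(design)
  design@baselineDuration +
    design@nDirections * design@stepsPerSweep * design@stepDuration
}

# sweep table: one row per sweep in canonical order (orientation ascending,
# forward then reverse direction); `diagonal` marks sweeps subject to the
# blank-replacement rule
sweepSchedule <- function(design) {
  ori <- design@orientations
  data.frame(
    orientation = rep(ori, each = 2L),
    reversed = rep(c(FALSE, TRUE), length(ori)),
    diagonal = rep(ori %% 90 != 0, each = 2L)
  )
}

#' Generate the binarized aperture sequence for a bar-sweep design
#'
#' Renders one binary frame per bar step on a square grid of pixel centers in
#' degrees (fixation at the origin). For each sweep the bar, a band of width
#' `barWidth` perpendicular to the sweep direction, advances so that it
#' traverses the field while remaining fully inside it; opposite directions of
#' an orientation visit the same positions in reverse order. Under the
#' blank-replacement rule the final `floor(stepsPerSweep / 2)` frames of every
#' diagonal sweep are all-zero, and `baselineDuration` of leading all-zero
#' frames precede the sweeps.
#'
#' @param design a [BarDesign-class].
#' @param gridResolution pixels per side; odd and at least 3 so one pixel is
#'   centered at fixation.
#' @return an [ApertureSequence-class].
#' @examples
#' ap <- generateAperture(buildBarDesign(), gridResolution = 41)
#' dim(apertureFrames(ap))
#' @export
generateAperture <- function(design, gridResolution = 101L) {
  stopifnot(is(design, "BarDesign"))
  validObject(design)
  gridResolution <- as.integer(gridResolution)
  if (gridResolution < 3L || gridResolution %% 2L == 0L)
    stop("gridResolution must be odd and >= 3")

  E <- design@fieldExtent
  w <- design@barWidth
  S <- design@stepsPerSweep
  half <- E / 2
  coords <- seq(-half, half, length.out = gridResolution)
  X <- matrix(coords, gridResolution, gridResolution, byrow = TRUE)
  Y <- matrix(coords, gridResolution, gridResolution)

  sched <- sweepSchedule(design)
  nBaseline <- round(design@baselineDuration / design@stepDuration)
  total <- nBaseline + nrow(sched) * S
  frames <- array(0, dim = c(total, gridResolution, gridResolution))

  t0 <- nBaseline
  for (k in seq_len(nrow(sched))) {
    th <- sched$orientation[k] * pi / 180     # bar long-axis angle
    # sweep axis is perpendicular to the bar
    ux <- cos(th + pi / 2); uy <- sin(th + pi / 2)
    proj <- X * ux + Y * uy
    # extent of the square field projected onto the sweep axis
    projExtent <- E * (abs(ux) + abs(uy))
    span <- projExtent - w
    centers <- if (S == 1L) 0 else seq(-span / 2, span / 2, length.out = S)
    if (sched$reversed[k]) centers <- rev(centers)
    nBlank <- if (sched$diagonal[k] &&
                  design@blankRule == "replace_second_half_of_diagonals")
      S %/% 2L else 0L
    for (s in seq_len(S - nBlank)) {
      # small tolerance keeps boundary-pixel inclusion consistent across
      # orientations when |proj - center| lands exactly on w/2
      bar <- abs(proj - centers[s]) <= w / 2 + 1e-9
      frames[t0 + s, , ] <- bar + 0
    }
    t0 <- t0 + S
  }

  ap <- new("ApertureSequence", frames = frames, gridX = coords,
            gridY = coords, frameDuration = design@stepDuration)
  validObject(ap)
  ap
}
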