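# shared fixtures, built once per test run

fixtureDesign <- buildBarDesign()
fixtureAperture <- generateAperture(fixtureDesign, gridResolution = 51L)
fixtureHRF <- canonicalHRF(dt = 1)
fixtureTR <- 2

# a small hand-made fit table wrapped as a PRFFitSet
makeFitSet <- function(x, y, sigma, n = 1, ve = 0.9, atFloor = FALSE) {
  len <- max(lengths(list(x, y, sigma)))
  rl <- function(v) if (len) rep_len(v, len) else v[0]
  f <- data.frame(x = rl(x), y = rl(y),
                  sigma = rl(sigma), n = rl(n),
                  gain = rl(1), ve = rl(ve), converged = rl(TRUE),
                  atSigmaFloor = rl(atFloor))
  f$ecc <- sqrt(f$x^2 + f$y^2)
  f$phase <- atan2(f$y, f$x)
  f$size <- f$sigma / sqrt(f$n)
  new("PRFFitSet", fits = f)
}

makeVoxelSet <- function(..., hemisphere = "right", label = "synthROI") {
  new("ROIVoxelSet", roiLabel = label, hemisphere = hemisphere,
      fits = makeFitSet(...))
}

# straight streamline of given arc length along +x from a start point (1 mm
# steps plus a fractional remainder step)
straightStreamline <- function(length, start = c(0, 0, 0)) {
  nWhole <- floor(length)
  xs <- seq(0, nWhole)
  if (length > nWhole) xs <- c(xs, length)
  cbind(start[1] + xs, start[2], start[3])
}

makeConnectome <- function(lengths, start = c(0, 0, 0)) {
  mats <- lapply(lengths, straightStreamline, start = start)
  new("Connectome", points = do.call(rbind, mats),
      counts = as.integer(vapply(mats, nrow, integer(1))),
      metadata = list(stepSize = 1))
}

# binomial 99% CI half-width
binomCI99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
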