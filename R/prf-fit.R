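#' Variance explained by a model prediction
#'
#' `1 - SS_residual / SS_total`, with the total sum of squares taken about
#' the mean of the observed series. Negative values (model worse than the
#' mean) are clipped to 0 for reporting unless `clip = FALSE`. A
#' zero-variance observed series is degenerate: the value is defined as 0 and
#' the result carries attribute `degenerate = TRUE`.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @param clip clip the reported value into [0, 1]?
#' @return variance explained as a fraction.
#' @examples
#' varianceExplained(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 0.8
#' @export
varianceExplained <- function(observed, predicted, clip = TRUE) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("observed and predicted must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    ve <- 0
    attr(ve, "degenerate") <- TRUE
    return(ve)
  }
  ve <- 1 - sum((observed - predicted)^2) / sst
  if (clip) ve <- min(max(ve, 0), 1)
  ve
}

#' Fitting options for the pRF estimator
#'
#' @param sigmaFloor lower sigma bound, degrees; fits stuck exactly at this
#'   bound are flagged (`atSigmaFloor`) and excluded by [applyInclusion()].
#' @param sigmaMax upper sigma bound, degrees.
#' @param boundXY center bound: x, y restricted to `[-boundXY, boundXY]`.
#' @param nMin lower bound of the compressive exponent.
#' @param gridEcc candidate center eccentricities, degrees; default spans 0 to
#'   1.25 x the 40-degree field.
#' @param gridAngles number of polar angles in the candidate grid.
#' @param gridSigma number of log-spaced candidate sigmas (sigmaFloor to 40).
#' @param gridN candidate exponents.
#' @param refine run bounded nonlinear refinement after the grid search?
#' @param maxit refinement iteration cap.
#' @return named list of options.
#' @export
fitOptions <- function(sigmaFloor = 0.21, sigmaMax = 60, boundXY = 60,
                       nMin = 0.01,
                       gridEcc = c(0, 1, 2, 3.5, 5, 7, 10, 14, 19, 25, 33, 50),
                       gridAngles = 12L, gridSigma = 8L,
                       gridN = c(0.25, 0.5, 1), refine = TRUE, maxit = 150L) {
  list(sigmaFloor = sigmaFloor, sigmaMax = sigmaMax, boundXY = boundXY,
       nMin = nMin, gridEcc = gridEcc, gridAngles = gridAngles,
       gridSigma = gridSigma, gridN = gridN, refine = refine, maxit = maxit)
}

# flatten an aperture to a T x P stimulus matrix
stimulusMatrix <- function(aperture) {
  matrix(aperture@frames, nrow = dim(aperture@frames)[1])
}

# linear operator mapping a per-frame neural response to the BOLD series:
# column j is the BOLD series evoked by a unit response in frame j
boldOperator <- function(aperture, hrf, tr) {
  nT <- dim(aperture@frames)[1]
  nVol <- round(nT * aperture@frameDuration / tr)
  C <- matrix(0, nVol, nT)
  for (j in seq_len(nT)) {
    e <- numeric(nT); e[j] <- 1
    C[, j] <- boldFromNeural(e, aperture@frameDuration, hrf, tr)[seq_len(nVol)]
  }
  C
}

# candidate table for the coarse grid search
candidateGrid <- function(opts) {
  angles <- seq(0, 2 * pi, length.out = opts$gridAngles + 1L)[-1L]
  ecc <- opts$gridEcc
  centers <- rbind(
    c(0, 0),
    do.call(rbind, lapply(ecc[ecc > 0], function(e)
      cbind(e * cos(angles), e * sin(angles))))
  )
  sigmas <- exp(seq(log(opts$sigmaFloor), log(40), length.out = opts$gridSigma))
  expand <- expand.grid(center = seq_len(nrow(centers)),
                        sigma = sigmas, n = opts$gridN)
  data.frame(x = centers[expand$center, 1], y = centers[expand$center, 2],
             sigma = expand$sigma, n = expand$n)
}

# SSE of one CSS parameter vector against one observed series, with the gain
# solved in closed form (non-negative least squares for a single regressor)
cssSSE <- function(par, y, S, C, gridX, gridY, pixArea) {
  g <- exp(-((outer((gridY - par[2])^2, (gridX - par[1])^2, "+")) /
               (2 * par[3]^2))) * (pixArea / (2 * pi * par[3]^2))
  overlap <- as.vector(S %*% as.vector(g))
  overlap[overlap < 0] <- 0
  pred <- as.vector(C %*% overlap^par[4])
  den <- sum(pred^2)
  num <- sum(y * pred)
  gain <- if (den > 0 && num > 0) num / den else 0
  list(sse = sum((y - gain * pred)^2), gain = gain, pred = gain * pred)
}

#' Fit CSS pRF models to a set of voxel time series
#'
#' Two-stage estimator: a coarse grid search over center, sigma and exponent
#' (the gain solved in closed form by least squares at every candidate) seeds
#' a bounded quasi-Newton refinement of all four shape parameters minimizing
#' the sum of squared errors. Variance explained, convergence and
#' sigma-at-floor flags plus derived eccentricity, phase and size are
#' returned per voxel.
#'
#' @param Y numeric matrix of observed series, voxels x volumes (a single
#'   series may be given as a vector).
#' @param aperture an [ApertureSequence-class] matching the acquisition.
#' @param hrf an [HRFModel-class].
#' @param tr repetition time, seconds; `nFrames * frameDuration / tr` must
#'   equal `ncol(Y)`.
#' @param opts options from [fitOptions()].
#' @return a [PRFFitSet-class] with one row per voxel.
#' @seealso [applyInclusion()], [proportionModulated()]
#' @export
fitPRFSet <- function(Y, aperture, hrf, tr, opts = fitOptions()) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  stopifnot(is(aperture, "ApertureSequence"), is(hrf, "HRFModel"))
  nT <- dim(aperture@frames)[1]
  nVol <- round(nT * aperture@frameDuration / tr)
  if (ncol(Y) != nVol)
    stop("series length (", ncol(Y), ") does not match the schedule (",
         nVol, " volumes)")

  S <- stimulusMatrix(aperture)
  C <- boldOperator(aperture, hrf, tr)
  gridX <- aperture@gridX; gridY <- aperture@gridY
  pixArea <- mean(diff(gridX)) * mean(diff(gridY))
  cand <- candidateGrid(opts)

  # overlap per unique Gaussian; exponents share Gaussians
  geom <- unique(cand[c("x", "y", "sigma")])
  geomKey <- match(interaction(cand$x, cand$y, cand$sigma, drop = TRUE),
                   interaction(geom$x, geom$y, geom$sigma, drop = TRUE))
  O <- matrix(0, nT, nrow(geom))
  for (k in seq_len(nrow(geom))) {
    g <- exp(-((outer((gridY - geom$y[k])^2, (gridX - geom$x[k])^2, "+")) /
                 (2 * geom$sigma[k]^2))) *
      (pixArea / (2 * pi * geom$sigma[k]^2))
    O[, k] <- S %*% as.vector(g)
  }
  O[O < 0] <- 0
  P <- matrix(0, nVol, nrow(cand))
  for (nv in unique(cand$n)) {
    idx <- which(cand$n == nv)
    P[, idx] <- C %*% (O[, geomKey[idx], drop = FALSE]^nv)
  }

  den <- colSums(P^2)
  num <- Y %*% P                       # nvox x ncand
  score <- num^2 / rep(pmax(den, .Machine$double.eps), each = nrow(Y))
  score[num <= 0] <- 0
  best <- max.col(score, ties.method = "first")

  lower <- c(-opts$boundXY, -opts$boundXY, opts$sigmaFloor, opts$nMin)
  upper <- c(opts$boundXY, opts$boundXY, opts$sigmaMax, 1)

  out <- vector("list", nrow(Y))
  for (v in seq_len(nrow(Y))) {
    y <- Y[v, ]
    if (stats::var(y) == 0) {
      out[[v]] <- data.frame(x = 0, y = 0, sigma = opts$sigmaFloor, n = 1,
                             gain = 0, ve = 0, converged = FALSE,
                             atSigmaFloor = TRUE)
      next
    }
    b <- best[v]
    par0 <- c(cand$x[b], cand$y[b], cand$sigma[b], cand$n[b])
    seed <- cssSSE(par0, y, S, C, gridX, gridY, pixArea)
    par <- par0; sse <- seed$sse; gain <- seed$gain; conv <- TRUE
    if (opts$refine) {
      fit <- try(stats::optim(
        par0, function(p) cssSSE(p, y, S, C, gridX, gridY, pixArea)$sse,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = opts$maxit, factr = 1e4,
                       parscale = c(1, 1, 1, 0.2))), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$value <= sse) {
        par <- fit$par; sse <- fit$value
        conv <- fit$convergence == 0
        gain <- cssSSE(par, y, S, C, gridX, gridY, pixArea)$gain
      }
    }
    final <- cssSSE(par, y, S, C, gridX, gridY, pixArea)
    out[[v]] <- data.frame(
      x = par[1], y = par[2], sigma = par[3], n = par[4], gain = final$gain,
      ve = as.numeric(varianceExplained(y, final$pred)),
      converged = conv, atSigmaFloor = par[3] <= opts$sigmaFloor)
  }
  fits <- do.call(rbind, out)
  fits$ecc <- sqrt(fits$x^2 + fits$y^2)
  fits$phase <- atan2(fits$y, fits$x)
  fits$size <- fits$sigma / sqrt(fits$n)
  rownames(fits) <- NULL
  new("PRFFitSet", fits = fits)
}

#' Fit a single voxel time series
#'
#' Convenience wrapper around [fitPRFSet()] for one series.
#'
#' @inheritParams fitPRFSet
#' @param ts numeric vector of observed signal per volume.
#' @return a [PRFFitSet-class] with one row.
#' @export
fitPRF <- function(ts, aperture, hrf, tr, opts = fitOptions()) {
  fitPRFSet(matrix(ts, nrow = 1), aperture, hrf, tr, opts)
}

#' Apply voxel inclusion criteria to a fit set
#'
#' Keeps voxels whose variance explained strictly exceeds `veMin` and whose
#' sigma did not stick at the optimizer floor; drops the whole ROI (returns
#' `NULL`) when fewer than `minVoxels` survive. `veMin = 0.10` reproduces the
#' relaxed robustness threshold.
#'
#' @param fitset a [PRFFitSet-class].
#' @param veMin variance-explained threshold (strict `>`).
#' @param sigmaFloor sigma floor used at fit time, degrees.
#' @param minVoxels minimum surviving voxel count for the ROI to be kept.
#' @param roiLabel,hemisphere ROI annotation for the returned set.
#' @return an [ROIVoxelSet-class], or `NULL` when the ROI is dropped.
#' @export
applyInclusion <- function(fitset, veMin = 0.20, sigmaFloor = 0.21,
                           minVoxels = 10L, roiLabel = "ROI",
                           hemisphere = "right") {
  stopifnot(is(fitset, "PRFFitSet"), veMin >= 0, veMin < 1, sigmaFloor > 0)
  f <- fitset@fits
  keep <- f$ve > veMin & !f$atSigmaFloor & f$sigma > sigmaFloor
  if (sum(keep) < minVoxels) return(NULL)
  new("ROIVoxelSet", roiLabel = roiLabel, hemisphere = hemisphere,
      fits = new("PRFFitSet", fits = f[keep, , drop = FALSE]))
}

#' Proportion of retinotopically modulated voxels
#'
#' Fraction of voxels whose pRF model variance explained strictly exceeds the
#' threshold, the per-ROI responsiveness statistic.
#'
#' @param fitset a non-empty [PRFFitSet-class].
#' @param veMin variance-explained threshold.
#' @return fraction in [0, 1].
#' @export
proportionModulated <- function(fitset, veMin = 0.20) {
  stopifnot(is(fitset, "PRFFitSet"))
  f <- fitset@fits
  if (!nrow(f)) stop("empty fit set")
  mean(f$ve > veMin)
}
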