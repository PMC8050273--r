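test_that("population sampling matches its closed-form eccentricity law", {
  vp <- ventralProfile(500)
  truth <- samplePopulation(vp, seed = 4)
  ecc <- derivedMetrics(truth)$ecc
  pTrue <- profileEccCDF(vp, 5)
  expect_gt(pTrue, 0.6)                       # foveally concentrated
  expect_lt(abs(mean(ecc < 5) - pTrue), binomCI99(pTrue, 500))

  lp <- lateralProfile(500)
  expect_equal(profileEccCDF(lp, 5), (5 / 35)^2)
  eccL <- derivedMetrics(samplePopulation(lp, seed = 5))$ecc
  expect_lt(mean(eccL < 5), 0.2)

  # reproducibility and constraints
  expect_identical(samplePopulation(vp, seed = 4)@x, truth@x)
  expect_true(all(truth@sigma >= 0.3))
  expect_true(all(ecc >= 0))
})

test_that("contralateral polar concentration respects the hemisphere", {
  right <- samplePopulation(ventralProfile(300, hemisphere = "right"),
                            seed = 6)
  left <- samplePopulation(ventralProfile(300, hemisphere = "left"),
                           seed = 6)
  expect_gt(mean(right@x < 0), 0.9)           # right hemisphere -> left field
  expect_gt(mean(left@x > 0), 0.9)
})

test_that("generated BOLD reduces to the forward model at zero noise", {
  truth <- samplePopulation(ventralProfile(3), seed = 7)
  Y <- generateBold(truth, fixtureAperture, fixtureHRF, fixtureTR,
                    noiseSd = 0, seed = 8)
  for (v in 1:3)
    expect_identical(Y[v, ], predictBold(truth, fixtureAperture, fixtureHRF,
                                         fixtureTR, which = v))
  # zero-gain voxels give pure noise
  flat <- prfParams(0, 0, 2, 0.5, gain = 0)
  Yn <- generateBold(flat, fixtureAperture, fixtureHRF, fixtureTR,
                     noiseSd = 1, seed = 9)
  expect_gt(stats::sd(Yn[1, ]), 0.5)
  expect_equal(mean(Yn[1, ]), 0, tolerance = 0.5)
})

test_that("targetVE noise calibration lands near the requested level", {
  set.seed(10)
  nv <- 40
  ecc <- runif(nv, 0, 15)
  truth <- prfParams(ecc, 0, sigma = runif(nv, 2, 8), n = runif(nv, 0.3, 1))
  Y <- generateBold(truth, fixtureAperture, fixtureHRF, fixtureTR,
                    noiseSd = "targetVE", targetVE = 0.6, seed = 11)
  # VE of the true prediction against the noisy series
  ves <- vapply(seq_len(nv), function(v)
    as.numeric(varianceExplained(Y[v, ],
                                 predictBold(truth, fixtureAperture,
                                             fixtureHRF, fixtureTR,
                                             which = v))),
    numeric(1))
  expect_lt(abs(median(ves) - 0.6), 0.1)
})

test_that("synthetic surface spans the band range smoothly and evenly", {
  s <- synthEVCSurface(5000, seed = 12)
  ecc <- surfaceEccentricity(s)
  expect_gte(min(ecc), 0)
  expect_lte(max(ecc), 40)
  counts <- tabulate(bandAssign(ecc, eccBands()), 4)
  expect_lt(max(counts) / min(counts), 1.3 / 0.7)   # within 30% of each other

  # neighbor smoothness: adjacent vertices along the gradient differ < 2 deg
  v <- surfaceVertices(s)
  ord <- order(v[, 2], v[, 1])
  sameRow <- diff(v[ord, 2]) == 0
  expect_lt(max(abs(diff(ecc[ord]))[sameRow]), 2)
})

test_that("synthetic endpoints honor band weights and reproduce under a seed", {
  s <- synthEVCSurface(5000, seed = 13)
  w <- c(0.5, 0.25, 0.15, 0.1)
  ep <- synthEndpoints(w, 10000, s, weightDispersion = 0, seed = 14)
  pr <- endpointBandProportions(ep)$fractions
  for (b in 1:4)
    expect_lt(abs(pr[b] - w[b]), binomCI99(w[b], 10000))
  expect_true(all(ep$tdiWeight == 1))

  ep2 <- synthEndpoints(w, 10000, s, weightDispersion = 0, seed = 14)
  expect_identical(ep, ep2)
  expect_error(synthEndpoints(c(0.5, 0.5, 0.1, 0.1), 10, s), "sum to 1")

  one <- synthEndpoints(c(1, 0, 0, 0), 200, s, seed = 15)
  expect_true(all(bandAssign(one$eccentricity, eccBands()) == 1))
})

test_that("synthetic streamlines use 1 mm steps with the stated lengths", {
  con <- synthStreamlines(200, lengthMean = 30, lengthSd = 8,
                          maxStepAngle = 20, seed = 16)
  expect_equal(nStreamlines(con), 200)
  len <- streamlineLengths(con)
  expect_equal(len, con@counts - 1, tolerance = 1e-9)
  expect_lt(abs(mean(len) - 30), 3)

  # every step is exactly 1 mm
  off <- prfcss:::streamlineOffsets(con@counts)
  firstSteps <- sqrt(rowSums((con@points[off + 1L, ] - con@points[off, ])^2))
  expect_equal(firstSteps, rep(1, 200), tolerance = 1e-9)

  expect_equal(nStreamlines(synthStreamlines(0)), 0)
  expect_identical(con@points, synthStreamlines(200, 30, 8, 20, 16)@points)
})

test_that("turning angles never exceed the per-step bound", {
  con <- synthStreamlines(50, lengthMean = 20, lengthSd = 3,
                          maxStepAngle = 15, seed = 17)
  off <- prfcss:::streamlineOffsets(con@counts)
  for (i in seq_len(50)) {
    pts <- con@points[off[i]:(off[i] + con@counts[i] - 1L), , drop = FALSE]
    if (nrow(pts) < 3) next
    d <- diff(pts)
    d <- d / sqrt(rowSums(d^2))
    cosang <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
    expect_true(all(cosang >= cos(15 * pi / 180) - 1e-9))
  }
})
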