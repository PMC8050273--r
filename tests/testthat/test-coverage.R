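test_that("band assignment follows the half-open convention", {
  b <- eccBands()
  expect_identical(bandEdges(b), c(0, 5, 10, 20, 40))
  expect_equal(bandAssign(c(0, 2, 4.999), b), c(1L, 1L, 1L))
  expect_equal(bandAssign(5, b), 2L)            # edge goes to the upper band
  expect_equal(bandAssign(c(10, 20), b), c(3L, 4L))
  expect_equal(bandAssign(40, b), 4L)           # last band closed
  expect_true(is.na(bandAssign(40.001, b)))
  expect_true(is.na(bandAssign(-1, b)))
  expect_error(eccBands(c(0, 5, 5)), "increasing")
})

test_that("coverage equals brute-force point-in-disk counting exactly", {
  set.seed(31)
  nP <- 20
  vs <- makeVoxelSet(x = runif(nP, -15, 15), y = runif(nP, -15, 15),
                     sigma = runif(nP, 1, 8), n = runif(nP, 0.25, 1))
  map <- computeVFC(vs, gridResolution = 51, fieldExtent = 40)
  f <- fitTable(vs)
  grid <- seq(-20, 20, length.out = 51)
  oracle <- matrix(0, 51, 51)
  for (i in 1:51) for (j in 1:51) {
    cnt <- 0
    for (v in 1:nP)
      if ((grid[j] - f$x[v])^2 + (grid[i] - f$y[v])^2 <= f$size[v]^2)
        cnt <- cnt + 1
    oracle[i, j] <- cnt / nP
  }
  expect_identical(coverageDensity(map), oracle)
})

test_that("single and replicated pRFs give the expected disk indicator", {
  one <- computeVFC(makeVoxelSet(0, 0, sigma = 5, n = 1), 51, 40)
  many <- computeVFC(makeVoxelSet(rep(0, 7), 0, sigma = 5, n = 1), 51, 40)
  expect_identical(coverageDensity(one), coverageDensity(many))
  expect_true(all(coverageDensity(one) %in% c(0, 1)))
  expect_error(computeVFC(makeFitSet(numeric(), numeric(), numeric()),
                          hemisphere = "right"))
})

test_that("density-by-eccentricity matches a per-annulus masking oracle", {
  vs <- makeVoxelSet(x = c(-3, -8, 2), y = c(1, -4, 6),
                     sigma = c(4, 6, 3), n = c(1, 0.5, 1))
  map <- computeVFC(vs, 51, 40)
  curve <- densityVsEccentricity(map, binWidth = 2)

  grid <- seq(-20, 20, length.out = 51)
  X <- matrix(grid, 51, 51, byrow = TRUE)
  Y <- matrix(grid, 51, 51)
  ecc <- sqrt(X^2 + Y^2)
  contra <- X < 0                               # right hemisphere
  d <- coverageDensity(map)
  for (k in seq_len(nrow(curve))) {
    lo <- curve$ecc[k] - 1; hi <- curve$ecc[k] + 1
    m <- contra & ecc >= lo & ecc < hi
    expect_equal(curve$density[k], mean(d[m]))
  }
})

test_that("flat and single-disk maps give the expected density profiles", {
  res <- 41
  coords <- seq(-20, 20, length.out = res)
  uniform <- new("CoverageMap", gridX = coords, gridY = coords,
                 density = matrix(0.4, res, res), hemisphere = "right")
  curve <- densityVsEccentricity(uniform)
  expect_true(all(abs(curve$density - 0.4) < 1e-12))

  disk <- computeVFC(makeVoxelSet(0, 0, sigma = 5, n = 1), res, 40)
  dc <- densityVsEccentricity(disk)
  expect_true(all(dc$density[dc$ecc < 4] > 0))
  expect_true(all(dc$density[dc$ecc > 6] == 0))
})

test_that("laterality and vertical-bias indices hit their identities", {
  # fully contralateral disk (right hemisphere -> left visual field)
  contra <- computeVFC(makeVoxelSet(-10, 0, sigma = 4, n = 1), 51, 40)
  expect_equal(lateralityIndex(contra), 1)
  # mirror-symmetric pair
  symm <- computeVFC(makeVoxelSet(c(-10, 10), 0, sigma = 4, n = 1), 51, 40)
  expect_equal(lateralityIndex(symm), 0)
  # fully ipsilateral
  ipsi <- computeVFC(makeVoxelSet(10, 0, sigma = 4, n = 1), 51, 40)
  expect_equal(lateralityIndex(ipsi), -1)

  upper <- computeVFC(makeVoxelSet(-10, 8, sigma = 4, n = 1), 51, 40)
  expect_equal(verticalBiasIndex(upper), 1)
  vsymm <- computeVFC(makeVoxelSet(c(-10, -10), c(8, -8), sigma = 4, n = 1),
                      51, 40)
  expect_equal(verticalBiasIndex(vsymm), 0)
  lower <- computeVFC(makeVoxelSet(-10, -8, sigma = 4, n = 1), 51, 40)
  expect_equal(verticalBiasIndex(lower), -1)

  empty <- new("CoverageMap", gridX = contra@gridX, gridY = contra@gridY,
               density = matrix(0, 51, 51), hemisphere = "right")
  expect_true(is.na(lateralityIndex(empty)))
  expect_true(attr(lateralityIndex(empty), "degenerate"))
})

test_that("formula cases for the indices", {
  # contra mean 0.3, ipsi mean 0.1 -> 0.5; build it directly
  res <- 41
  coords <- seq(-20, 20, length.out = res)
  dens <- matrix(0.1, res, res)
  dens[, coords < 0] <- 0.3
  m <- new("CoverageMap", gridX = coords, gridY = coords, density = dens,
           hemisphere = "right")
  expect_equal(lateralityIndex(m), 0.5, tolerance = 1e-2)

  dens2 <- matrix(0, res, res)
  dens2[coords > 0, coords < 0] <- 0.2      # upper contra
  dens2[coords < 0, coords < 0] <- 0.6      # lower contra
  m2 <- new("CoverageMap", gridX = coords, gridY = coords, density = dens2,
            hemisphere = "right")
  expect_equal(verticalBiasIndex(m2), -0.5)
})

test_that("center band proportions sum to one and respect exclusions", {
  vs <- makeVoxelSet(x = c(-2, -3, -7, -15, -45), y = 0, sigma = 2)
  bp <- centerBandProportions(vs)
  expect_equal(sum(bp$fractions), 1, tolerance = 1e-9)
  expect_equal(bp$nItems, 4)
  expect_equal(bp$nExcluded, 1)              # the 45-degree center
  expect_equal(bp$fractions, c(0.5, 0.25, 0.25, 0))

  all2 <- centerBandProportions(makeVoxelSet(rep(-2, 5), 0, 2))
  expect_equal(all2$fractions, c(1, 0, 0, 0))
  expect_error(centerBandProportions(makeVoxelSet(-50, 0, 2)), "outside")

  # uniform-by-area centers match annulus-area ratios
  truth <- samplePopulation(populationProfile("u", "uniform_area",
                                              maxEcc = 40, nVoxels = 4000),
                            seed = 32)
  dm <- derivedMetrics(truth)
  fs <- makeFitSet(truth@x, truth@y, truth@sigma, truth@n)
  bp2 <- centerBandProportions(fs)
  areas <- c(25, 75, 300, 1200) / 1600
  for (b in 1:4)
    expect_lt(abs(bp2$fractions[b] - areas[b]), binomCI99(areas[b], 4000))
})

test_that("median size per band matches a sort-and-pick oracle", {
  vs <- makeVoxelSet(x = c(-2, -3, -4, -8, -12, -25), y = 0,
                     sigma = c(1, 2, 9, 5, 6, 7), n = 1)
  med <- medianSizeByBand(vs)
  expect_equal(med, c(2, 5, 6, 7))
  one <- medianSizeByBand(makeVoxelSet(-3, 0, sigma = 2, n = 1))
  expect_equal(one, c(2, NA, NA, NA))
})
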