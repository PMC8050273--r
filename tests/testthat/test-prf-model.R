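test_that("gaussian field is unit-volume, unimodal, and flags far-out centers", {
  grid <- apertureGrid(fixtureAperture)
  p <- prfParams(2.1, -3.1, sigma = 2)
  g <- gaussianField(p, grid$x, grid$y)
  expect_lt(abs(sum(g) - 1), 1e-6)               # truncation loss tiny
  # maximum at the pixel nearest the center
  peak <- which(g == max(g), arr.ind = TRUE)
  expect_equal(grid$x[peak[2]], grid$x[which.min(abs(grid$x - 2.1))])
  expect_equal(grid$y[peak[1]], grid$y[which.min(abs(grid$y + 3.1))])

  far <- gaussianField(prfParams(120, 0, sigma = 2), grid$x, grid$y)
  expect_lt(sum(far), 0.01)
  expect_true(attr(far, "outOfAperture"))

  expect_error(prfParams(0, 0, sigma = 0, n = 1), "sigma")
})

test_that("neural response follows compressive summation limits", {
  grid <- apertureGrid(fixtureAperture)
  res <- length(grid$x)
  fullField <- new("ApertureSequence",
                   frames = array(1, dim = c(2, res, res)),
                   gridX = grid$x, gridY = grid$y, frameDuration = 2)
  for (n in c(0.25, 0.5, 1)) {
    r <- predictNeural(prfParams(0, 0, 2, n), fullField)
    expect_equal(r, c(1, 1), tolerance = 1e-6)
  }
  blank <- new("ApertureSequence", frames = array(0, dim = c(3, res, res)),
               gridX = grid$x, gridY = grid$y, frameDuration = 2)
  expect_equal(predictNeural(prfParams(1, 1, 3, 0.5), blank), c(0, 0, 0))
})

test_that("half-plane overlap matches the Gaussian-tail closed form", {
  grid <- apertureGrid(fixtureAperture)
  res <- length(grid$x)
  half <- matrix(as.numeric(grid$x > 0), res, res, byrow = TRUE)
  ap <- new("ApertureSequence", frames = array(half, dim = c(1, res, res)),
            gridX = grid$x, gridY = grid$y, frameDuration = 2)
  sg <- 3
  # pixels with center x > 0 cover the area from x = dx/2 on
  dx <- mean(diff(grid$x))
  expectOverlap <- stats::pnorm(dx / 2 / sg, lower.tail = FALSE)
  r <- predictNeural(prfParams(0, 0, sg, 0.5), ap)
  expect_equal(r, expectOverlap^0.5, tolerance = 2e-3)
  # exact half the mass -> 0.5^0.5 in the continuum limit
  expect_lt(abs(r - 0.5^0.5), 0.06)
})

test_that("monotonicity in overlap and in the exponent", {
  grid <- apertureGrid(fixtureAperture)
  sg <- 4
  overlaps <- predictNeural(prfParams(0, 0, sg, 1), fixtureAperture)
  sub <- overlaps[overlaps > 0 & overlaps < 1]
  # for overlap < 1 the response is non-increasing in n
  r25 <- sub^0.25; r5 <- sub^0.5; r1 <- sub
  expect_true(all(r25 >= r5 & r5 >= r1))
  # and non-decreasing in overlap for fixed n
  ord <- order(sub)
  expect_true(all(diff(sub[ord]^0.5) >= 0))
})

test_that("canonical HRF peaks near 5 s with truncated support and positive integral", {
  h <- canonicalHRF(dt = 1)
  peakT <- (which.max(h@samples) - 1) * h@dt
  expect_true(abs(peakT - 5) <= 1)
  expect_equal(max(h@samples), 1)
  expect_gt(sum(h@samples) * h@dt, 0)
  expect_lte(length(h@samples) * h@dt, 33)
  expect_error(canonicalHRF(dt = 0))
})

test_that("predicted BOLD matches a direct O(T^2) convolution oracle", {
  p <- prfParams(4, -2, 3, 0.5, gain = 1.7)
  pred <- predictBold(p, fixtureAperture, fixtureHRF, fixtureTR)

  # independent oracle: upsample, convolve by explicit summation, resample
  r <- predictNeural(p, fixtureAperture)
  dt <- fixtureHRF@dt
  dense <- rep(r, each = round(fixtureAperture@frameDuration / dt))
  k <- fixtureHRF@samples
  conv <- numeric(length(dense))
  for (t in seq_along(dense))
    for (j in seq_along(k))
      if (t - j + 1 >= 1) conv[t] <- conv[t] + dense[t - j + 1] * k[j]
  oracle <- 1.7 * conv[seq(1, length(conv), by = round(fixtureTR / dt))]
  expect_equal(pred, oracle, tolerance = 1e-10)
})

test_that("BOLD prediction scales with gain and is zero for a blank stimulus", {
  p1 <- prfParams(0, 5, 3, 0.5, gain = 1)
  p2 <- prfParams(0, 5, 3, 0.5, gain = 2)
  b1 <- predictBold(p1, fixtureAperture, fixtureHRF, fixtureTR)
  b2 <- predictBold(p2, fixtureAperture, fixtureHRF, fixtureTR)
  expect_equal(b2, 2 * b1)

  res <- length(fixtureAperture@gridX)
  blank <- new("ApertureSequence", frames = array(0, dim = c(10, res, res)),
               gridX = fixtureAperture@gridX, gridY = fixtureAperture@gridY,
               frameDuration = 2)
  expect_equal(predictBold(p1, blank, fixtureHRF, 2), rep(0, 10))
  expect_error(predictBold(p1, fixtureAperture, canonicalHRF(dt = 0.75), 2),
               "divide")
})

test_that("derived metrics follow the size and polar conventions", {
  m <- derivedMetrics(prfParams(c(3, 0, 1), c(4, 1, 0),
                                sigma = c(2, 2, 3), n = c(0.25, 1, 1)))
  expect_equal(m$ecc, c(5, 1, 1))
  expect_equal(m$size, c(4, 2, 3))
  expect_equal(m$phase[2], pi / 2)
  expect_equal(m$phase[3], 0)
  # size decreasing in n, equal to sigma at n = 1
  sizes <- derivedMetrics(prfParams(0, 0, 2, c(0.2, 0.5, 1)))$size
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[3], 2)
})
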