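test_that("length filtering is inclusive at both bounds and idempotent", {
  con <- makeConnectome(c(3, 4, 100, 200, 201))
  kept <- filterStreamlines(con)
  expect_equal(nStreamlines(kept), 3)
  expect_equal(sort(streamlineLengths(kept)), c(4, 100, 200))

  again <- filterStreamlines(kept)
  expect_identical(kept@points, again@points)

  allIn <- makeConnectome(c(10, 20))
  expect_equal(nStreamlines(filterStreamlines(allIn)), 2)
  expect_equal(nStreamlines(filterStreamlines(synthStreamlines(0))), 0)
  expect_error(filterStreamlines(con, minLen = 10, maxLen = 5), "exceed")
})

test_that("ensemble concatenation preserves every streamline and provenance", {
  cands <- lapply(1:3, function(k)
    synthStreamlines(10 * k, lengthMean = 15, lengthSd = 2, seed = k))
  ens <- concatenateEnsemble(cands)
  expect_equal(nStreamlines(ens), 10 + 20 + 30)
  expect_equal(as.vector(table(ens@metadata$candidate)), c(10, 20, 30))

  # duplicates retained: multiset semantics
  dup <- concatenateEnsemble(list(cands[[1]], cands[[1]]))
  expect_equal(nStreamlines(dup), 20)
  expect_identical(dup@points[1:nrow(cands[[1]]@points), ],
                   cands[[1]]@points)
  expect_equal(nStreamlines(concatenateEnsemble(list())), 0)
})

test_that("the validation stub passes through or applies the predicate", {
  con <- makeConnectome(c(10, 20, 30))
  expect_identical(cullConnectome(con)@points, con@points)
  culled <- cullConnectome(con, function(c) streamlineLengths(c) > 15)
  expect_equal(nStreamlines(culled), 2)
})

test_that("ROI intersection matches an exhaustive endpoint-distance oracle", {
  surf <- synthEVCSurface(2500, seed = 51)
  roi <- makeDiskROI(c(10, 10, 0), 4, surf, label = "fROI")
  evc <- makeDiskROI(c(40, 25, 0), 6, surf, label = "EVC")

  # 10 hand-placed two-point streamlines
  starts <- rbind(c(10, 10, 0), c(11, 10, 0.5), c(10, 10, 0), c(300, 300, 0),
                  c(40, 25, 0), c(10, 10, 0), c(39, 24, 1), c(10, 14, 0),
                  c(200, 0, 0), c(10, 10, 10))
  ends <- rbind(c(40, 25, 0), c(40, 26, 0), c(100, 100, 0), c(40, 25, 0),
                c(10, 10, 0), c(12, 12, 0), c(10, 11, 0), c(41, 25, 0),
                c(220, 0, 0), c(40, 25, 0))
  pts <- do.call(rbind, lapply(1:10, function(i) rbind(starts[i, ], ends[i, ])))
  con <- new("Connectome", points = pts, counts = rep(2L, 10),
             metadata = list())

  got <- intersectROI(con, roi, surf, evc = evc, captureDist = 2)

  rv <- surfaceVertices(surf)[roi@vertexIndices, , drop = FALSE]
  ev <- surfaceVertices(surf)[evc@vertexIndices, , drop = FALSE]
  near <- function(p, verts, eps = 2)
    min(sqrt(colSums((t(verts) - p)^2))) <= eps
  oracle <- vapply(1:10, function(i) {
    (near(starts[i, ], rv) && near(ends[i, ], ev)) ||
      (near(ends[i, ], rv) && near(starts[i, ], ev))
  }, logical(1))
  expect_equal(nStreamlines(got), sum(oracle))

  # single-ROI mode keeps anything touching the ROI; endpoint exactly on a
  # vertex is included, both-ends-outside is excluded
  single <- intersectROI(con, roi, surf, captureDist = 2)
  oracle1 <- vapply(1:10, function(i)
    near(starts[i, ], rv) || near(ends[i, ], rv), logical(1))
  expect_equal(nStreamlines(single), sum(oracle1))
  expect_true(oracle[1])                       # on-vertex endpoints captured
  expect_false(oracle1[9])                     # far-away streamline excluded
})

test_that("fWMT percentage is a guarded ratio", {
  expect_equal(fwmtPercentage(12, 3), 25)
  expect_equal(fwmtPercentage(10, 10), 100)
  expect_equal(fwmtPercentage(10, 0), 0)
  expect_true(is.na(fwmtPercentage(0, 0)))
  expect_error(fwmtPercentage(3, 5))
})

test_that("endpoint eccentricity assignment matches a nearest-neighbor oracle", {
  surf <- synthEVCSurface(1000, seed = 52)
  v <- surfaceVertices(surf)
  set.seed(53)
  q <- v[sample(nrow(v), 30), ] + matrix(runif(90, -0.4, 0.4), 30)
  q <- rbind(q, c(1e5, 1e5, 0))                # unreachable endpoint
  rec <- assignEndpointEccentricity(q, surf, maxDist = 2)
  expect_equal(attr(rec, "nDropped"), 1)
  expect_equal(nrow(rec), 30)
  for (i in 1:30) {
    d <- sqrt(colSums((t(v) - q[i, ])^2))
    expect_equal(rec$eccentricity[i], surfaceEccentricity(surf)[which.min(d)])
  }
  # coincident endpoint inherits the vertex value exactly
  rec1 <- assignEndpointEccentricity(v[7, , drop = FALSE], surf)
  expect_identical(rec1$eccentricity, surfaceEccentricity(surf)[7])
})

test_that("endpoint band proportions are TDI-weighted and scale-invariant", {
  rec <- data.frame(x = 0, y = 0, z = 0, eccentricity = c(3, 15),
                    tdiWeight = c(3, 1))
  pr <- endpointBandProportions(rec)
  expect_equal(pr$fractions, c(0.75, 0, 0.25, 0))
  scaled <- rec; scaled$tdiWeight <- rec$tdiWeight * 17
  expect_equal(endpointBandProportions(scaled)$fractions, pr$fractions)
  unw <- endpointBandProportions(rec, weighted = FALSE)
  expect_equal(unw$fractions, c(0.5, 0, 0.5, 0))

  same <- data.frame(x = 0, y = 0, z = 0, eccentricity = rep(3, 5),
                     tdiWeight = 1)
  expect_equal(endpointBandProportions(same)$fractions, c(1, 0, 0, 0))
  expect_error(endpointBandProportions(same[0, ]), "no endpoint")
})

test_that("disk ROIs capture the expected vertex neighborhoods", {
  surf <- synthEVCSurface(2500, seed = 54)   # 50 x 50 sheet, 1 mm spacing
  disk <- makeDiskROI(c(25, 25, 0), 5, surf)
  expect_lt(abs(length(disk@vertexIndices) - pi * 25), 8)
  whole <- makeDiskROI(c(25, 25, 0), 100, surf)
  expect_equal(length(whole@vertexIndices), 2500)
  expect_error(makeDiskROI(c(25.5, 25.5, 0), 0.2, surf), "captures no")
})

test_that("foveally-weighted endpoint generators beat uniform ones in band 1", {
  surf <- synthEVCSurface(2500, seed = 55)
  fov <- synthEndpoints(c(0.5, 0.25, 0.15, 0.1), 2000, surf,
                        weightDispersion = 0.5, seed = 56)
  uni <- synthEndpoints(rep(0.25, 4), 2000, surf,
                        weightDispersion = 0.5, seed = 57)
  expect_gt(endpointBandProportions(fov)$fractions[1],
            endpointBandProportions(uni)$fractions[1])
})
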