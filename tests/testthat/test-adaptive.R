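test_that("the empirical k model evaluates its piecewise branches", {
  expect_equal(estimateK(100)[c("kLow", "kHigh")], list(kLow = 2L, kHigh = 5L))
  expect_equal(estimateK(1000)[c("kLow", "kHigh")],
               list(kLow = 20L, kHigh = 50L))
  # continuity at the knot: the log branch gives the same range at n = 1000
  expect_equal(ceiling(log2(1000) + 10), 20)
  expect_equal(5 * ceiling(log2(1000)), 50)
  expect_error(estimateK(99), "n >= 100")
})

test_that("the k bounds are non-decreasing in n", {
  ns <- c(100, 250, 500, 1000, 5000, 2e4, 1e6)
  lows <- vapply(ns, function(n) estimateK(n)$kLow, integer(1))
  highs <- vapply(ns, function(n) estimateK(n)$kHigh, integer(1))
  expect_true(all(diff(lows) >= 0))
  expect_true(all(diff(highs) >= 0))
  expect_true(all(lows <= highs))
})

test_that("tiny triangulations have the expected structure", {
  tri3 <- buildTin(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(nrow(tinTriangles(tri3)), 1)
  expect_equal(nrow(tinEdges(tri3)), 3)
  # handshake: sum of degrees = 2E
  expect_equal(length(as.vector(tinEdges(tri3))), 2 * 3)

  sq <- buildTin(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(tinTriangles(sq)), 2)
  expect_equal(nrow(tinEdges(sq)), 5)
  expect_equal(sum(tabulate(as.vector(tinTriangles(sq)))), 2 * 3)
})

test_that("collinear input is rejected", {
  expect_error(buildTin(cbind(1:5, 2 * (1:5) + 1)), "collinear|degenerate")
})

test_that("random triangulations satisfy the 2D Euler identity", {
  set.seed(43)
  x <- matrix(runif(400), ncol = 2)
  tin <- buildTin(x)
  V <- length(tin@vertices)
  E <- nrow(tinEdges(tin))
  F <- nrow(tinTriangles(tin))
  expect_equal(V + F - E, 1)
})

test_that("Delaunay triangles match the scipy oracle", {
  set.seed(47)
  x <- matrix(rnorm(300), ncol = 2)
  tin <- buildTin(x)
  oracle <- pyOracle(c(
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    sprintf("x = np.loadtxt('%s', delimiter=',')", writeTempCsv(x)),
    "t = Delaunay(x)",
    "for s in t.simplices: print(','.join(map(str, sorted(s + 1))))"
  ))
  expect_setequal(facetKey(tinTriangles(tin)), oracle)
})

test_that("cross-cluster triangles are flagged by the mutual-KNN rule", {
  # three tight triads at distant corners; k = 2 keeps KNNs within a triad
  corners <- rbind(c(0, 0), c(40, 0), c(20, 35))
  pts <- do.call(rbind, lapply(1:3, function(c_) {
    sweep(rbind(c(0, 0), c(1, 0), c(0.5, 1)), 2, corners[c_, ], "+")
  }))
  g <- buildKnn(pts, k = 2)
  tin <- flagCrossTriangles(buildTin(pts), g)
  tri <- tinTriangles(tin)
  triad <- matrix(rep(1:3, each = 3), ncol = 1)[tri]
  dim(triad) <- dim(tri)
  within <- triad[, 1] == triad[, 2] & triad[, 2] == triad[, 3]
  # within-triad triangles score 6 (full mutual proximity): never flagged
  expect_false(any(crossFlags(tin)[within]))
  # triangles spanning triads score 0: always flagged
  expect_true(all(crossFlags(tin)[!within]))
})

test_that("boundary count follows B = 2V - F - 2C with clamping", {
  tri <- buildTin(rbind(c(0, 0), c(1, 0), c(0, 1)))
  # raw arithmetic gives 2*3-1-2 = 3 = V (all vertices on the boundary);
  # the estimate keeps at least one internal point, so it clamps to V-1
  expect_warning(B3 <- estimateBoundaryCount(tri), "clamped")
  expect_equal(B3, 2L)
  # square: raw 2*4-2-2 = 4 counts all four corners, again clamped to V-1
  sq <- buildTin(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_warning(B4 <- estimateBoundaryCount(sq), "clamped")
  expect_equal(B4, 3L)
  expect_warning(estimateBoundaryCount(tri, C = 5), "clamped")
  # a configuration with genuine interior points needs no clamping
  hex <- rbind(c(0, 0), 2 * cbind(cos(2 * pi * (0:5) / 6),
                                  sin(2 * pi * (0:5) / 6)))
  expect_equal(estimateBoundaryCount(buildTin(hex)), 6L) # 2*7-6-2
})

test_that("2V - F - 2 counts the hull vertices of an unflagged TIN", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(30:150, 1)
    x <- matrix(runif(2 * n), ncol = 2)
    tin <- buildTin(x)
    B <- 2 * length(tin@vertices) - nrow(tinTriangles(tin)) - 2
    expect_equal(B, length(grDevices::chull(x)))
  }
})

test_that("threshold estimation picks the B-th largest DCM", {
  ds <- genBlobs(300, centers = rbind(c(0, 0), c(14, 0)), sigmas = 1,
                 seed = 14)
  x <- pointCoords(ds)
  g <- buildKnn(x, k = 10)
  dcm <- computeDcmField(x, g)
  est <- estimateTdcm(x, g, dcm, C = 2)
  expect_equal(est$tdcm, sort(dcm, decreasing = TRUE)[est$B])
  expect_equal(est$ratio, 1 - est$B / nrow(x))
  # the estimated boundary count is near the count of hull-adjacent points
  hullish <- sum(dcm >= sort(dcm, decreasing = TRUE)[est$B])
  expect_gte(hullish, est$B)
  # clustering at the estimated threshold recovers both blobs
  part <- cdcCluster(x, k = 10, threshold = est$tdcm)
  expect_equal(ariScore(trueLabels(ds), clusterLabels(part)), 1)
})

test_that("threshold estimation refuses non-2D input", {
  x <- matrix(rnorm(300), ncol = 3)
  g <- buildKnn(x, k = 5)
  expect_error(estimateTdcm(x, g, runif(100)), "2D only")
})
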