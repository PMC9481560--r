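test_that("threshold division classifies boundary as DCM >= T", {
  div <- dividePoints(c(0.9, 0.5, 0.1, 0.05), threshold = 0.4)
  expect_equal(div$role, c("boundary", "boundary", "internal", "internal"))
  expect_equal(div$thresholdUsed, 0.4)
  # ties go to the boundary
  expect_equal(dividePoints(c(0.4, 0.1), threshold = 0.4)$role[1], "boundary")
})

test_that("ratio division selects the descending-rank threshold", {
  set.seed(3)
  dcm <- runif(10)
  div <- dividePoints(dcm, ratio = 0.7) # rank round(10*0.3) = 3
  expect_equal(div$thresholdUsed, sort(dcm, decreasing = TRUE)[3])
  expect_gte(sum(div$role == "boundary"), 3)

  dcm100 <- runif(100)
  div99 <- dividePoints(dcm100, ratio = 0.99) # rank 1: the single largest
  expect_equal(div99$thresholdUsed, max(dcm100))
  expect_equal(sum(div99$role == "boundary"), 1)
})

test_that("degenerate divisions error or warn as appropriate", {
  expect_error(dividePoints(c(0.5, 0.6), threshold = 0.1), "all points")
  expect_warning(dividePoints(c(0.5, 0.6), threshold = 0.9), "no boundary")
  expect_error(dividePoints(c(0.5, 0.6)), "exactly one")
  expect_error(dividePoints(c(0.5, 0.6), threshold = 0.5, ratio = 0.5),
               "exactly one")
})

test_that("reachable distances equal the minimum to the boundary set", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  role <- c("internal", "boundary", "boundary")
  expect_equal(reachableDistances(pts, role), c(3, NA, NA))

  pts2 <- rbind(c(1, 1), c(1, 1), c(9, 9))
  expect_equal(reachableDistances(pts2, c("internal", "boundary", "boundary"))[1],
               0)
})

test_that("reachable distances match the brute-force oracle", {
  set.seed(19)
  x <- matrix(runif(600, -10, 10), ncol = 2)
  role <- ifelse(runif(300) < 0.3, "boundary", "internal")
  reach <- reachableDistances(x, role)
  bnd <- x[role == "boundary", , drop = FALSE]
  for (i in which(role == "internal")) {
    expect_equal(reach[i],
                 min(sqrt(rowSums((bnd - matrix(x[i, ], nrow(bnd), 2,
                                                byrow = TRUE))^2))),
                 tolerance = 1e-12)
  }
})

test_that("the association rule joins internal points by r_i + r_j", {
  # separation 1.5 well within r_i + r_j: joined
  pts <- rbind(c(0, 0), c(1.5, 0), c(0.4, 3), c(1.1, -3))
  role <- c("internal", "internal", "boundary", "boundary")
  reach <- reachableDistances(pts, role)
  lab <- connectInternal(pts, role, reach)
  expect_equal(lab[1], lab[2])

  # r1 + r2 = 0.5 + 0.6 < 1.5: separate clusters
  pts2 <- rbind(c(0, 0), c(1.5, 0), c(0, 0.5), c(1.5, 0.6))
  role2 <- c("internal", "internal", "boundary", "boundary")
  reach2 <- reachableDistances(pts2, role2)
  lab2 <- connectInternal(pts2, role2, reach2)
  expect_equal(lab2[1], 1L)
  expect_equal(lab2[2], 2L)
})

test_that("internal connection equals the brute-force transitive closure", {
  set.seed(29)
  x <- matrix(runif(500, 0, 10), ncol = 2)
  role <- ifelse(runif(250) < 0.4, "boundary", "internal")
  reach <- reachableDistances(x, role)
  lab <- connectInternal(x, role, reach)
  intIdx <- which(role == "internal")
  oracle <- bruteConnect(x[intIdx, , drop = FALSE], reach[intIdx])
  expect_true(sameGrouping(lab[intIdx], oracle))
  # component ids follow the smallest member index
  expect_equal(lab[intIdx][1], 1L)
})

test_that("boundary points adopt the nearest internal label, ties by index", {
  pts <- rbind(c(0, 0), c(1, 0), c(3, 0))
  role <- c("boundary", "internal", "internal")
  lab <- assignBoundary(pts, role, c(NA, 1L, 2L))
  expect_equal(lab[1], 1L)

  ptsTie <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  roleTie <- c("boundary", "internal", "internal")
  labTie <- assignBoundary(ptsTie, roleTie, c(NA, 1L, 2L))
  expect_equal(labTie[1], 1L) # equidistant: smaller internal index wins
})

test_that("well-separated blobs are recovered exactly", {
  ds <- genBlobs(400, centers = rbind(c(0, 0), c(10, 0)), sigmas = 1,
                 seed = 2)
  part <- cdcCluster(pointCoords(ds), k = 10, ratio = 0.9)
  expect_equal(nClusters(part), 2)
  expect_equal(ariScore(trueLabels(ds), clusterLabels(part)), 1)
})

test_that("a ring enclosing an island blob is separated", {
  ds <- genRingIsland(nRing = 600, nCore = 200, radius = 5, width = 0.3,
                      coreSigma = 0.4, seed = 4)
  part <- cdcCluster(pointCoords(ds), k = 20, ratio = 0.85)
  expect_equal(nClusters(part), 2)
  expect_gte(ariScore(trueLabels(ds), clusterLabels(part)), 0.95)
})

test_that("an all-internal run yields a single cluster", {
  set.seed(37)
  x <- matrix(rnorm(200), ncol = 2)
  suppressWarnings({
    div <- dividePoints(rep(0.01, 100), threshold = 0.99)
  })
  reach <- reachableDistances(x, div$role)
  expect_true(all(is.infinite(reach)))
  lab <- assignBoundary(x, div$role, connectInternal(x, div$role, reach))
  expect_true(all(lab == 1L))
})

test_that("every point gets exactly one label and ids are contiguous", {
  ds <- genBlobs(300, centers = rbind(c(0, 0), c(8, 0), c(0, 8)),
                 sigmas = c(0.5, 1, 0.8), seed = 6)
  part <- cdcCluster(pointCoords(ds), k = 8, ratio = 0.85)
  lab <- clusterLabels(part)
  expect_false(anyNA(lab))
  expect_setequal(unique(lab), seq_len(nClusters(part)))
})

test_that("the boundary cage blocks cross-blob connections", {
  ds <- genBlobs(300, centers = rbind(c(0, 0), c(10, 0)), sigmas = 1,
                 seed = 8)
  x <- pointCoords(ds)
  truth <- trueLabels(ds)
  # mark each blob's hull points as the boundary, everything else internal
  role <- rep("internal", nrow(x))
  for (b in 1:2) {
    idx <- which(truth == b)
    role[idx[grDevices::chull(x[idx, ])]] <- "boundary"
  }
  reach <- reachableDistances(x, role)
  intIdx <- which(role == "internal")
  P <- x[intIdx, ]
  D <- as.matrix(dist(P))
  joined <- D <= outer(reach[intIdx], reach[intIdx], "+")
  cross <- outer(truth[intIdx], truth[intIdx], "!=")
  expect_false(any(joined & cross))
})

test_that("the partition is invariant to point permutation", {
  ds <- genBlobs(250, centers = rbind(c(0, 0), c(9, 0), c(4, 8)),
                 sigmas = c(0.6, 1.1, 0.8), seed = 12)
  x <- pointCoords(ds)
  part <- cdcCluster(x, k = 10, ratio = 0.88)
  set.seed(99)
  perm <- sample(nrow(x))
  partP <- cdcCluster(x[perm, ], k = 10, ratio = 0.88)
  expect_true(sameGrouping(clusterLabels(part)[perm], clusterLabels(partP)))
  expect_equal(thresholdUsed(partP), thresholdUsed(part))
})
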