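test_that("2D DCM attains its analytic extrema and hand-computed values", {
  expect_identical(dcm2d(rep(pi / 2, 4)), 0)
  expect_identical(dcm2d(c(2 * pi, 0, 0, 0)), 1)
  expect_identical(dcm2d(c(2 * pi, rep(0, 9))), 1)
  expect_equal(dcm2d(c(pi, pi / 2, pi / 2)), 1 / 16)
  expect_error(dcm2d(2 * pi), "at least 2")
  expect_error(dcm2d(c(1, 1)), "sum to 2\\*pi")
})

test_that("neighbour directions are mapped to deduplicated unit vectors", {
  x <- rbind(c(0, 0), c(2, 0), c(5, 0), c(0, 3), c(1, 1))
  g <- buildKnn(x, k = 4)
  dirs <- mapToUnitSphere(x, g, 1)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) < 1e-12))
  # (2,0) and (5,0) collapse to the same +x direction
  expect_equal(nrow(dirs), 3)
})

test_that("unit-sphere surface area matches closed forms", {
  expect_equal(sphereArea(2), 2 * pi)
  expect_equal(sphereArea(3), 4 * pi)
  expect_equal(sphereArea(4), 2 * pi^2)
})

test_that("simplex volumes match hand calculations and detect degeneracy", {
  expect_equal(simplexVolume(rbind(c(1, 0), c(0, 1))), sqrt(2))
  expect_equal(simplexVolume(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               sqrt(3) / 2)
  expect_identical(simplexVolume(rbind(c(1, 2, 3), c(1, 2, 3), c(0, 0, 1))),
                   0)
})

test_that("Gram-determinant volumes agree with the Cayley-Menger oracle", {
  set.seed(23)
  for (d in 2:5) {
    for (rep in 1:50) {
      V <- matrix(rnorm(d * d), d, d)
      expect_equal(simplexVolume(V), cayleyMengerVolume(V), tolerance = 1e-9)
    }
  }
})

test_that("the 2D convex complex is the azimuth-adjacent chord cycle", {
  dirs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  cc <- buildConvexComplex(dirs)
  expect_equal(nrow(cc@simplices), 4)
  expect_setequal(facetKey(cc@simplices), c("1,2", "2,3", "3,4", "1,4"))
  expect_equal(simplexVolumes(cc), rep(sqrt(2), 4))
})

test_that("the 3D complex of a regular tetrahedron has 4 triangular facets", {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  cc <- buildConvexComplex(dirs)
  expect_equal(nrow(cc@simplices), 4)
  expect_setequal(facetKey(cc@simplices), c("1,2,3", "1,2,4", "1,3,4", "2,3,4"))
})

test_that("hull facets match an independent construction and Euler's formula", {
  set.seed(5)
  dirs <- randomDirections(20, 3)
  cc <- buildConvexComplex(dirs)
  f <- cc@simplices
  V <- length(unique(as.vector(f)))
  E <- nrow(unique(t(apply(rbind(f[, 1:2], f[, c(1, 3)], f[, 2:3]), 1, sort))))
  expect_equal(V - E + nrow(f), 2) # Euler characteristic of the 2-sphere

  oracle <- pyOracle(c(
    "import numpy as np",
    "from scipy.spatial import ConvexHull",
    sprintf("x = np.loadtxt('%s', delimiter=',')", writeTempCsv(dirs)),
    "h = ConvexHull(x)",
    "for s in h.simplices: print(','.join(map(str, sorted(s + 1))))"
  ))
  expect_setequal(facetKey(f), oracle)
})

test_that("degenerate direction sets are refused", {
  # fewer than d+1 directions
  expect_error(buildConvexComplex(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               class = "cdcDegenerate")
  # directions confined to a plane in 3D
  planar <- cbind(randomDirections(10, 2), 0)
  expect_error(buildConvexComplex(planar), class = "cdcDegenerate")
})

test_that("unit-volume allocation conserves the sphere area and the ranking", {
  cc <- new("ConvexComplex",
            directions = diag(2), simplices = rbind(1:2, 2:1),
            simplexVolumes = c(1, 2), unitVolumes = numeric(0),
            sphereArea = 4)
  out <- allocateUnitVolumes(cc)
  expect_equal(unitVolumes(out), c(1.5, 2.5))

  set.seed(31)
  for (d in 2:4) {
    cc <- allocateUnitVolumes(buildConvexComplex(randomDirections(4 * d, d)))
    expect_equal(sum(unitVolumes(cc)), sphereArea(d), tolerance = 1e-9)
    expect_identical(order(unitVolumes(cc)), order(simplexVolumes(cc)))
  }
})

test_that("high-d DCM attains its extrema on constructed unit volumes", {
  mk <- function(u, S) {
    f <- length(u)
    new("ConvexComplex", directions = diag(2),
        simplices = cbind(seq_len(f), c(seq_len(f)[-1], 1L)),
        simplexVolumes = u, unitVolumes = u, sphereArea = S)
  }
  expect_equal(dcmHighd(mk(rep(pi / 2, 4), 2 * pi)), 0)
  expect_equal(dcmHighd(mk(c(2 * pi, 0, 0, 0), 2 * pi)), 1)
})

test_that("arc-length unit volumes reduce the high-d DCM to the 2D formula", {
  set.seed(41)
  for (rep in 1:500) {
    k <- sample(3:20, 1)
    ang <- diff(c(0, sort(runif(k - 1, 0, 2 * pi)), 2 * pi))
    cc <- new("ConvexComplex", directions = diag(2),
              simplices = cbind(seq_len(k), c(seq_len(k)[-1], 1L)),
              simplexVolumes = ang, unitVolumes = ang,
              sphereArea = 2 * pi)
    expect_equal(dcmHighd(cc), dcm2d(ang), tolerance = 1e-9)
  }
})

test_that("DCM field ranks interior grid points below corners", {
  grid <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  g <- buildKnn(grid, k = 8)
  dcm <- computeDcmField(grid, g)
  corner <- which(grid[, 1] == 1 & grid[, 2] == 1)
  interior <- which(grid[, 1] %in% 3:4 & grid[, 2] %in% 3:4)
  expect_lt(max(dcm[interior]), dcm[corner])
})

test_that("hull-vertex points of a blob score higher DCM than central points", {
  set.seed(13)
  x <- matrix(rnorm(1000), ncol = 2)
  g <- buildKnn(x, k = 20)
  dcm <- computeDcmField(x, g)
  hull <- grDevices::chull(x)
  centre <- order(rowSums(x^2))[1:50] # innermost 10%
  expect_gt(mean(dcm[hull]), mean(dcm[centre]))
})

test_that("collinear 2D neighbourhoods yield the maximal DCM", {
  x <- rbind(c(0, 0), c(1, 0), c(2, 0), c(5, 8), c(6, 9))
  g <- buildKnn(x, k = 2)
  dcm <- computeDcmField(x, g)
  expect_equal(dcm[1], 1) # both neighbours in one direction: one angle 2*pi
})

test_that("DCM values stay in [0,1] and are invariant to rescaling", {
  set.seed(17)
  x <- matrix(rnorm(600), ncol = 3)
  g <- buildKnn(x, k = 12)
  dcm <- computeDcmField(x, g)
  expect_true(all(dcm >= 0 & dcm <= 1))
  gs <- buildKnn(7.3 * x, k = 12)
  expect_equal(computeDcmField(7.3 * x, gs), dcm, tolerance = 1e-9)
})

test_that("degenerate high-d neighbourhoods receive DCM 1", {
  # 3D points confined to a plane: directions cannot span the space
  x <- cbind(matrix(rnorm(60), ncol = 2), 0)
  g <- buildKnn(x, k = 5)
  dcm <- computeDcmField(x, g, mode = "highd")
  expect_true(all(dcm == 1))
})
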