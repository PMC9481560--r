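# Seeded generators emulating the benchmark regimes the clustering method
# targets: Gaussian blobs of heterogeneous size and density (including
# weakly-connected pairs), a ring enclosing an island blob, elongated
# spindles, and uniform background noise. All randomness flows through an
# explicit seed and leaves the caller's RNG state untouched.

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

newSynthetic <- function(coords, labels, recipe) {
  new("SyntheticDataset",
      coords = coords,
      labels = as.integer(labels),
      recipe = recipe)
}

#' Gaussian blob mixtures with heterogeneous density
#'
#' Isotropic Gaussian clusters at the given centres. Unequal
#' \code{sigmas} and \code{weights} produce the heterogeneous-density
#' regime; placing two centres 2-3 sigma apart (with \code{truncate} set
#' so the blobs remain compact) produces the weak-connectivity regime of
#' nearly-touching clusters.
#'
#' Point counts per blob are deterministic (proportional allocation with
#' largest-remainder rounding) so the density ratio of the recipe is
#' exact.
#'
#' @param n total number of points.
#' @param centers C x d matrix of blob centres.
#' @param sigmas per-blob standard deviation (recycled).
#' @param weights per-blob sampling weights (default equal).
#' @param truncate optional radius cap in units of sigma; samples beyond
#'   it are redrawn, yielding compact blobs. NULL (default) leaves the
#'   Gaussians untruncated.
#' @param seed integer seed; same seed, same dataset, bit for bit.
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- genBlobs(400, centers = rbind(c(0, 0), c(10, 0)),
#'                sigmas = c(1, 0.3), weights = c(0.7, 0.3), seed = 7)
#' table(trueLabels(ds))
#' @export
genBlobs <- function(n, centers, sigmas = 1, weights = NULL,
                     truncate = NULL, seed = 1) {
  centers <- as.matrix(centers)
  C <- nrow(centers)
  d <- ncol(centers)
  sigmas <- rep_len(sigmas, C)
  if (is.null(weights)) weights <- rep(1, C)
  weights <- weights / sum(weights)
  counts <- floor(n * weights)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * weights - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  withLocalSeed(seed, {
    coords <- matrix(0, n, d)
    labels <- integer(n)
    at <- 0
    for (c_ in seq_len(C)) {
      m <- counts[c_]
      if (m == 0) next
      pts <- matrix(rnorm(m * d, sd = sigmas[c_]), m, d)
      if (!is.null(truncate)) {
        lim <- truncate * sigmas[c_]
        bad <- which(sqrt(rowSums(pts^2)) > lim)
        while (length(bad) > 0) {
          pts[bad, ] <- matrix(rnorm(length(bad) * d, sd = sigmas[c_]),
                               length(bad), d)
          bad <- bad[sqrt(rowSums(pts[bad, , drop = FALSE]^2)) > lim]
        }
      }
      coords[at + seq_len(m), ] <- sweep(pts, 2, centers[c_, ], "+")
      labels[at + seq_len(m)] <- c_
      at <- at + m
    }
    newSynthetic(coords, labels,
                 list(generator = "blobs", n = n, centers = centers,
                      sigmas = sigmas, weights = weights,
                      truncate = truncate, seed = seed))
  })
}

#' Ring enclosing an island blob
#'
#' A circular ring cluster (uniform in angle, Gaussian radial scatter
#' truncated at 3 widths) surrounding a central Gaussian blob: the
#' island regime, in which the enclosing and enclosed clusters share the
#' same region of space and density-based methods tend to merge them.
#'
#' @param nRing points on the ring (label 1).
#' @param nCore points in the central blob (label 2).
#' @param radius ring radius.
#' @param width radial standard deviation of the ring (samples truncated
#'   to +/- 3 widths).
#' @param coreSigma standard deviation of the central blob.
#' @param center 2-vector, centre of the structure.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class] with exactly two classes.
#' @export
genRingIsland <- function(nRing = 600, nCore = 200, radius = 5,
                          width = 0.3, coreSigma = 0.4, center = c(0, 0),
                          seed = 1) {
  withLocalSeed(seed, {
    theta <- runif(nRing, 0, 2 * pi)
    dr <- rnorm(nRing, sd = width)
    bad <- which(abs(dr) > 3 * width)
    while (length(bad) > 0) {
      dr[bad] <- rnorm(length(bad), sd = width)
      bad <- bad[abs(dr[bad]) > 3 * width]
    }
    r <- radius + dr
    ring <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
    core <- cbind(center[1] + rnorm(nCore, sd = coreSigma),
                  center[2] + rnorm(nCore, sd = coreSigma))
    newSynthetic(rbind(ring, core), rep(1:2, c(nRing, nCore)),
                 list(generator = "ringIsland", nRing = nRing,
                      nCore = nCore, radius = radius, width = width,
                      coreSigma = coreSigma, center = center, seed = seed))
  })
}

#' Elongated spindle-shaped clusters
#'
#' Anisotropic Gaussian clusters with a long major axis, rotated to the
#' given orientations: the spindle regime whose sparse tips are easily
#' misread as noise by density-based filters.
#'
#' @param nPer points per spindle (recycled).
#' @param centers C x 2 matrix of spindle centres.
#' @param lengths major-axis standard deviation per spindle (recycled).
#' @param widths minor-axis standard deviation per spindle (recycled).
#' @param angles orientation of each major axis in radians (recycled).
#' @param seed integer seed.
#' @return a [SyntheticDataset-class].
#' @export
genSpindles <- function(nPer = 150, centers, lengths = 3, widths = 0.4,
                        angles = 0, seed = 1) {
  centers <- as.matrix(centers)
  C <- nrow(centers)
  if (ncol(centers) != 2) stop("spindles are generated in 2D")
  nPer <- rep_len(nPer, C)
  lengths <- rep_len(lengths, C)
  widths <- rep_len(widths, C)
  angles <- rep_len(angles, C)
  withLocalSeed(seed, {
    coords <- NULL
    labels <- integer(0)
    for (c_ in seq_len(C)) {
      m <- nPer[c_]
      raw <- cbind(rnorm(m, sd = lengths[c_]), rnorm(m, sd = widths[c_]))
      a <- angles[c_]
      rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      coords <- rbind(coords, sweep(raw %*% t(rot), 2, centers[c_, ], "+"))
      labels <- c(labels, rep(c_, m))
    }
    newSynthetic(coords, labels,
                 list(generator = "spindles", nPer = nPer,
                      centers = centers, lengths = lengths,
                      widths = widths, angles = angles, seed = seed))
  })
}

#' Overlay uniform background noise on a dataset
#'
#' Appends \code{nNoise} points drawn uniformly over a bounding box
#' (default: the dataset's own bounding box) and labels them -1. The
#' original coordinates are preserved exactly.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param nNoise number of noise points to add.
#' @param bbox numeric of length 2*d, (min_1, max_1, min_2, max_2, ...);
#'   default the data bounding box.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class] with the noise appended.
#' @export
genNoiseOverlay <- function(dataset, nNoise, bbox = NULL, seed = 1) {
  coords <- dataset@coords
  d <- ncol(coords)
  if (is.null(bbox)) {
    bbox <- as.vector(rbind(apply(coords, 2, min), apply(coords, 2, max)))
  }
  if (length(bbox) != 2 * d) stop("bbox must give (min, max) per dimension")
  withLocalSeed(seed, {
    noise <- vapply(seq_len(d), function(j) {
      runif(nNoise, bbox[2 * j - 1], bbox[2 * j])
    }, numeric(nNoise))
    noise <- matrix(noise, nrow = nNoise)
    newSynthetic(rbind(coords, noise), c(dataset@labels, rep(-1L, nNoise)),
                 c(dataset@recipe,
                   list(noise = list(nNoise = nNoise, bbox = bbox,
                                     seed = seed))))
  })
}
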