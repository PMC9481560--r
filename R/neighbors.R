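#' Validate a point matrix
#'
#' @param points numeric matrix (or coercible) of n points x d features.
#' @return a numeric matrix with validated dimensions.
#' @keywords internal
#' @noRd
asPointMatrix <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2) stop("at least 2 points are required")
  if (ncol(points) < 2) stop("at least 2 dimensions are required")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  points
}

#' Build the exact k-nearest-neighbour graph
#'
#' Computes, for every point, its \code{k} nearest neighbours under the
#' chosen metric, excluding the point itself. Ties in distance are broken
#' by ascending original point index, which makes the graph deterministic
#' and permutation-equivariant.
#'
#' @param points numeric matrix, n points x d features (n >= 2, d >= 2).
#' @param k integer, number of neighbours, 1 <= k <= n-1.
#' @param metric distance metric, \code{"euclidean"} (default) or
#'   \code{"manhattan"}.
#' @return a [KnnGraph-class] object.
#' @examples
#' x <- matrix(rnorm(100), ncol = 2)
#' g <- buildKnn(x, k = 5)
#' head(knnIndices(g))
#' @export
buildKnn <- function(points, k, metric = c("euclidean", "manhattan")) {
  points <- asPointMatrix(points)
  metric <- match.arg(metric)
  n <- nrow(points)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of points")
  D <- as.matrix(dist(points, method = metric))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  seqn <- seq_len(n)
  for (i in seqn) {
    di <- D[i, ]
    di[i] <- Inf # self excluded
    ord <- order(di, seqn)[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- di[ord]
  }
  new("KnnGraph", k = k, indices = idx, distances = dst, metric = metric)
}

#' Central angles of a 2D neighbourhood
#'
#' For a point in 2D, sorts the azimuths of its k neighbour directions
#' (measured counterclockwise from the +x axis in [0, 2*pi)) and returns
#' the k successive central angles, including the wrap-around angle, so
#' that the angles always sum to 2*pi.
#'
#' @param points 2-column numeric coordinate matrix.
#' @param graph a [KnnGraph-class] built from \code{points}.
#' @param i index of the centre point.
#' @return numeric vector of k central angles (radians).
#' @examples
#' x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
#' g <- buildKnn(x, k = 4)
#' centralAngles(x, g, 1) # four right angles
#' @export
centralAngles <- function(points, graph, i) {
  points <- asPointMatrix(points)
  if (ncol(points) != 2) stop("central angles are defined in 2D only")
  nb <- points[graph@indices[i, ], , drop = FALSE]
  dx <- nb[, 1] - points[i, 1]
  dy <- nb[, 2] - points[i, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("degenerate direction: a neighbour coincides with the centre point")
  }
  az <- atan2(dy, dx)
  az[az < 0] <- az[az < 0] + 2 * pi
  az <- sort(az)
  k <- length(az)
  if (k < 2) stop("at least 2 neighbours are required")
  c(diff(az), 2 * pi - az[k] + az[1])
}
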