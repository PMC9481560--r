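#' Empirical neighbourhood-size range from the number of points
#'
#' Continuous piecewise empirical model relating the KNN size k to the
#' number of points n:
#' \itemize{
#'   \item 100 <= n <= 1000: k in [ceiling(n/50), ceiling(n/20)];
#'   \item n >= 1000: k in [ceiling(log2(n) + 10), 5 * ceiling(log2(n))].
#' }
#' The two branches agree at n = 1000 (both give 20..50). The recommended
#' point estimate is the midpoint of the range, rounded up.
#'
#' @param n number of points, n >= 100 (the model is not defined below).
#' @return a list with \code{kLow}, \code{kHigh} and \code{k} (the
#'   recommended midpoint).
#' @examples
#' estimateK(100)  # range 2..5
#' estimateK(1000) # range 20..50
#' @export
estimateK <- function(n) {
  if (n < 100) {
    stop("the empirical k model is defined for n >= 100; ",
         "choose k manually for smaller data")
  }
  if (n <= 1000) {
    kLow <- ceiling(n / 50)
    kHigh <- ceiling(n / 20)
  } else {
    kLow <- ceiling(log2(n) + 10)
    kHigh <- 5 * ceiling(log2(n))
  }
  list(kLow = as.integer(kLow), kHigh = as.integer(kHigh),
       k = as.integer(ceiling((kLow + kHigh) / 2)))
}

#' Delaunay triangulated irregular network of 2D points
#'
#' Builds the Delaunay triangulation (via the lower convex hull of the
#' paraboloid lift) and derives the edge list. For points in general
#' position the triangulation satisfies the 2D Euler identity
#' V + F - E = 1 with F the triangle count.
#'
#' @param points 2-column numeric coordinate matrix with at least 3
#'   non-collinear points.
#' @return a [TinGraph-class] object (cross flags not yet computed).
#' @export
buildTin <- function(points) {
  points <- asPointMatrix(points)
  if (ncol(points) != 2) stop("the TIN is defined for 2D points only")
  ctr <- sweep(points, 2, colMeans(points))
  if (qr(ctr)$rank < 2) {
    stop("triangulation failed: points are collinear or degenerate")
  }
  if (nrow(points) == 3) {
    tri <- matrix(1:3, nrow = 1)
  } else {
    res <- cpp_delaunay(points)
    if (isTRUE(res$degenerate) || nrow(res$triangles) == 0) {
      # exactly cocircular/cospherical configurations (e.g. grid corners)
      # defeat the lifted hull; break ties with a deterministic jitter
      scale <- max(abs(ctr))
      n <- nrow(points)
      jit <- 1e-9 * scale *
        cbind(sin(17 * seq_len(n) + 1), cos(23 * seq_len(n) + 2))
      res <- cpp_delaunay(points + jit)
      if (isTRUE(res$degenerate) || nrow(res$triangles) == 0) {
        stop("triangulation failed: points are collinear or degenerate")
      }
    }
    tri <- res$triangles
  }
  e <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  new("TinGraph",
      vertices = sort(unique(as.integer(tri))),
      edges = matrix(as.integer(e), ncol = 2),
      triangles = matrix(as.integer(tri), ncol = 3),
      crossFlags = logical(0))
}

#' Flag cross-cluster triangles in a TIN
#'
#' A TIN triangle is flagged as cross-cluster when its three vertices fail
#' the mutual proximity rule: with the indicator sigma(v_i, v_j) = 1 iff
#' v_j is among the k nearest neighbours of v_i, the triangle is flagged
#' iff the sum of sigma over all six ordered vertex pairs is below 3.
#' Flagged triangles are excluded from the intra-cluster triangle count
#' used by [estimateBoundaryCount()].
#'
#' @param tin a [TinGraph-class].
#' @param graph a [KnnGraph-class] on the same points (the same k as
#'   clustering, by the shared-k principle).
#' @return the TIN with its \code{crossFlags} slot filled.
#' @export
flagCrossTriangles <- function(tin, graph) {
  tri <- tin@triangles
  idx <- graph@indices
  score <- integer(nrow(tri))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    s <- 0L
    for (a in 1:3) {
      for (b in 1:3) {
        if (a != b && v[b] %in% idx[v[a], ]) s <- s + 1L
      }
    }
    score[t] <- s
  }
  tin@crossFlags <- score < 3L
  tin
}

#' Estimate the number of cluster boundary points from a TIN
#'
#' Combining the handshake identity, the triangle/edge count of a
#' triangulation and the 2D Euler formula over C disconnected
#' sub-networks gives the boundary-point estimate
#' \deqn{B = 2V - F - 2C,}
#' where V is the vertex count and F the number of intra-cluster
#' triangles (triangles not flagged as cross-cluster). The estimate is
#' clamped into [1, V-1] with a warning if the flagging left it outside.
#'
#' @param tin a [TinGraph-class]; if cross flags are present, flagged
#'   triangles are excluded from F.
#' @param C assumed number of clusters (default 1, the fallback when the
#'   cluster count is unknown).
#' @return integer boundary-point count estimate B.
#' @export
estimateBoundaryCount <- function(tin, C = 1) {
  V <- length(tin@vertices)
  nTri <- nrow(tin@triangles)
  f <- if (length(tin@crossFlags) > 0) sum(!tin@crossFlags) else nTri
  B <- 2 * V - f - 2 * C
  if (B < 1 || B > V - 1) {
    warning("boundary-point estimate ", B, " clamped into [1, V-1]")
    B <- min(max(B, 1), V - 1)
  }
  as.integer(B)
}

#' Adaptive DCM threshold from a Delaunay TIN
#'
#' Estimates the number of boundary points B from the Delaunay TIN (after
#' removing cross-cluster triangles) and sets the DCM threshold to the
#' B-th largest DCM value, i.e. ratio = 1 - B/n. Only defined for 2D
#' input; the Euler-formula argument does not carry over to higher
#' dimensions, so non-2D input is refused.
#'
#' @param points 2-column numeric coordinate matrix.
#' @param graph a [KnnGraph-class] on the same points.
#' @param dcm per-point DCM values from [computeDcmField()].
#' @param C assumed number of clusters (default 1).
#' @return a list with \code{tdcm}, \code{ratio}, \code{B} and the
#'   flagged \code{tin}.
#' @examples
#' ds <- genBlobs(n = 300, centers = rbind(c(0, 0), c(12, 0)),
#'                sigmas = c(1, 1), seed = 1)
#' x <- pointCoords(ds)
#' g <- buildKnn(x, k = 10)
#' est <- estimateTdcm(x, g, computeDcmField(x, g))
#' est$ratio
#' @export
estimateTdcm <- function(points, graph, dcm, C = 1) {
  points <- asPointMatrix(points)
  if (ncol(points) != 2) {
    stop("the TIN-based threshold estimate is defined in 2D only")
  }
  tin <- buildTin(points)
  tin <- flagCrossTriangles(tin, graph)
  B <- estimateBoundaryCount(tin, C = C)
  n <- nrow(points)
  tdcm <- sort(dcm, decreasing = TRUE)[B]
  list(tdcm = tdcm, ratio = 1 - B / n, B = B, tin = tin)
}
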