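#' Divide points into internal and boundary by DCM
#'
#' A point is a boundary point when its DCM is at or above the threshold
#' \code{T_DCM} (ties go to the boundary, which errs toward a stronger
#' cage). With \code{ratio} (the target fraction of internal points) the
#' threshold is the \code{round(n * (1 - ratio))}-th largest DCM value,
#' the rank being clamped into [1, n-1]; exact ties can inflate the
#' boundary set beyond the nominal count.
#'
#' @param dcm numeric vector of per-point DCM values.
#' @param threshold absolute DCM threshold (exclusive with \code{ratio}).
#' @param ratio fraction of internal points in [0, 1] (exclusive with
#'   \code{threshold}).
#' @return a list with \code{role} (character, \code{"internal"} /
#'   \code{"boundary"}) and \code{thresholdUsed}.
#' @examples
#' dividePoints(c(0.9, 0.5, 0.1, 0.05), threshold = 0.4)$role
#' @export
dividePoints <- function(dcm, threshold = NULL, ratio = NULL) {
  if (is.null(threshold) == is.null(ratio)) {
    stop("exactly one of threshold or ratio must be given")
  }
  n <- length(dcm)
  if (!is.null(ratio)) {
    if (ratio < 0 || ratio > 1) stop("ratio must be in [0, 1]")
    rank <- floor(n * (1 - ratio) + 0.5) # round half up
    rank <- min(max(rank, 1L), n - 1L)
    threshold <- sort(dcm, decreasing = TRUE)[rank]
  }
  role <- ifelse(dcm >= threshold, "boundary", "internal")
  if (all(role == "boundary")) {
    stop("all points classified as boundary; increase ratio or threshold")
  }
  if (all(role == "internal")) {
    warning("no boundary points; all points will join a single cluster")
  }
  list(role = role, thresholdUsed = threshold)
}

#' Reachable distance of each internal point
#'
#' The reachable distance r_i of an internal point is its minimum distance
#' to any boundary point. With no boundary points at all, r_i is +Inf for
#' every internal point (the rule's limit: a single unconstrained
#' cluster).
#'
#' @param points numeric coordinate matrix.
#' @param role character vector of per-point roles (\code{"internal"} /
#'   \code{"boundary"}).
#' @return numeric vector aligned with \code{points}: r_i for internal
#'   points, NA for boundary points.
#' @export
reachableDistances <- function(points, role) {
  points <- asPointMatrix(points)
  intIdx <- which(role == "internal")
  bndIdx <- which(role == "boundary")
  reach <- rep(NA_real_, nrow(points))
  if (length(bndIdx) == 0) {
    reach[intIdx] <- Inf
    return(reach)
  }
  D <- crossDist(points[intIdx, , drop = FALSE], points[bndIdx, , drop = FALSE])
  reach[intIdx] <- apply(D, 1, min)
  reach
}

# pairwise Euclidean distances between two point sets (rows x rows)
crossDist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Connect internal points within the boundary cage
#'
#' Two internal points i and j belong to the same cluster when
#' \eqn{d(p_i, p_j) \le r_i + r_j}; the clusters are the connected
#' components of the transitive closure of this relation. Component ids
#' are assigned in order of each component's smallest member index.
#'
#' @param points numeric coordinate matrix.
#' @param role per-point roles from [dividePoints()].
#' @param reachable per-point reachable distances from
#'   [reachableDistances()].
#' @return integer vector aligned with \code{points}: cluster ids
#'   (1, 2, ...) for internal points, NA for boundary points.
#' @export
connectInternal <- function(points, role, reachable) {
  points <- asPointMatrix(points)
  intIdx <- which(role == "internal")
  m <- length(intIdx)
  labels <- rep(NA_integer_, nrow(points))
  if (m == 0) return(labels)
  r <- reachable[intIdx]
  if (all(is.infinite(r))) {
    labels[intIdx] <- 1L
    return(labels)
  }
  P <- points[intIdx, , drop = FALSE]
  D <- crossDist(P, P)
  adj <- D <= outer(r, r, "+")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # relabel components by smallest member index
  first <- vapply(seq_len(max(comp)), function(cid) min(which(comp == cid)),
                  integer(1))
  remap <- integer(max(comp))
  remap[order(first)] <- seq_len(max(comp))
  labels[intIdx] <- remap[comp]
  labels
}

#' Assign boundary points to their nearest internal point's cluster
#'
#' Each boundary point takes the cluster label of its nearest internal
#' point; exact distance ties are broken by the smallest internal-point
#' index. A run with no boundary points is a no-op.
#'
#' @param points numeric coordinate matrix.
#' @param role per-point roles.
#' @param labels internal-point labels from [connectInternal()].
#' @return completed integer label vector covering every point.
#' @export
assignBoundary <- function(points, role, labels) {
  points <- asPointMatrix(points)
  intIdx <- which(role == "internal")
  bndIdx <- which(role == "boundary")
  if (length(bndIdx) == 0 || length(intIdx) == 0) return(labels)
  D <- crossDist(points[bndIdx, , drop = FALSE],
                 points[intIdx, , drop = FALSE])
  nearest <- apply(D, 1, which.min) # first minimum = smallest index
  labels[bndIdx] <- labels[intIdx][nearest]
  labels
}

#' CDC clustering
#'
#' The complete CDC procedure: build the exact KNN graph, compute the
#' per-point Direction Centrality Metric, divide internal and boundary
#' points by a DCM threshold (or internal-point ratio), connect the
#' internal points under the reachable-distance rule inside the boundary
#' cage, and attach each boundary point to its nearest internal point.
#' Deterministic for fixed input and parameters.
#'
#' @param points numeric matrix of n points x d features, typically a
#'   2-5 dimensional embedding.
#' @param k neighbourhood size (see [estimateK()] for a data-driven
#'   choice).
#' @param ratio target fraction of internal points in [0, 1]; default 0.9,
#'   within the recommended 0.7-0.99 band. Ignored when \code{threshold}
#'   is given.
#' @param threshold absolute DCM threshold T_DCM (optional, overrides
#'   \code{ratio}).
#' @param mode DCM formulation, \code{"auto"} (angle variance in 2D,
#'   convex complex otherwise), \code{"2d"} or \code{"highd"}.
#' @param metric distance metric for the KNN graph.
#' @return a [CdcPartition-class] object.
#' @examples
#' ds <- genBlobs(n = 200, centers = rbind(c(0, 0), c(10, 0)),
#'                sigmas = c(1, 1), seed = 1)
#' part <- cdcCluster(pointCoords(ds), k = 10, ratio = 0.9)
#' table(clusterLabels(part), trueLabels(ds))
#' @export
cdcCluster <- function(points, k, ratio = 0.9, threshold = NULL,
                       mode = c("auto", "2d", "highd"),
                       metric = c("euclidean", "manhattan")) {
  points <- asPointMatrix(points)
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  graph <- buildKnn(points, k, metric = metric)
  dcm <- computeDcmField(points, graph, mode = mode)
  div <- if (is.null(threshold)) {
    dividePoints(dcm, ratio = ratio)
  } else {
    dividePoints(dcm, threshold = threshold)
  }
  reach <- reachableDistances(points, div$role)
  labels <- connectInternal(points, div$role, reach)
  labels <- assignBoundary(points, div$role, labels)
  new("CdcPartition",
      labels = as.integer(labels),
      role = div$role,
      reachable = reach,
      dcm = dcm,
      thresholdUsed = div$thresholdUsed,
      k = as.integer(k),
      params = list(ratio = if (is.null(threshold)) ratio else NA_real_,
                    mode = mode, metric = metric))
}
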