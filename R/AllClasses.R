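#' @useDynLib cdclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dist quantile rnorm runif sd
#' @importFrom utils head
NULL

#' K-nearest-neighbour graph
#'
#' Exact k-nearest-neighbour structure of a point set: for every point the
#' identities and distances of its \code{k} nearest neighbours (the point
#' itself excluded), each row sorted by distance with ties broken by
#' ascending point index so that the structure is reproducible under row
#' permutation.
#'
#' @slot k integer(1), the number of neighbours per point.
#' @slot indices n x k integer matrix of neighbour indices (1-based).
#' @slot distances n x k numeric matrix of neighbour distances,
#'   non-decreasing along each row.
#' @slot metric character(1), the distance metric used.
#'
#' @seealso [buildKnn()]
#' @export
setClass("KnnGraph",
  representation(
    k = "integer",
    indices = "matrix",
    distances = "matrix",
    metric = "character"
  )
)

setValidity("KnnGraph", function(object) {
  msg <- NULL
  if (ncol(object@indices) != object@k) {
    msg <- c(msg, "indices must have k columns")
  }
  if (!identical(dim(object@indices), dim(object@distances))) {
    msg <- c(msg, "indices and distances dimensions differ")
  }
  n <- nrow(object@indices)
  if (n > 0) {
    if (any(object@indices == seq_len(n))) {
      msg <- c(msg, "a point may not be its own neighbour")
    }
    if (any(object@distances < 0)) {
      msg <- c(msg, "distances must be non-negative")
    }
    if (object@k > 1 &&
        any(object@distances[, -1, drop = FALSE] <
            object@distances[, -object@k, drop = FALSE] - 1e-12)) {
      msg <- c(msg, "distances must be non-decreasing along rows")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Convex complex of neighbour directions on the unit hypersphere
#'
#' The convex hull of a point's deduplicated unit neighbour directions. In
#' d dimensions every facet is a (d-1)-simplex; each facet corresponds to
#' one subdivision unit of the hyperspherical surface. Unit volumes are the
#' simplex volumes plus an equal share of the global volume deficit, so
#' they always sum to the surface area of the unit d-sphere.
#'
#' @slot directions f x d numeric matrix of unit direction vectors.
#' @slot simplices f x d integer matrix; each row the direction indices of
#'   one facet.
#' @slot simplexVolumes numeric, flat (Gram-determinant) facet volumes.
#' @slot unitVolumes numeric, facet volumes after equal error allocation;
#'   empty until [allocateUnitVolumes()] is applied.
#' @slot sphereArea numeric(1), surface area of the unit sphere in the
#'   ambient dimension.
#'
#' @seealso [buildConvexComplex()], [allocateUnitVolumes()], [dcmHighd()]
#' @export
setClass("ConvexComplex",
  representation(
    directions = "matrix",
    simplices = "matrix",
    simplexVolumes = "numeric",
    unitVolumes = "numeric",
    sphereArea = "numeric"
  )
)

setValidity("ConvexComplex", function(object) {
  msg <- NULL
  d <- ncol(object@directions)
  if (ncol(object@simplices) != d) {
    msg <- c(msg, "each simplex must have d vertex indices")
  }
  if (length(object@simplexVolumes) != nrow(object@simplices)) {
    msg <- c(msg, "one volume per simplex required")
  }
  if (length(object@unitVolumes) > 0) {
    if (length(object@unitVolumes) != nrow(object@simplices)) {
      msg <- c(msg, "one unit volume per simplex required")
    } else if (abs(sum(object@unitVolumes) - object@sphereArea) > 1e-6) {
      msg <- c(msg, "unit volumes must sum to the sphere surface area")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Triangulated irregular network (Delaunay TIN) of 2D points
#'
#' Delaunay triangulation with the bookkeeping needed to estimate the
#' number of cluster boundary points through the 2D Euler formula
#' V + F - E = 1: vertex list, undirected edge list, triangle list and an
#' optional per-triangle cross-cluster flag.
#'
#' @slot vertices integer vector of vertex indices present in the
#'   triangulation.
#' @slot edges 2-column integer matrix of undirected edges.
#' @slot triangles 3-column integer matrix of triangle vertex indices.
#' @slot crossFlags logical, one flag per triangle (length 0 until
#'   [flagCrossTriangles()] is applied); TRUE marks a cross-cluster
#'   triangle excluded from the intra-cluster count.
#'
#' @seealso [buildTin()], [estimateBoundaryCount()], [estimateTdcm()]
#' @export
setClass("TinGraph",
  representation(
    vertices = "integer",
    edges = "matrix",
    triangles = "matrix",
    crossFlags = "logical"
  )
)

setValidity("TinGraph", function(object) {
  msg <- NULL
  if (ncol(object@edges) != 2) msg <- c(msg, "edges must have 2 columns")
  if (ncol(object@triangles) != 3) {
    msg <- c(msg, "triangles must have 3 columns")
  }
  if (length(object@crossFlags) > 0 &&
      length(object@crossFlags) != nrow(object@triangles)) {
    msg <- c(msg, "one cross flag per triangle required")
  }
  if (is.null(msg)) TRUE else msg
})

#' CDC clustering result
#'
#' Full output of the CDC procedure: the per-point internal/boundary role
#' from thresholding the Direction Centrality Metric, the reachable
#' distance of each internal point (its distance to the nearest boundary
#' point), and the final cluster labels from connecting internal points
#' under the reachable-distance rule and attaching each boundary point to
#' its nearest internal point.
#'
#' Cluster labels are contiguous integers starting at 1, ordered by the
#' smallest member index; points removed as noise (when denoising is
#' applied upstream) carry the label -1.
#'
#' @slot labels integer cluster label per point.
#' @slot role character per point, \code{"internal"} or \code{"boundary"}
#'   (\code{"noise"} for points removed before clustering).
#' @slot reachable numeric per point; the reachable distance for internal
#'   points, NA for boundary/noise points.
#' @slot dcm numeric per point, the normalized DCM in [0, 1] (NA for noise
#'   points).
#' @slot thresholdUsed numeric(1), the DCM threshold actually applied.
#' @slot k integer(1), the neighbourhood size used.
#' @slot params list of the remaining effective parameters (ratio, mode,
#'   metric, denoising settings).
#'
#' @seealso [cdcCluster()]
#' @export
setClass("CdcPartition",
  representation(
    labels = "integer",
    role = "character",
    reachable = "numeric",
    dcm = "numeric",
    thresholdUsed = "numeric",
    k = "integer",
    params = "list"
  )
)

setValidity("CdcPartition", function(object) {
  msg <- NULL
  n <- length(object@labels)
  if (length(object@role) != n || length(object@reachable) != n ||
      length(object@dcm) != n) {
    msg <- c(msg, "labels, role, reachable and dcm must have equal length")
  }
  if (!all(object@role %in% c("internal", "boundary", "noise"))) {
    msg <- c(msg, "roles must be internal, boundary or noise")
  }
  keep <- object@labels != -1L
  if (any(keep) && !setequal(unique(object@labels[keep]),
                             seq_len(max(object@labels[keep])))) {
    msg <- c(msg, "cluster ids must be contiguous starting at 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Seeded synthetic dataset
#'
#' A generated point set with ground-truth labels and the full recipe
#' (generator name, parameters, seed) needed to reproduce it bit-for-bit.
#' Injected background noise points carry the label -1.
#'
#' @slot coords n x d numeric coordinate matrix.
#' @slot labels integer ground-truth label per point (-1 = noise).
#' @slot recipe list with the generator name, its parameters and the seed.
#'
#' @seealso [genBlobs()], [genRingIsland()], [genSpindles()],
#'   [genNoiseOverlay()]
#' @export
setClass("SyntheticDataset",
  representation(
    coords = "matrix",
    labels = "integer",
    recipe = "list"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- NULL
  if (nrow(object@coords) != length(object@labels)) {
    msg <- c(msg, "one label per point required")
  }
  if (!all(is.finite(object@coords))) {
    msg <- c(msg, "coordinates must be finite")
  }
  if (is.null(msg)) TRUE else msg
})
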