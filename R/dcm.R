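#' Normalized 2D Direction Centrality Metric from central angles
#'
#' The DCM of a 2D neighbourhood is the variance of its k central angles,
#' normalized by the analytic maximum 4(k-1)pi^2/k^2 so that it lies in
#' [0, 1]:
#' \deqn{DCM = \frac{k}{4(k-1)\pi^2}\sum_{i=1}^{k}\left(\alpha_i -
#'   \frac{2\pi}{k}\right)^2}
#' It is 0 exactly when all angles are equal (neighbours evenly spread in
#' every direction) and 1 exactly when one angle is 2*pi and the rest are 0
#' (all neighbours on one side).
#'
#' @param angles numeric vector of k >= 2 central angles summing to 2*pi.
#' @return a single DCM value in [0, 1].
#' @examples
#' dcm2d(rep(pi / 2, 4))        # 0
#' dcm2d(c(2 * pi, 0, 0, 0))    # 1
#' @export
dcm2d <- function(angles) {
  k <- length(angles)
  if (k < 2) stop("at least 2 angles are required")
  if (abs(sum(angles) - 2 * pi) > 1e-6) {
    stop("central angles must sum to 2*pi")
  }
  v <- sum((angles - 2 * pi / k)^2)
  min(max(k / (4 * (k - 1) * pi^2) * v, 0), 1)
}

#' Map a point's neighbours onto the unit hypersphere
#'
#' Converts the k nearest neighbours of point \code{i} into unit direction
#' vectors centred at the point. Neighbours that coincide with the centre
#' contribute no direction and are dropped; repeated directions (duplicate
#' neighbours) are collapsed to a single vector.
#'
#' @param points numeric coordinate matrix.
#' @param graph a [KnnGraph-class] built from \code{points}.
#' @param i index of the centre point.
#' @return a matrix of deduplicated unit direction vectors (possibly fewer
#'   rows than k).
#' @export
mapToUnitSphere <- function(points, graph, i) {
  points <- asPointMatrix(points)
  nb <- points[graph@indices[i, ], , drop = FALSE]
  dirs <- sweep(nb, 2, points[i, ])
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  dirs[!duplicated(dirs), , drop = FALSE]
}

#' Surface area of the unit d-sphere
#'
#' Generalized surface area of the unit sphere embedded in d dimensions,
#' \eqn{S = 2\pi^{d/2}/\Gamma(d/2)}: the circle circumference 2*pi for
#' d = 2, the sphere area 4*pi for d = 3, 2*pi^2 for d = 4.
#'
#' @param d ambient dimension, d >= 2.
#' @return the surface area.
#' @export
sphereArea <- function(d) {
  if (d < 2) stop("dimension must be at least 2")
  2 * pi^(d / 2) / gamma(d / 2)
}

#' Volume of a (d-1)-simplex embedded in d-space
#'
#' Gram-determinant volume of the simplex with vertex rows
#' \code{vertices}: with A the matrix of edge vectors from the last
#' vertex, the volume is \eqn{\sqrt{\det(AA^T)}/(d-1)!}. Affinely
#' dependent vertices give volume 0.
#'
#' @param vertices d x d numeric matrix; each row one vertex of the
#'   (d-1)-simplex in d-space.
#' @return the non-negative simplex volume.
#' @examples
#' simplexVolume(rbind(c(1, 0), c(0, 1)))                   # sqrt(2)
#' simplexVolume(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) # sqrt(3)/2
#' @export
simplexVolume <- function(vertices) {
  vertices <- as.matrix(vertices)
  d <- ncol(vertices)
  if (nrow(vertices) != d) {
    stop("a (d-1)-simplex in d-space needs d vertices")
  }
  as.numeric(cpp_simplex_volumes(vertices, matrix(seq_len(d), nrow = 1)))
}

#' Build the convex complex of unit directions
#'
#' Constructs the convex hull of the (deduplicated) unit neighbour
#' directions. In d >= 3 dimensions the hull is built by an exact
#' incremental algorithm and every facet is a (d-1)-simplex; in 2D the
#' facets are the chords between azimuth-adjacent directions on the unit
#' circle. Flat simplex volumes are computed for every facet; apply
#' [allocateUnitVolumes()] to obtain subdivision-unit volumes.
#'
#' A neighbourhood whose directions do not span the ambient dimension (or
#' with fewer than d+1 distinct directions in d >= 3, fewer than 3 in 2D)
#' is degenerate and signalled as an error of class
#' \code{"cdcDegenerate"}; [computeDcmField()] maps such points to DCM 1.
#'
#' @param directions matrix of unit direction vectors (rows).
#' @return a [ConvexComplex-class] object (unit volumes not yet
#'   allocated).
#' @export
buildConvexComplex <- function(directions) {
  directions <- as.matrix(directions)
  d <- ncol(directions)
  m <- nrow(directions)
  degenerate <- function() {
    cond <- structure(
      list(message = "degenerate neighbourhood: directions do not span the space",
           call = NULL),
      class = c("cdcDegenerate", "error", "condition")
    )
    stop(cond)
  }
  if (d == 2) {
    if (m < 3) degenerate()
    az <- atan2(directions[, 2], directions[, 1])
    az[az < 0] <- az[az < 0] + 2 * pi
    ord <- order(az)
    simp <- cbind(ord, ord[c(seq_len(m)[-1], 1)])
  } else {
    if (m < d + 1) degenerate()
    # directions confined to a lower-dimensional subspace cannot enclose
    # the sphere; detect this before attempting hull construction
    if (qr(sweep(directions, 2, colMeans(directions)))$rank < d) degenerate()
    h <- cpp_convex_hull(directions, 1e-10)
    if (isTRUE(h$degenerate)) {
      # one retry with a deterministic tiny jitter, then give up
      jit <- directions +
        1e-10 * sin(outer(seq_len(m), seq_len(d), function(a, b) a * 13 + b * 7))
      h <- cpp_convex_hull(jit, 1e-10)
      if (isTRUE(h$degenerate)) degenerate()
    }
    simp <- h$facets
  }
  vols <- as.numeric(cpp_simplex_volumes(directions, simp))
  new("ConvexComplex",
      directions = directions,
      simplices = matrix(as.integer(simp), nrow = nrow(simp)),
      simplexVolumes = vols,
      unitVolumes = numeric(0),
      sphereArea = sphereArea(d))
}

#' Allocate subdivision-unit volumes on the hypersphere
#'
#' The flat facet simplices under-measure the curved subdivision units, so
#' the global deficit between the unit-sphere surface area S and the sum
#' of the simplex volumes is shared equally among the f units:
#' \deqn{vol(u_i) = vol(s_i) + (S - \sum_j vol(s_j))/f.}
#' The unit volumes then sum to S exactly and preserve the ranking of the
#' simplex volumes.
#'
#' @param complex a [ConvexComplex-class] from [buildConvexComplex()].
#' @return the complex with its \code{unitVolumes} slot filled.
#' @export
allocateUnitVolumes <- function(complex) {
  vols <- complex@simplexVolumes
  f <- length(vols)
  if (f < 1) stop("the complex has no facets")
  S <- complex@sphereArea
  complex@unitVolumes <- vols + (S - sum(vols)) / f
  complex
}

#' High-dimensional DCM from a convex complex
#'
#' Normalized variance of the f subdivision-unit volumes of the
#' hyperspherical surface:
#' \deqn{DCM = \frac{f}{(f-1)S^2}\sum_{i=1}^{f}\left(vol(u_i) -
#'   \frac{S}{f}\right)^2,}
#' which is 0 when all units are equal and 1 when a single unit carries
#' the whole surface. On the unit circle with exact arc lengths as unit
#' volumes this reduces to the 2D angle formulation.
#'
#' @param complex a [ConvexComplex-class] with allocated unit volumes (the
#'   allocation is applied automatically if missing).
#' @return a DCM value in [0, 1].
#' @export
dcmHighd <- function(complex) {
  if (length(complex@unitVolumes) == 0) {
    complex <- allocateUnitVolumes(complex)
  }
  u <- complex@unitVolumes
  f <- length(u)
  if (f < 2) stop("at least 2 subdivision units are required")
  S <- complex@sphereArea
  v <- sum((u - S / f)^2)
  min(max(f / ((f - 1) * S^2) * v, 0), 1)
}

#' Compute the Direction Centrality Metric for every point
#'
#' Per-point normalized DCM in [0, 1]. With \code{mode = "auto"} the 2D
#' angle-variance formulation is used for 2-column input and the
#' convex-complex (hyperspherical subdivision) formulation otherwise.
#' Degenerate neighbourhoods -- a neighbour coinciding with the centre in
#' 2D, or directions that do not span the space in higher dimensions --
#' receive DCM 1 and are therefore marked as boundary by any threshold:
#' their directional coverage is maximally one-sided.
#'
#' @param points numeric coordinate matrix.
#' @param graph a [KnnGraph-class] built from \code{points}.
#' @param mode \code{"auto"} (default), \code{"2d"} or \code{"highd"}.
#' @return numeric vector of n DCM values in [0, 1].
#' @examples
#' x <- as.matrix(expand.grid(1:5, 1:5))
#' g <- buildKnn(x, k = 4)
#' dcm <- computeDcmField(x, g)
#' dcm[13] < dcm[1] # grid interior more surrounded than the corner
#' @export
computeDcmField <- function(points, graph, mode = c("auto", "2d", "highd")) {
  points <- asPointMatrix(points)
  mode <- match.arg(mode)
  d <- ncol(points)
  if (mode == "2d" && d != 2) stop("2d mode requires 2-column input")
  use2d <- (mode == "2d") || (mode == "auto" && d == 2)
  n <- nrow(points)
  if (graph@k < 2) stop("DCM requires k >= 2")
  vapply(seq_len(n), function(i) {
    if (use2d) {
      ang <- tryCatch(centralAngles(points, graph, i), error = function(e) NULL)
      if (is.null(ang)) return(1)
      dcm2d(ang)
    } else {
      dirs <- mapToUnitSphere(points, graph, i)
      cc <- tryCatch(buildConvexComplex(dirs), cdcDegenerate = function(e) NULL)
      if (is.null(cc)) return(1)
      dcmHighd(allocateUnitVolumes(cc))
    }
  }, numeric(1))
}
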