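#' Inverse-distance-metric noise scores
#'
#' IDM scores each point by the inverse of the summed distances to its k
#' nearest neighbours, \eqn{1/\sum_{j \in KNN(i)} d(i, j)}. Isolated
#' points score low. A point whose neighbour distances sum to zero
#' (exact duplicates) scores +Inf and is therefore never removed.
#'
#' @param graph a [KnnGraph-class].
#' @return numeric vector of scores (low = noise-like).
#' @export
idmScores <- function(graph) {
  1 / rowSums(graph@distances)
}

#' Reverse-KNN noise scores
#'
#' Counts, for every point, how many other points include it among their
#' own k nearest neighbours. The scores always sum to n * k. Remote
#' points that nobody selects score 0.
#'
#' @param graph a [KnnGraph-class].
#' @return integer vector of reverse-neighbour counts (low = noise-like).
#' @export
rknnScores <- function(graph) {
  n <- nrow(graph@indices)
  tabulate(as.integer(graph@indices), nbins = n)
}

#' Local outlier factor
#'
#' Canonical LOF at the shared neighbourhood size k: the reachability
#' distance of p from o is max(k-distance(o), d(p, o)); the local
#' reachability density of p is the inverse mean reachability distance
#' over its neighbours; LOF(p) is the mean ratio of the neighbours' local
#' reachability densities to p's own. Values near 1 indicate points
#' embedded in homogeneous density, values well above 1 indicate
#' outliers.
#'
#' @param graph a [KnnGraph-class].
#' @return numeric vector of LOF scores (high = noise-like).
#' @export
lofScores <- function(graph) {
  idx <- graph@indices
  dst <- graph@distances
  k <- graph@k
  n <- nrow(idx)
  kdist <- dst[, k]
  # reach(i, j-th neighbour) = max(kdist[neighbour], d(i, neighbour))
  reach <- pmax(matrix(kdist[idx], n, k), dst)
  lrd <- 1 / rowMeans(reach)
  lrd[!is.finite(lrd)] <- Inf # duplicate-heavy neighbourhoods
  ratio <- matrix(lrd[idx], n, k) / lrd
  ratio[is.nan(ratio)] <- 1 # Inf/Inf: identical duplicated points
  rowMeans(ratio)
}

#' Remove noise points before clustering
#'
#' KNN-based noise elimination as a preprocessing step that shares k with
#' clustering. With the quantile cutoff policy (default) the lowest
#' \code{cut} fraction of IDM/RKNN scores -- or the highest \code{cut}
#' fraction of LOF scores -- is removed; an absolute score threshold can
#' be given instead. Removed points are reported with label -1 by
#' [denoiseCluster()] and are never assigned to clusters.
#'
#' @param points numeric coordinate matrix.
#' @param method \code{"idm"}, \code{"rknn"} or \code{"lof"}.
#' @param cut quantile cutoff in [0, 1) (fraction of points to drop);
#'   0 removes nothing.
#' @param threshold absolute score threshold overriding \code{cut}
#'   (IDM/RKNN: remove scores strictly below; LOF: strictly above).
#' @param k neighbourhood size (default from [estimateK()] when n >= 100,
#'   else 10).
#' @param graph optional precomputed [KnnGraph-class].
#' @return a list with \code{keep} (logical mask), \code{scores},
#'   \code{method} and \code{points} (the filtered matrix).
#' @examples
#' ds <- genNoiseOverlay(genBlobs(n = 300, centers = matrix(0, 1, 2),
#'                                sigmas = 1, seed = 1),
#'                       nNoise = 30, bbox = c(-8, 8, -8, 8), seed = 2)
#' dn <- denoisePoints(pointCoords(ds), method = "idm", cut = 0.1, k = 10)
#' sum(!dn$keep)
#' @export
denoisePoints <- function(points, method = c("idm", "rknn", "lof"),
                          cut = 0.1, threshold = NULL, k = NULL,
                          graph = NULL) {
  points <- asPointMatrix(points)
  method <- match.arg(method)
  n <- nrow(points)
  if (is.null(graph)) {
    if (is.null(k)) k <- if (n >= 100) estimateK(n)$k else 10L
    graph <- buildKnn(points, k)
  }
  scores <- switch(method,
    idm = idmScores(graph),
    rknn = as.numeric(rknnScores(graph)),
    lof = lofScores(graph)
  )
  if (is.null(threshold)) {
    if (cut < 0 || cut >= 1) stop("cut must be in [0, 1)")
    if (cut == 0) {
      keep <- rep(TRUE, n)
    } else if (method == "lof") {
      keep <- scores <= quantile(scores, 1 - cut)
    } else {
      keep <- scores >= quantile(scores, cut)
    }
  } else {
    keep <- if (method == "lof") scores <= threshold else scores >= threshold
  }
  list(keep = keep, scores = scores, method = method,
       points = points[keep, , drop = FALSE])
}

#' Denoise then cluster
#'
#' Convenience wrapper running [denoisePoints()] followed by
#' [cdcCluster()] on the retained points. Removed points get label -1 and
#' role \code{"noise"} in the returned partition, aligned with the input
#' rows.
#'
#' @inheritParams cdcCluster
#' @inheritParams denoisePoints
#' @param noiseCut quantile cutoff passed to [denoisePoints()].
#' @return a [CdcPartition-class] covering all input points.
#' @export
denoiseCluster <- function(points, k, ratio = 0.9, threshold = NULL,
                           mode = c("auto", "2d", "highd"),
                           method = c("idm", "rknn", "lof"),
                           noiseCut = 0.1) {
  points <- asPointMatrix(points)
  method <- match.arg(method)
  mode <- match.arg(mode)
  dn <- denoisePoints(points, method = method, cut = noiseCut, k = k)
  part <- cdcCluster(dn$points, k = k, ratio = ratio,
                     threshold = threshold, mode = mode)
  n <- nrow(points)
  labels <- rep(-1L, n)
  role <- rep("noise", n)
  reach <- rep(NA_real_, n)
  dcm <- rep(NA_real_, n)
  labels[dn$keep] <- part@labels
  role[dn$keep] <- part@role
  reach[dn$keep] <- part@reachable
  dcm[dn$keep] <- part@dcm
  new("CdcPartition", labels = labels, role = role, reachable = reach,
      dcm = dcm, thresholdUsed = part@thresholdUsed, k = part@k,
      params = c(part@params, list(denoise = method, noiseCut = noiseCut)))
}
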