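# External clustering-agreement metrics. Noise points (label -1 in either
# vector) are excluded by default; with noise = "cluster" they are scored
# as a cluster of their own.

labelPair <- function(truth, predicted, noise = c("exclude", "cluster")) {
  noise <- match.arg(noise)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted labels must have equal length")
  }
  if (noise == "exclude") {
    keep <- truth != -1 & predicted != -1
  } else {
    keep <- rep(TRUE, length(truth))
  }
  if (!any(keep)) stop("no non-noise points to evaluate")
  list(truth = as.integer(factor(truth[keep])),
       predicted = as.integer(factor(predicted[keep])))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index between two labelings; 1 for
#' identical partitions, about 0 for independent ones, possibly negative.
#'
#' @param truth ground-truth label vector.
#' @param predicted predicted label vector (-1 = noise).
#' @param noise \code{"exclude"} (default) drops noise-labelled points;
#'   \code{"cluster"} scores them as their own cluster.
#' @return ARI in [-1, 1].
#' @examples
#' ariScore(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: labels are nominal
#' @export
ariScore <- function(truth, predicted, noise = c("exclude", "cluster")) {
  p <- labelPair(truth, predicted, noise)
  tab <- table(p$truth, p$predicted)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(1) # both partitions trivial
  (sumij - expected) / (maxidx - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two labelings normalized by the
#' arithmetic mean of their entropies (one of several conventions; stated
#' here because published NMI values depend on it).
#'
#' @inheritParams ariScore
#' @return NMI in [0, 1].
#' @export
nmiScore <- function(truth, predicted, noise = c("exclude", "cluster")) {
  p <- labelPair(truth, predicted, noise)
  tab <- table(p$truth, p$predicted)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 == 0 && h2 == 0) return(1) # both single-cluster: identical
  if (h1 == 0 || h2 == 0) return(0)
  mi / ((h1 + h2) / 2)
}

#' Clustering accuracy by optimal label matching
#'
#' Fraction of points whose predicted cluster matches the truth after the
#' cluster ids are mapped one-to-one to truth ids by a maximum-weight
#' assignment (Hungarian algorithm) on the contingency table.
#'
#' @inheritParams ariScore
#' @return ACC in [0, 1].
#' @export
accScore <- function(truth, predicted, noise = c("exclude", "cluster")) {
  p <- labelPair(truth, predicted, noise)
  tab <- unclass(table(p$truth, p$predicted))
  n <- sum(tab)
  sq <- max(dim(tab))
  padded <- matrix(0, sq, sq)
  padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  match <- solveAssignment(max(padded) - padded)
  sum(padded[cbind(seq_len(sq), match)]) / n
}

#' Pairwise F1 score
#'
#' Precision and recall over point pairs: a pair counts as a true
#' positive when it is co-clustered in both labelings. F1 is their
#' harmonic mean, computed in closed form from the contingency table.
#'
#' @inheritParams ariScore
#' @return F1 in [0, 1].
#' @export
f1Score <- function(truth, predicted, noise = c("exclude", "cluster")) {
  p <- labelPair(truth, predicted, noise)
  tab <- table(p$truth, p$predicted)
  tp <- sum(choose(tab, 2))
  predPairs <- sum(choose(colSums(tab), 2))
  truthPairs <- sum(choose(rowSums(tab), 2))
  if (predPairs == 0 || truthPairs == 0) {
    return(if (predPairs == truthPairs) 1 else 0)
  }
  prec <- tp / predPairs
  rec <- tp / truthPairs
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Evaluate a clustering against ground truth
#'
#' All four external metrics at once.
#'
#' @inheritParams ariScore
#' @return named numeric vector with \code{acc}, \code{nmi}, \code{ari}
#'   and \code{f1}.
#' @examples
#' evaluateClustering(rep(1:2, each = 5), rep(1:2, each = 5))
#' @export
evaluateClustering <- function(truth, predicted,
                               noise = c("exclude", "cluster")) {
  noise <- match.arg(noise)
  c(acc = accScore(truth, predicted, noise),
    nmi = nmiScore(truth, predicted, noise),
    ari = ariScore(truth, predicted, noise),
    f1 = f1Score(truth, predicted, noise))
}

# Hungarian algorithm (Jonker-Volgenant potentials, O(n^3)) for a square
# cost matrix; returns the column assigned to each row, minimizing cost.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- -1
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1]] <- j
  ans
}
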