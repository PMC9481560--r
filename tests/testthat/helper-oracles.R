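# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles (or defers to an external reference
# implementation) and never calls the code path under test.

# brute-force exact KNN by repeated minimum extraction over hand-computed
# distances (ties by ascending index)
bruteKnn <- function(x, k) {
  n <- nrow(x)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))
    di[i] <- Inf
    remaining <- seq_len(n)
    for (j in seq_len(k)) {
      best <- remaining[which.min(di[remaining])] # which.min: first = lowest index
      idx[i, j] <- best
      dst[i, j] <- di[best]
      remaining <- setdiff(remaining, best)
    }
  }
  list(indices = idx, distances = dst)
}

# Cayley-Menger volume of the (m-1)-simplex on m vertex rows
cayleyMengerVolume <- function(V) {
  m <- nrow(V)
  D2 <- as.matrix(dist(V))^2
  B <- rbind(c(0, rep(1, m)), cbind(1, D2))
  v2 <- (-1)^m / (2^(m - 1) * factorial(m - 1)^2) * det(B)
  sqrt(max(v2, 0))
}

# transitive closure of the reachable-distance relation by naive union-find
bruteConnect <- function(P, r) {
  m <- nrow(P)
  parent <- seq_len(m)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (sqrt(sum((P[i, ] - P[j, ])^2)) <= r[i] + r[j]) {
        ra <- find(i)
        rb <- find(j)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  as.integer(factor(roots, levels = unique(roots[order(seq_len(m))])))
}

# pair-enumeration precision/recall/F1 and Rand statistics
brutePairMetrics <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      sameT <- truth[i] == truth[j]
      sameP <- pred[i] == pred[j]
      if (sameT && sameP) tp <- tp + 1
      else if (!sameT && sameP) fp <- fp + 1
      else if (sameT && !sameP) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = prec, recall = rec,
       f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
         2 * prec * rec / (prec + rec))
}

# brute-force assignment by permutation enumeration (n <= 7)
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  bestp <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; bestp <- p }
  }
  list(cost = best, perm = bestp)
}

# run a python oracle script; returns stdout lines. python (with numpy,
# scipy, scikit-learn) ships in the runtime environment.
pyOracle <- function(code) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  }
  out
}

writeTempCsv <- function(x) {
  f <- tempfile(fileext = ".csv")
  utils::write.table(x, f, sep = ",", row.names = FALSE, col.names = FALSE)
  f
}

# canonical facet/triangle set representation for set comparison
facetKey <- function(m) {
  sort(apply(m, 1, function(r) paste(sort(r), collapse = ",")))
}

# random unit directions
randomDirections <- function(m, d) {
  x <- matrix(rnorm(m * d), m, d)
  x / sqrt(rowSums(x^2))
}

# partitions agree as label sets (grouping identical up to renaming)
sameGrouping <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}
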