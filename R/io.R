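# Delimited-matrix readers/writers and the plain-text run report. Parsing
# is strict: ragged rows, non-numeric cells and misaligned label files are
# reported with the offending line number.

#' Read a numeric point matrix from delimited text
#'
#' @param path CSV/TSV file, one point per row.
#' @param delimiter field separator (default comma).
#' @param header TRUE to skip a single header row (off by default; header
#'   auto-detection is deliberately not attempted).
#' @return numeric matrix of points.
#' @export
readPointMatrix <- function(path, delimiter = ",", header = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only; blank lines inside the body are errors
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  offset <- 0L
  if (header) {
    lines <- lines[-1]
    offset <- 1L
  }
  if (length(lines) == 0) stop("empty input file: ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row at line ", bad + offset, " of ", path,
         " (", widths[bad], " fields, expected ", widths[1], ")")
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / widths[1])
    stop("non-numeric value at line ", bad + offset, " of ", path)
  }
  matrix(vals, nrow = length(cells), ncol = widths[1], byrow = TRUE)
}

#' Read a label vector (one label per row)
#'
#' @param path text file with one integer label per line.
#' @param n expected number of labels; a mismatch is an alignment error.
#' @return integer label vector.
#' @export
readLabels <- function(path, n = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) stop("empty label file: ", path)
  vals <- suppressWarnings(as.integer(trimws(lines)))
  if (anyNA(vals)) {
    stop("non-integer label at line ", which(is.na(vals))[1], " of ", path)
  }
  if (!is.null(n) && length(vals) != n) {
    stop("label file ", path, " has ", length(vals),
         " rows but the matrix has ", n)
  }
  vals
}

#' Write a point matrix to delimited text
#'
#' Coordinates are written with 17 significant digits so that a write/read
#' round trip reproduces them bitwise.
#'
#' @param path output file.
#' @param coords numeric matrix.
#' @param delimiter field separator.
#' @export
writePointMatrix <- function(path, coords, delimiter = ",") {
  rows <- apply(coords, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = delimiter)
  })
  writeLines(rows, path)
}

#' Write cluster labels, one per row
#'
#' @param path output file.
#' @param labels a [CdcPartition-class] or an integer vector.
#' @export
writeLabels <- function(path, labels) {
  if (is(labels, "CdcPartition")) labels <- clusterLabels(labels)
  writeLines(format(as.integer(labels), trim = TRUE, scientific = FALSE),
             path)
}

#' Write a plain-text run report
#'
#' Key=value lines describing the effective (post-clamp) parameters and
#' headline results of a run, so that a published run can be replayed.
#'
#' @param path output file.
#' @param partition a [CdcPartition-class].
#' @param metrics optional named numeric vector (e.g. from
#'   [evaluateClustering()]) appended to the report.
#' @export
writeReport <- function(path, partition, metrics = NULL) {
  kv <- c(
    version = as.character(utils::packageVersion("cdclust")),
    n = length(partition@labels),
    k = partition@k,
    threshold_used = sprintf("%.17g", partition@thresholdUsed),
    ratio = sprintf("%.17g", partition@params$ratio),
    mode = partition@params$mode,
    m_internal = sum(partition@role == "internal"),
    n_boundary = sum(partition@role == "boundary"),
    n_noise = sum(partition@role == "noise"),
    clusters = nClusters(partition)
  )
  if (!is.null(metrics)) {
    kv <- c(kv, vapply(metrics, function(v) sprintf("%.17g", v),
                       character(1)))
  }
  writeLines(paste0(names(kv), "=", kv), path)
}
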