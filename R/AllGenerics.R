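#' @name cdclust-accessors
#' @title Accessors for cdclust S4 classes
#'
#' @description Accessor generics for the [KnnGraph-class],
#' [CdcPartition-class], [TinGraph-class], [ConvexComplex-class] and
#' [SyntheticDataset-class] objects. Slots should be read through these
#' rather than with \code{@}.
#'
#' @param object an object of the respective class.
#' @return The slot contents (see the individual methods).
NULL

#' @rdname cdclust-accessors
#' @export
setGeneric("knnIndices", function(object) standardGeneric("knnIndices"))

#' @rdname cdclust-accessors
#' @export
setGeneric("knnDistances", function(object) standardGeneric("knnDistances"))

#' @rdname cdclust-accessors
#' @export
setGeneric("nNeighbors", function(object) standardGeneric("nNeighbors"))

#' @rdname cdclust-accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname cdclust-accessors
#' @export
setGeneric("pointRoles", function(object) standardGeneric("pointRoles"))

#' @rdname cdclust-accessors
#' @export
setGeneric("reachableDist", function(object) standardGeneric("reachableDist"))

#' @rdname cdclust-accessors
#' @export
setGeneric("dcmValues", function(object) standardGeneric("dcmValues"))

#' @rdname cdclust-accessors
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))

#' @rdname cdclust-accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname cdclust-accessors
#' @export
setGeneric("tinEdges", function(object) standardGeneric("tinEdges"))

#' @rdname cdclust-accessors
#' @export
setGeneric("tinTriangles", function(object) standardGeneric("tinTriangles"))

#' @rdname cdclust-accessors
#' @export
setGeneric("crossFlags", function(object) standardGeneric("crossFlags"))

#' @rdname cdclust-accessors
#' @export
setGeneric("simplexVolumes", function(object) standardGeneric("simplexVolumes"))

#' @rdname cdclust-accessors
#' @export
setGeneric("unitVolumes", function(object) standardGeneric("unitVolumes"))

#' @rdname cdclust-accessors
#' @export
setGeneric("sphereSurface", function(object) standardGeneric("sphereSurface"))

#' @rdname cdclust-accessors
#' @export
setGeneric("pointCoords", function(object) standardGeneric("pointCoords"))

#' @rdname cdclust-accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))

#' @rdname cdclust-accessors
#' @export
setGeneric("datasetRecipe", function(object) standardGeneric("datasetRecipe"))

# ---- methods ---------------------------------------------------------------

#' @rdname cdclust-accessors
#' @export
setMethod("knnIndices", "KnnGraph", function(object) object@indices)

#' @rdname cdclust-accessors
#' @export
setMethod("knnDistances", "KnnGraph", function(object) object@distances)

#' @rdname cdclust-accessors
#' @export
setMethod("nNeighbors", "KnnGraph", function(object) object@k)

#' @rdname cdclust-accessors
#' @export
setMethod("clusterLabels", "CdcPartition", function(object) object@labels)

#' @rdname cdclust-accessors
#' @export
setMethod("pointRoles", "CdcPartition", function(object) object@role)

#' @rdname cdclust-accessors
#' @export
setMethod("reachableDist", "CdcPartition", function(object) object@reachable)

#' @rdname cdclust-accessors
#' @export
setMethod("dcmValues", "CdcPartition", function(object) object@dcm)

#' @rdname cdclust-accessors
#' @export
setMethod("thresholdUsed", "CdcPartition", function(object) object@thresholdUsed)

#' @rdname cdclust-accessors
#' @export
setMethod("nClusters", "CdcPartition", function(object) {
  keep <- object@labels != -1L
  if (!any(keep)) 0L else max(object@labels[keep])
})

#' @rdname cdclust-accessors
#' @export
setMethod("tinEdges", "TinGraph", function(object) object@edges)

#' @rdname cdclust-accessors
#' @export
setMethod("tinTriangles", "TinGraph", function(object) object@triangles)

#' @rdname cdclust-accessors
#' @export
setMethod("crossFlags", "TinGraph", function(object) object@crossFlags)

#' @rdname cdclust-accessors
#' @export
setMethod("simplexVolumes", "ConvexComplex", function(object) object@simplexVolumes)

#' @rdname cdclust-accessors
#' @export
setMethod("unitVolumes", "ConvexComplex", function(object) object@unitVolumes)

#' @rdname cdclust-accessors
#' @export
setMethod("sphereSurface", "ConvexComplex", function(object) object@sphereArea)

#' @rdname cdclust-accessors
#' @export
setMethod("pointCoords", "SyntheticDataset", function(object) object@coords)

#' @rdname cdclust-accessors
#' @export
setMethod("trueLabels", "SyntheticDataset", function(object) object@labels)

#' @rdname cdclust-accessors
#' @export
setMethod("datasetRecipe", "SyntheticDataset", function(object) object@recipe)

# ---- show ------------------------------------------------------------------

setMethod("show", "KnnGraph", function(object) {
  cat("KnnGraph:", nrow(object@indices), "points, k =", object@k,
      ", metric =", object@metric, "\n")
})

setMethod("show", "ConvexComplex", function(object) {
  cat("ConvexComplex:", nrow(object@directions), "directions in",
      ncol(object@directions), "dimensions,", nrow(object@simplices),
      "facets\n")
  cat("  sphere area:", format(object@sphereArea),
      if (length(object@unitVolumes)) "(unit volumes allocated)\n" else
        "(unit volumes not yet allocated)\n")
})

setMethod("show", "TinGraph", function(object) {
  cat("TinGraph:", length(object@vertices), "vertices,",
      nrow(object@edges), "edges,", nrow(object@triangles), "triangles")
  if (length(object@crossFlags)) {
    cat(";", sum(object@crossFlags), "cross-cluster triangles flagged")
  }
  cat("\n")
})

setMethod("show", "CdcPartition", function(object) {
  n <- length(object@labels)
  cat("CdcPartition:", n, "points,", nClusters(object), "clusters\n")
  cat("  internal:", sum(object@role == "internal"),
      " boundary:", sum(object@role == "boundary"),
      " noise:", sum(object@role == "noise"), "\n")
  cat("  k =", object@k, ", DCM threshold =",
      format(object@thresholdUsed, digits = 4), "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset ('", object@recipe$generator, "'): ",
      nrow(object@coords), " points in ", ncol(object@coords),
      " dimensions, ", length(setdiff(unique(object@labels), -1L)),
      " classes", sep = "")
  nn <- sum(object@labels == -1L)
  if (nn > 0) cat(" +", nn, "noise points")
  cat(", seed =", object@recipe$seed, "\n")
})
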