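#' @rdname RoiTimeSeries-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("regionIds", function(object) standardGeneric("regionIds"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("boldMatrix", function(object) standardGeneric("boldMatrix"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname SnapshotSequence-class
#' @param object an object.
#' @export
setGeneric("snapshotTimes", function(object) standardGeneric("snapshotTimes"))

#' @rdname SnapshotSequence-class
#' @export
setGeneric("snapshotMatrices", function(object) standardGeneric("snapshotMatrices"))

#' @rdname SnapshotSequence-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

setMethod("subjectId", "RoiTimeSeries", function(object) object@subjectId)
setMethod("regionIds", "RoiTimeSeries", function(object) object@regionIds)
setMethod("boldMatrix", "RoiTimeSeries", function(object) object@data)
setMethod("nRegions", "RoiTimeSeries", function(object) nrow(object@data))
setMethod("nVolumes", "RoiTimeSeries", function(object) ncol(object@data))

setMethod("subjectId", "SnapshotSequence", function(object) object@subjectId)
setMethod("snapshotTimes", "SnapshotSequence", function(object) object@times)
setMethod("snapshotMatrices", "SnapshotSequence", function(object) object@matrices)
setMethod("provenance", "SnapshotSequence", function(object) object@provenance)
setMethod("nVolumes", "SnapshotSequence", function(object) object@nVolumes)

#' @rdname SnapshotSequence-class
#' @export
setMethod("length", "SnapshotSequence", function(x) length(x@matrices))

#' @rdname SnapshotSequence-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SnapshotSequence", function(x, i, j, ..., drop = TRUE) {
  new("SnapshotSequence",
      subjectId = x@subjectId,
      times = x@times[i],
      matrices = x@matrices[i],
      provenance = x@provenance[i],
      nVolumes = x@nVolumes)
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d regions x %d volumes (TR %.2f s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@trSeconds))
})

setMethod("show", "SnapshotSequence", function(object) {
  tab <- table(factor(object@provenance, levels = c("observed", "in", "out")))
  cat(sprintf(
    "SnapshotSequence '%s': %d snapshots (%d observed, %d in, %d out), %d nodes, span [0, %g)\n",
    object@subjectId, length(object@matrices), tab[["observed"]], tab[["in"]],
    tab[["out"]], if (length(object@matrices)) nrow(object@matrices[[1]]) else 0L,
    object@nVolumes))
})

setMethod("show", "CouplingGraph", function(object) {
  m <- nrow(object@adjacency)
  ne <- sum(object@adjacency[upper.tri(object@adjacency)] > 0)
  cat(sprintf("CouplingGraph: %d nodes, %d weighted edges (density %.3f)\n",
              m, ne, ne / (m * (m - 1) / 2)))
})

setMethod("show", "NdcnModel", function(object) {
  cat(sprintf(
    "NdcnModel: %d nodes, hidden dim %d, solver %s (step %g), %s loss\n",
    nrow(object@x0), object@config@hiddenDim, object@config@odeSolver,
    object@config@stepSize, object@config@lossNorm))
  cat(sprintf("  trained on %d snapshots over [0, %g); final loss %.5g\n",
              length(object@trainTimes), object@timeSpan[2], object@finalLoss))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges\n", object@nNodes, nrow(object@edges)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: m=%d, T=%d, %d modules, within %.2f (+%.2f group), between %.2f, drift %s, noise sd %.2f, seed %d\n",
    object@m, object@T, object@nModules, object@withinCorr, object@groupEffect,
    object@betweenCorr, object@driftModel, object@noiseSd, object@seed))
})
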