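#' @import methods
#' @importFrom stats cor rnorm runif sd quantile predict setNames
#' @importFrom utils head read.table write.table
NULL

#' One subject's multi-region BOLD time series
#'
#' Container for an extracted region-of-interest (ROI) BOLD matrix:
#' \code{m} regions by \code{T} volumes, in arbitrary BOLD units. The object
#' starts where fMRI preprocessing ends; motion correction, normalization and
#' band-pass filtering are assumed to have been done upstream.
#'
#' @slot subjectId single subject identifier.
#' @slot regionIds unique region labels, one per row of \code{data}; row
#'   \code{i} of every downstream connectivity matrix refers to
#'   \code{regionIds[i]}.
#' @slot data numeric matrix, regions x volumes, all entries finite.
#' @slot trSeconds repetition time in seconds (metadata only; the internal
#'   time axis is the 0-based volume index).
#'
#' @seealso [readRoiSeries()], [buildObservedSnapshots()]
#' @export
setClass("RoiTimeSeries",
  slots = c(
    subjectId = "character",
    regionIds = "character",
    data      = "matrix",
    trSeconds = "numeric"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (nrow(object@data) < 2L) msg <- c(msg, "need at least 2 regions")
  if (ncol(object@data) < 2L) msg <- c(msg, "need at least 2 time points")
  if (length(object@regionIds) != nrow(object@data))
    msg <- c(msg, "regionIds length must equal nrow(data)")
  if (anyDuplicated(object@regionIds)) msg <- c(msg, "regionIds must be unique")
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Sliding-window scheme
#'
#' Window length \code{t} and moving step \code{s}, both in volumes, defining
#' how a BOLD series of length \code{T} is segmented into
#' \code{floor((T - t)/s) + 1} fully contained windows with starts
#' \code{0, s, 2s, ...} (half-open on a 0-based volume axis).
#'
#' @slot windowLength window length in volumes (>= 1).
#' @slot step moving step in volumes (>= 1).
#' @export
setClass("WindowScheme",
  slots = c(windowLength = "integer", step = "integer")
)

setValidity("WindowScheme", function(object) {
  msg <- character()
  if (length(object@windowLength) != 1L || is.na(object@windowLength) ||
      object@windowLength < 1L)
    msg <- c(msg, "windowLength must be a positive integer")
  if (length(object@step) != 1L || is.na(object@step) || object@step < 1L)
    msg <- c(msg, "step must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Time-ordered sequence of connectivity snapshots
#'
#' Holds square, symmetric connectivity matrices indexed by nominal time on
#' the volume axis, with per-snapshot provenance: \code{"observed"} (windowed
#' Pearson network), \code{"in"} (interpolated by the fitted continuous-time
#' model inside the acquisition window) or \code{"out"} (extrapolated beyond
#' it). Observed snapshots have unit diagonal and entries in [-1, 1].
#'
#' @slot subjectId subject identifier.
#' @slot times strictly increasing nominal times (volume units).
#' @slot matrices list of m x m numeric matrices, one per time.
#' @slot provenance character vector, one of observed/in/out per snapshot.
#' @slot nVolumes length of the underlying BOLD series in volumes (the
#'   acquisition span [0, nVolumes) separates interpolation from
#'   extrapolation).
#' @export
setClass("SnapshotSequence",
  slots = c(
    subjectId  = "character",
    times      = "numeric",
    matrices   = "list",
    provenance = "character",
    nVolumes   = "numeric"
  )
)

setValidity("SnapshotSequence", function(object) {
  msg <- character()
  n <- length(object@matrices)
  if (length(object@times) != n) msg <- c(msg, "times and matrices lengths differ")
  if (length(object@provenance) != n) msg <- c(msg, "provenance length mismatch")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (n > 0 && !all(object@provenance %in% c("observed", "in", "out")))
    msg <- c(msg, "provenance must be observed/in/out")
  dims <- vapply(object@matrices, function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) -1L else nrow(m)
  }, integer(1))
  if (n > 0 && (any(dims < 2L) || length(unique(dims)) > 1L))
    msg <- c(msg, "all snapshots must be square matrices of a common size >= 2")
  if (length(msg)) msg else TRUE
})

#' Static coupling graph for the graph-ODE operator
#'
#' The graph neural dynamics layer needs one static graph describing how
#' regions interact. It is summarized from the observed snapshots as the
#' proportionally thresholded mean absolute correlation, and carried together
#' with its symmetrically normalized diffusion operator
#' \eqn{D^{-1/2}(A + I)D^{-1/2}}.
#'
#' @slot adjacency non-negative symmetric m x m weight matrix, zero diagonal.
#' @slot operator normalized operator with self-loops; spectral norm <= 1.
#' @export
setClass("CouplingGraph",
  slots = c(adjacency = "matrix", operator = "matrix")
)

setValidity("CouplingGraph", function(object) {
  msg <- character()
  A <- object@adjacency
  P <- object@operator
  if (!isTRUE(all.equal(dim(A), dim(P)))) msg <- c(msg, "adjacency/operator shape mismatch")
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(A < 0)) msg <- c(msg, "adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-8) msg <- c(msg, "adjacency must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Configuration for the continuous-time network-dynamics model
#'
#' @slot hiddenDim width of the hidden space each node is encoded into.
#' @slot odeSolver one of \code{"euler"}, \code{"rk4"}.
#' @slot stepSize fixed solver step in volume units; must be smaller than the
#'   spacing between training snapshot times.
#' @slot epochs number of gradient-descent epochs.
#' @slot learningRate Adam learning rate.
#' @slot weightDecay L2 penalty on weights (0 disables).
#' @slot seed integer seed controlling weight initialization.
#' @slot lossNorm training loss, \code{"l1"} or \code{"l2"} (per-entry mean).
#' @slot activation \code{"tanh"} or \code{"linear"}, applied by the encoder
#'   and the hidden dynamics layer.
#' @slot terminalLossEnabled reserved hook for a terminal semantic-label loss;
#'   always \code{FALSE} here because no node labels enter this pipeline
#'   (classification happens downstream on graph features).
#' @export
setClass("NdcnConfig",
  slots = c(
    hiddenDim           = "integer",
    odeSolver           = "character",
    stepSize            = "numeric",
    epochs              = "integer",
    learningRate        = "numeric",
    weightDecay         = "numeric",
    seed                = "integer",
    lossNorm            = "character",
    activation          = "character",
    terminalLossEnabled = "logical"
  )
)

setValidity("NdcnConfig", function(object) {
  msg <- character()
  if (object@hiddenDim < 1L) msg <- c(msg, "hiddenDim must be >= 1")
  if (!object@odeSolver %in% c("euler", "rk4")) msg <- c(msg, "odeSolver must be euler or rk4")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be positive")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (!object@lossNorm %in% c("l1", "l2")) msg <- c(msg, "lossNorm must be l1 or l2")
  if (!object@activation %in% c("tanh", "linear"))
    msg <- c(msg, "activation must be tanh or linear")
  if (isTRUE(object@terminalLossEnabled))
    msg <- c(msg, "terminal loss is a disabled hook; no node labels exist in this pipeline")
  if (length(msg)) msg else TRUE
})

#' Fitted encoder / graph-ODE / decoder model
#'
#' @slot weights named list of weight matrices and biases: \code{We, be}
#'   (encoder), \code{Wh, bh} (hidden graph dynamics), \code{Wd, bd}
#'   (decoder).
#' @slot coupling the static [CouplingGraph-class] used by the dynamics layer.
#' @slot config the [NdcnConfig-class] the model was trained with.
#' @slot x0 initial snapshot the trajectory is integrated from.
#' @slot trainTimes snapshot times the running loss was evaluated at.
#' @slot timeSpan numeric length-2, the trained span [0, T) in volume units.
#' @slot timeScale volume units per internal model time unit. Training
#'   nondimensionalizes time by the snapshot spacing so trajectories evolve
#'   over order-one spans regardless of the window step; all user-facing
#'   times stay in volume units.
#' @slot finalLoss final training loss (per-entry mean, lossNorm scale).
#' @slot lossHistory per-epoch training loss.
#' @export
setClass("NdcnModel",
  slots = c(
    weights     = "list",
    coupling    = "CouplingGraph",
    config      = "NdcnConfig",
    x0          = "matrix",
    trainTimes  = "numeric",
    timeSpan    = "numeric",
    timeScale   = "numeric",
    finalLoss   = "numeric",
    lossHistory = "numeric"
  )
)

setValidity("NdcnModel", function(object) {
  need <- c("We", "be", "Wh", "bh", "Wd", "bd")
  msg <- character()
  if (!all(need %in% names(object@weights)))
    msg <- c(msg, paste("weights must contain", paste(need, collapse = ", ")))
  else if (!all(vapply(object@weights[need], function(w) all(is.finite(w)), logical(1))))
    msg <- c(msg, "all weights must be finite")
  if (length(object@timeSpan) != 2L || object@timeSpan[1] != 0)
    msg <- c(msg, "timeSpan must be c(0, T)")
  if (length(msg)) msg else TRUE
})

#' Unweighted simple graph obtained by thresholding a snapshot
#'
#' @slot nNodes number of nodes m.
#' @slot edges integer matrix with two columns (i, j), 1-based, i < j,
#'   no self-loops, no duplicates.
#' @export
setClass("BinaryGraph",
  slots = c(nNodes = "integer", edges = "matrix")
)

setValidity("BinaryGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0) {
    if (any(e < 1L) || any(e > object@nNodes)) msg <- c(msg, "edge endpoints out of range")
    if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must satisfy i < j")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Specification for the synthetic BOLD generator
#'
#' Describes a modular, optionally time-varying covariance from which
#' multi-region BOLD series are drawn, with a group-level shift of the
#' within-module correlation so that downstream network clustering differs
#' between simulated diagnostic groups in a controlled way.
#'
#' @slot m number of regions.
#' @slot T number of volumes.
#' @slot nModules number of covariance modules (contiguous region blocks).
#' @slot withinCorr correlation inside a module, in (-1, 1).
#' @slot betweenCorr correlation across modules, in (-1, 1).
#' @slot driftModel \code{"static"}, \code{"linear_mixing"} (the module
#'   partition slowly mixes toward a shifted partition) or
#'   \code{"oscillatory"} (within-module correlation oscillates).
#' @slot groupEffect additive shift applied to withinCorr for a group.
#' @slot noiseSd standard deviation of additive observation noise
#'   (signal variance is 1, so noiseSd = 0.2 attenuates correlations by
#'   about 4 percent).
#' @slot seed integer seed; generation is bit-reproducible given the seed.
#' @export
setClass("SyntheticSpec",
  slots = c(
    m = "integer", T = "integer", nModules = "integer",
    withinCorr = "numeric", betweenCorr = "numeric",
    driftModel = "character", groupEffect = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@m < 2L) msg <- c(msg, "m must be >= 2")
  if (object@T < 2L) msg <- c(msg, "T must be >= 2")
  if (object@nModules < 1L || object@nModules > object@m)
    msg <- c(msg, "nModules must be in [1, m]")
  w <- object@withinCorr + object@groupEffect
  if (abs(object@withinCorr) >= 1 || abs(object@betweenCorr) >= 1 || abs(w) >= 1)
    msg <- c(msg, "correlations (including group effect) must lie in (-1, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@driftModel %in% c("static", "linear_mixing", "oscillatory"))
    msg <- c(msg, "driftModel must be static, linear_mixing or oscillatory")
  if (length(msg)) msg else TRUE
})
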