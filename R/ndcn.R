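#' Configuration constructor for the continuous-time dynamics model
#'
#' Defaults are sized for single-CPU, desk-scale problems (tens of regions):
#' hidden width 16, fourth-order fixed-step solver with step 0.2 volume
#' units, 300 Adam epochs at learning rate 0.02, L1 running loss.
#'
#' @param hiddenDim hidden width per node.
#' @param odeSolver "rk4" (default) or "euler".
#' @param stepSize fixed solver step, volume units; must stay below the
#'   spacing between training snapshot times.
#' @param epochs training epochs.
#' @param learningRate Adam step size.
#' @param weightDecay L2 weight penalty.
#' @param seed seed for weight initialization.
#' @param lossNorm "l1" (default) or "l2"; per-entry mean over snapshots.
#' @param activation "tanh" (default) or "linear"; applied by the encoder and
#'   the hidden dynamics layer. The linear variant turns the model into pure
#'   graph-linear dynamics, useful for analytic checks.
#' @return an [NdcnConfig-class].
#' @export
ndcnConfig <- function(hiddenDim = 16L, odeSolver = "rk4", stepSize = 0.2,
                       epochs = 300L, learningRate = 0.02, weightDecay = 1e-4,
                       seed = 1L, lossNorm = "l1", activation = "tanh") {
  new("NdcnConfig", hiddenDim = as.integer(hiddenDim), odeSolver = odeSolver,
      stepSize = as.numeric(stepSize), epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay), seed = as.integer(seed),
      lossNorm = lossNorm, activation = activation,
      terminalLossEnabled = FALSE)
}

#' Build the static coupling graph from observed snapshots
#'
#' The graph dynamics layer needs one static interaction graph. It is taken
#' as the element-wise mean of the observed absolute correlation matrices,
#' proportionally thresholded to keep the strongest \code{density} fraction
#' of off-diagonal weights, then symmetrized. The diffusion operator is the
#' renormalized \eqn{D^{-1/2}(A + I)D^{-1/2}} with D the degree matrix of
#' A + I, whose spectral norm is at most 1.
#'
#' @param sequence a [SnapshotSequence-class] of observed snapshots.
#' @param density fraction of off-diagonal weights kept, in (0, 1].
#' @return a [CouplingGraph-class].
#' @export
buildCouplingGraph <- function(sequence, density = 0.15) {
  stopifnot(is(sequence, "SnapshotSequence"))
  if (length(sequence) == 0L) stop("empty snapshot sequence")
  stopifnot(density > 0, density <= 1)
  A <- Reduce(`+`, lapply(sequence@matrices, abs)) / length(sequence)
  diag(A) <- 0
  A <- symm(A)
  m <- nrow(A)
  ut <- which(upper.tri(A))
  k <- max(1L, floor(density * length(ut) + 1e-9))
  w <- A[ut]
  ord <- order(-w, ut)          # ties broken by linear (column-major) index
  keep <- ut[ord[seq_len(min(k, length(ut)))]]
  Athr <- matrix(0, m, m)
  Athr[keep] <- A[keep]
  Athr <- Athr + t(Athr)
  Ahat <- Athr + diag(m)
  d <- rowSums(Ahat)
  Dinv <- 1 / sqrt(d)
  P <- Ahat * outer(Dinv, Dinv)
  new("CouplingGraph", adjacency = Athr, operator = P)
}

# row-broadcast bias add
.addBias <- function(M, b) M + rep(b, each = nrow(M))

# hidden-space dynamics f(H) = act(P H Wh + bh)
.rhs <- function(H, P, Wh, bh, act = "tanh") {
  A <- .addBias(P %*% H %*% Wh, bh)
  if (act == "tanh") tanh(A) else A
}

# vector-Jacobian product of .rhs at H with cotangent G.
# t(P) appears because nothing guarantees callers pass a symmetric operator.
.rhsVjp <- function(H, G, P, Wh, bh, act = "tanh") {
  PH <- P %*% H
  S <- if (act == "tanh") {
    Th <- tanh(.addBias(PH %*% Wh, bh))
    (1 - Th * Th) * G
  } else G
  list(dH = t(P) %*% (S %*% t(Wh)),
       dWh = crossprod(PH, S),
       dbh = colSums(S))
}

#' Instantaneous hidden-space change rate
#'
#' Evaluates the governing dynamics of the hidden state,
#' \eqn{dX_h/dt = \tanh(\Phi X_h W_h + b_h)}, where \eqn{\Phi} is the
#' normalized coupling operator.
#'
#' @param model an [NdcnModel-class] (only its dynamics weights and coupling
#'   operator are used).
#' @param hiddenState m x hiddenDim matrix.
#' @return matrix of the same shape.
#' @export
ndcnRhs <- function(model, hiddenState) {
  P <- model@coupling@operator
  if (nrow(hiddenState) != nrow(P) ||
      ncol(hiddenState) != ncol(model@weights$Wh))
    stop("hiddenState shape does not match model (expected ",
         nrow(P), " x ", ncol(model@weights$Wh), ")")
  .rhs(hiddenState, P, model@weights$Wh, model@weights$bh,
       model@config@activation)
}

# integration grid covering [0, max(times)] at step h, with all requested
# times inserted as grid nodes
.makeGrid <- function(times, h) {
  tmax <- max(times, 0)
  g <- sort(unique(c(0, times, seq(0, tmax, by = h))))
  keep <- c(TRUE, diff(g) > 1e-9)
  g[keep]
}

.matchTimes <- function(grid, times) {
  vapply(times, function(tt) {
    i <- which.min(abs(grid - tt))
    if (abs(grid[i] - tt) > 1e-6) stop("internal: time not on grid")
    i
  }, integer(1))
}

# forward pass: encode x0, integrate the hidden state over the grid, return
# hidden states at every grid node (list) for use by decode/backward
.forwardHidden <- function(w, P, x0, grid, solver, act = "tanh") {
  A0 <- .addBias(x0 %*% w$We, w$be)
  H <- if (act == "tanh") tanh(A0) else A0
  states <- vector("list", length(grid))
  states[[1]] <- H
  for (n in seq_len(length(grid) - 1L)) {
    dt <- grid[n + 1L] - grid[n]
    if (solver == "euler") {
      H <- H + dt * .rhs(H, P, w$Wh, w$bh, act)
    } else {
      k1 <- .rhs(H, P, w$Wh, w$bh, act)
      k2 <- .rhs(H + dt / 2 * k1, P, w$Wh, w$bh, act)
      k3 <- .rhs(H + dt / 2 * k2, P, w$Wh, w$bh, act)
      k4 <- .rhs(H + dt * k3, P, w$Wh, w$bh, act)
      H <- H + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(H)))
      stop("solver diverged at t = ", grid[n + 1L],
           "; reduce learningRate or stepSize")
    states[[n + 1L]] <- H
  }
  states
}

# reverse-mode step through one solver step Hn -> Hn+1 of size dt.
# gbar is dL/dH_{n+1}; returns dL/dHn plus dynamics-weight gradients.
.stepVjp <- function(Hn, dt, gbar, P, Wh, bh, solver, act = "tanh") {
  if (solver == "euler") {
    v <- .rhsVjp(Hn, dt * gbar, P, Wh, bh, act)
    return(list(dH = gbar + v$dH, dWh = v$dWh, dbh = v$dbh))
  }
  k1 <- .rhs(Hn, P, Wh, bh, act)
  u2 <- Hn + dt / 2 * k1
  k2 <- .rhs(u2, P, Wh, bh, act)
  u3 <- Hn + dt / 2 * k2
  k3 <- .rhs(u3, P, Wh, bh, act)
  u4 <- Hn + dt * k3

  bk1 <- dt / 6 * gbar
  bk2 <- dt / 3 * gbar
  bk3 <- dt / 3 * gbar
  bk4 <- dt / 6 * gbar
  dH <- gbar
  v4 <- .rhsVjp(u4, bk4, P, Wh, bh, act)
  dH <- dH + v4$dH; bk3 <- bk3 + dt * v4$dH
  v3 <- .rhsVjp(u3, bk3, P, Wh, bh, act)
  dH <- dH + v3$dH; bk2 <- bk2 + dt / 2 * v3$dH
  v2 <- .rhsVjp(u2, bk2, P, Wh, bh, act)
  dH <- dH + v2$dH; bk1 <- bk1 + dt / 2 * v2$dH
  v1 <- .rhsVjp(Hn, bk1, P, Wh, bh, act)
  dH <- dH + v1$dH
  list(dH = dH,
       dWh = v1$dWh + v2$dWh + v3$dWh + v4$dWh,
       dbh = v1$dbh + v2$dbh + v3$dbh + v4$dbh)
}

# running loss and its gradient for the whole trajectory
.lossGrad <- function(w, P, x0, obsTimes, obsMats, solver, h, lossNorm,
                      act = "tanh", wantGrad = TRUE) {
  grid <- .makeGrid(obsTimes, h)
  idx <- .matchTimes(grid, obsTimes)
  states <- .forwardHidden(w, P, x0, grid, solver, act)
  nObs <- length(obsTimes)
  nEntries <- length(x0)
  loss <- 0
  dXhat <- vector("list", nObs)
  for (q in seq_len(nObs)) {
    Xhat <- .addBias(states[[idx[q]]] %*% w$Wd, w$bd)
    R <- Xhat - obsMats[[q]]
    if (lossNorm == "l1") {
      loss <- loss + mean(abs(R))
      if (wantGrad) dXhat[[q]] <- sign(R) / (nEntries * nObs)
    } else {
      loss <- loss + mean(R * R)
      if (wantGrad) dXhat[[q]] <- 2 * R / (nEntries * nObs)
    }
  }
  loss <- loss / nObs
  if (!wantGrad) return(list(loss = loss))

  g <- list(We = 0 * w$We, be = 0 * w$be, Wh = 0 * w$Wh, bh = 0 * w$bh,
            Wd = 0 * w$Wd, bd = 0 * w$bd)
  lam <- matrix(0, nrow(states[[1]]), ncol(states[[1]]))
  obsAt <- integer(length(grid)); obsAt[idx] <- seq_len(nObs)
  for (n in rev(seq_along(grid))) {
    if (obsAt[n] > 0L) {
      dX <- dXhat[[obsAt[n]]]
      g$Wd <- g$Wd + crossprod(states[[n]], dX)
      g$bd <- g$bd + colSums(dX)
      lam <- lam + dX %*% t(w$Wd)
    }
    if (n > 1L) {
      dt <- grid[n] - grid[n - 1L]
      v <- .stepVjp(states[[n - 1L]], dt, lam, P, w$Wh, w$bh, solver, act)
      lam <- v$dH
      g$Wh <- g$Wh + v$dWh
      g$bh <- g$bh + v$dbh
    }
  }
  S <- if (act == "tanh") (1 - states[[1]]^2) * lam else lam
  g$We <- g$We + crossprod(x0, S)
  g$be <- g$be + colSums(S)
  list(loss = loss, grad = g)
}

# Encoder and decoder start random; the dynamics layer starts at zero so the
# initial trajectory is constant (tanh(0) = 0) and training grows dynamics
# from a well-posed stationary start instead of an arbitrarily drifting one.
.initWeights <- function(m, d, seed) {
  withr::with_seed(seed, {
    list(We = matrix(rnorm(m * d, sd = 1 / sqrt(m)), m, d),
         be = rep(0, d),
         Wh = matrix(0, d, d),
         bh = rep(0, d),
         Wd = matrix(rnorm(d * m, sd = 1 / sqrt(d)), d, m),
         bd = rep(0, m))
  })
}

#' Fit the continuous-time network-dynamics model
#'
#' Learns encoder, hidden graph dynamics and decoder weights by minimizing
#' the running loss: the mean per-entry discrepancy (L1 or L2 per
#' \code{config}) between the decoded trajectory at the observed snapshot
#' times and the observed correlation matrices. The trajectory is obtained
#' by solving the hidden-space initial value problem with a fixed-step
#' solver; gradients flow by reverse accumulation through the unrolled
#' solver and weights are updated with Adam (gradient norm clipped at 5).
#' Internally, time is nondimensionalized by the median snapshot spacing so
#' the trajectory evolves over an order-one span whatever the window step;
#' every user-facing time stays in volume units. The dynamics layer is
#' initialized at zero (constant initial trajectory) and the decoder bias at
#' the mean observed pattern, a stationary warm start. The optional terminal
#' label loss is a disabled hook: no node labels exist in this pipeline.
#'
#' @param sequence observed [SnapshotSequence-class] with at least 3
#'   snapshots.
#' @param coupling a [CouplingGraph-class]; built from the sequence at the
#'   default density when NULL.
#' @param config an [NdcnConfig-class].
#' @return a fitted [NdcnModel-class]. Deterministic given the config seed.
#' @export
fitNdcn <- function(sequence, coupling = NULL, config = ndcnConfig()) {
  stopifnot(is(sequence, "SnapshotSequence"), is(config, "NdcnConfig"))
  obs <- which(sequence@provenance == "observed")
  if (length(obs) < 3L) stop("need at least 3 observed snapshots")
  obsTimes <- sequence@times[obs]
  obsMats <- sequence@matrices[obs]
  timeScale <- stats::median(diff(obsTimes))
  scaledTimes <- obsTimes / timeScale
  if (config@stepSize >= min(diff(scaledTimes)))
    stop("stepSize must be smaller than the minimum scaled snapshot spacing (",
         signif(min(diff(scaledTimes)), 3), ")")
  if (is.null(coupling)) coupling <- buildCouplingGraph(sequence)
  P <- coupling@operator
  m <- nrow(P)
  x0 <- obsMats[[1]]
  w <- .initWeights(m, config@hiddenDim, config@seed)
  w$bd <- colMeans(Reduce(`+`, obsMats) / length(obsMats))

  adamM <- lapply(w, function(x) 0 * x)
  adamV <- lapply(w, function(x) 0 * x)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config@learningRate
  hist <- numeric(config@epochs)
  for (ep in seq_len(config@epochs)) {
    lg <- .lossGrad(w, P, x0, scaledTimes, obsMats, config@odeSolver,
                    config@stepSize, config@lossNorm, config@activation)
    if (!is.finite(lg$loss))
      stop("training loss became non-finite at epoch ", ep,
           "; reduce learningRate or stepSize")
    hist[ep] <- lg$loss
    g <- lg$grad
    if (config@weightDecay > 0)
      for (nm in names(g)) g[[nm]] <- g[[nm]] + config@weightDecay * w[[nm]]
    gnorm <- sqrt(sum(vapply(g, function(x) sum(x * x), numeric(1))))
    if (gnorm > 5) g <- lapply(g, function(x) x * (5 / gnorm))
    for (nm in names(w)) {
      adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g[[nm]]
      adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- adamM[[nm]] / (1 - b1^ep)
      vh <- adamV[[nm]] / (1 - b2^ep)
      w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  finalLoss <- .lossGrad(w, P, x0, scaledTimes, obsMats, config@odeSolver,
                         config@stepSize, config@lossNorm, config@activation,
                         wantGrad = FALSE)$loss
  bdLog("fitNdcn: %d snapshots, %d epochs, final %s loss %.5g",
        length(obs), config@epochs, config@lossNorm, finalLoss)
  new("NdcnModel", weights = w, coupling = coupling, config = config,
      x0 = x0, trainTimes = obsTimes, timeScale = timeScale,
      timeSpan = c(0, sequence@nVolumes), finalLoss = finalLoss,
      lossHistory = hist)
}

#' Integrate a model trajectory and decode it at requested times
#'
#' Encodes \code{x0}, solves the hidden-space initial value problem from
#' time 0 through all requested times with the model's solver, and decodes
#' each state back to a connectivity matrix.
#'
#' @param model an [NdcnModel-class].
#' @param x0 initial m x m matrix; defaults to the matrix the model was
#'   trained from.
#' @param times non-negative, increasing times (volume units).
#' @return list of decoded m x m matrices, one per time.
#' @export
ndcnIntegrate <- function(model, x0 = model@x0, times) {
  if (length(times) == 0L) return(list())
  stopifnot(all(is.finite(times)), all(times >= 0), !is.unsorted(times))
  w <- model@weights
  scale <- if (length(model@timeScale) == 1L && is.finite(model@timeScale) &&
               model@timeScale > 0) model@timeScale else 1
  times <- times / scale
  grid <- .makeGrid(times, model@config@stepSize)
  idx <- .matchTimes(grid, times)
  states <- .forwardHidden(w, model@coupling@operator, x0, grid,
                           model@config@odeSolver, model@config@activation)
  lapply(idx, function(n) .addBias(states[[n]] %*% w$Wd, w$bd))
}

#' Interpolated snapshots inside the acquisition window
#'
#' Queries the fitted continuous-time system at times within the trained
#' span [0, T): the "in-snapshots". By default one snapshot per integer
#' volume index, so a 140-volume series yields 140 in-snapshots. Decoded
#' matrices are symmetrized as (M + t(M))/2.
#'
#' @param model a fitted [NdcnModel-class].
#' @param times query times; default \code{0:(T-1)}.
#' @param subjectId identifier for the returned sequence.
#' @return a [SnapshotSequence-class] with provenance "in".
#' @export
predictInSnapshots <- function(model, times = NULL, subjectId = "subject") {
  Tspan <- model@timeSpan[2]
  if (is.null(times)) times <- seq(0, ceiling(Tspan) - 1)
  if (length(times) == 0L)
    return(new("SnapshotSequence", subjectId = subjectId, times = numeric(),
               matrices = list(), provenance = character(), nVolumes = Tspan))
  if (any(times >= Tspan))
    stop("time(s) beyond the trained span [0, ", Tspan,
         "); use predictOutSnapshots for extrapolation")
  if (any(times < 0)) stop("times must be >= 0")
  mats <- lapply(ndcnIntegrate(model, times = times), symm)
  new("SnapshotSequence", subjectId = subjectId, times = as.numeric(times),
      matrices = mats, provenance = rep("in", length(mats)),
      nVolumes = Tspan)
}

#' Extrapolated snapshots beyond the acquisition window
#'
#' Integrates the fitted system past the trained span for \code{horizon}
#' additional unit (volume) steps: the "out-snapshots", at times
#' T, T+1, ..., T+horizon-1. Decoded matrices are symmetrized and clamped to
#' [-1, 1], since extrapolated correlations may drift outside the valid
#' range.
#'
#' @param model a fitted [NdcnModel-class].
#' @param horizon number of unit steps beyond the trained span (>= 0).
#' @param subjectId identifier for the returned sequence.
#' @return a [SnapshotSequence-class] with provenance "out".
#' @export
predictOutSnapshots <- function(model, horizon = 70L, subjectId = "subject") {
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 0L)
  Tspan <- model@timeSpan[2]
  if (horizon == 0L)
    return(new("SnapshotSequence", subjectId = subjectId, times = numeric(),
               matrices = list(), provenance = character(), nVolumes = Tspan))
  times <- Tspan + seq_len(horizon) - 1
  mats <- lapply(ndcnIntegrate(model, times = times),
                 function(M) pmax(pmin(symm(M), 1), -1))
  new("SnapshotSequence", subjectId = subjectId, times = as.numeric(times),
      matrices = mats, provenance = rep("out", length(mats)),
      nVolumes = Tspan)
}

#' Save / load a fitted model as a structured JSON archive
#'
#' @param model an [NdcnModel-class].
#' @param path file path (.json).
#' @return \code{saveNdcnModel}: the path, invisibly; \code{loadNdcnModel}:
#'   the restored model. Loading rejects archives with a different schema
#'   version.
#' @export
saveNdcnModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    schema = "braindynet-ndcn-1",
    weights = lapply(model@weights, function(x)
      if (is.matrix(x)) list(dim = dim(x), values = as.numeric(x))
      else list(dim = NULL, values = as.numeric(x))),
    adjacency = list(dim = dim(model@coupling@adjacency),
                     values = as.numeric(model@coupling@adjacency)),
    config = list(hiddenDim = cfg@hiddenDim, odeSolver = cfg@odeSolver,
                  stepSize = cfg@stepSize, epochs = cfg@epochs,
                  learningRate = cfg@learningRate,
                  weightDecay = cfg@weightDecay, seed = cfg@seed,
                  lossNorm = cfg@lossNorm, activation = cfg@activation),
    x0 = list(dim = dim(model@x0), values = as.numeric(model@x0)),
    trainTimes = model@trainTimes, timeSpan = model@timeSpan,
    timeScale = if (length(model@timeScale)) model@timeScale else 1,
    finalLoss = model@finalLoss, lossHistory = model@lossHistory)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveNdcnModel
#' @export
loadNdcnModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "braindynet-ndcn-1"))
    stop("unsupported model schema: ", obj$schema)
  restore <- function(slot) {
    if (is.null(slot$dim) || length(slot$dim) == 0)
      as.numeric(slot$values)
    else matrix(as.numeric(slot$values), slot$dim[1], slot$dim[2])
  }
  w <- lapply(obj$weights, restore)
  A <- restore(obj$adjacency)
  m <- nrow(A)
  Ahat <- A + diag(m)
  Dinv <- 1 / sqrt(rowSums(Ahat))
  cfg <- ndcnConfig(hiddenDim = obj$config$hiddenDim,
                    odeSolver = obj$config$odeSolver,
                    stepSize = obj$config$stepSize, epochs = obj$config$epochs,
                    learningRate = obj$config$learningRate,
                    weightDecay = obj$config$weightDecay,
                    seed = obj$config$seed, lossNorm = obj$config$lossNorm,
                    activation = obj$config$activation)
  new("NdcnModel", weights = w,
      coupling = new("CouplingGraph", adjacency = A,
                     operator = Ahat * outer(Dinv, Dinv)),
      config = cfg, x0 = restore(obj$x0),
      trainTimes = as.numeric(obj$trainTimes),
      timeSpan = as.numeric(obj$timeSpan),
      timeScale = as.numeric(obj$timeScale),
      finalLoss = as.numeric(obj$finalLoss),
      lossHistory = as.numeric(obj$lossHistory))
}
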