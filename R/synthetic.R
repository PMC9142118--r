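#' Construct a synthetic-data specification
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' test suite: 30 regions, 140 volumes (matching a typical resting-state
#' acquisition length), 3 covariance modules with within-module correlation
#' 0.6 and between-module correlation 0.1, static drift, mild observation
#' noise (sd 0.2 on unit-variance signal).
#'
#' @param m,T,nModules,withinCorr,betweenCorr,driftModel,groupEffect,noiseSd,seed
#'   see [SyntheticSpec-class].
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(m = 30L, T = 140L, nModules = 3L, withinCorr = 0.6,
                          betweenCorr = 0.1, driftModel = "static",
                          groupEffect = 0, noiseSd = 0.2, seed = 1L) {
  new("SyntheticSpec", m = as.integer(m), T = as.integer(T),
      nModules = as.integer(nModules), withinCorr = as.numeric(withinCorr),
      betweenCorr = as.numeric(betweenCorr), driftModel = driftModel,
      groupEffect = as.numeric(groupEffect), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# contiguous module assignment of m regions into k blocks; offset rotates
# the block boundaries (used by linear_mixing)
.moduleAssign <- function(m, k, offset = 0L) {
  base <- rep(seq_len(k), each = ceiling(m / k))[seq_len(m)]
  if (offset > 0L) base <- base[((seq_len(m) - 1L + offset) %% m) + 1L]
  base
}

# block correlation matrix: w within modules, b between, unit diagonal
.blockCorr <- function(assign, w, b) {
  S <- outer(assign, assign, function(a, bb) ifelse(a == bb, w, b))
  diag(S) <- 1
  S
}

.checkPsd <- function(S, what) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("covariance not positive semi-definite (min eigenvalue ",
         signif(ev, 3), ") for ", what)
  ev
}

# per-volume correlation matrices implied by a spec
.covSeries <- function(spec) {
  w <- spec@withinCorr + spec@groupEffect
  b <- spec@betweenCorr
  assignA <- .moduleAssign(spec@m, spec@nModules)
  T <- spec@T
  if (spec@driftModel == "static") {
    S <- .blockCorr(assignA, w, b)
    .checkPsd(S, sprintf("within=%.2f between=%.2f m=%d k=%d", w, b,
                         spec@m, spec@nModules))
    rep(list(S), T)
  } else if (spec@driftModel == "linear_mixing") {
    assignB <- .moduleAssign(spec@m, spec@nModules,
                             offset = as.integer(floor(spec@m / (2 * spec@nModules))))
    SA <- .blockCorr(assignA, w, b)
    SB <- .blockCorr(assignB, w, b)
    .checkPsd(SA, "endpoint A"); .checkPsd(SB, "endpoint B")
    lapply(seq_len(T), function(tt) {
      a <- (tt - 1) / (T - 1)
      (1 - a) * SA + a * SB       # convex mix of PSD matrices stays PSD
    })
  } else {  # oscillatory
    amp <- 0.15
    period <- 40
    lapply(seq_len(T), function(tt) {
      wt <- w + amp * sin(2 * pi * (tt - 1) / period)
      S <- .blockCorr(assignA, wt, b)
      .checkPsd(S, sprintf("oscillatory w(t)=%.2f at t=%d", wt, tt - 1L))
      S
    })
  }
}

#' Generate one synthetic subject
#'
#' Draws each volume as an independent sample from the spec's (possibly
#' time-varying) modular correlation matrix, then adds white observation
#' noise. Independence across volumes is deliberate: windowed Pearson
#' networks estimate the instantaneous covariance, which is what the
#' pipeline consumes. Bit-reproducible given the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param subjectId identifier for the returned series.
#' @return an [RoiTimeSeries-class] of dimension m x T.
#' @export
generateSubject <- function(spec, subjectId = "sim") {
  stopifnot(is(spec, "SyntheticSpec"))
  covs <- .covSeries(spec)
  m <- spec@m
  data <- withr::with_seed(spec@seed, {
    static <- spec@driftModel == "static"
    Ls <- if (static) list(t(chol(covs[[1]] + 1e-10 * diag(m))))
          else lapply(covs, function(S) t(chol(S + 1e-10 * diag(m))))
    Z <- matrix(rnorm(m * spec@T), m, spec@T)
    X <- vapply(seq_len(spec@T), function(tt) {
      L <- if (static) Ls[[1]] else Ls[[tt]]
      as.numeric(L %*% Z[, tt])
    }, numeric(m))
    X + spec@noiseSd * matrix(rnorm(m * spec@T), m, spec@T)
  })
  RoiTimeSeries(data, subjectId = subjectId,
                regionIds = sprintf("ROI%03d", seq_len(m)))
}

#' Generate a labeled synthetic cohort on disk
#'
#' Writes one BOLD TSV per subject plus a manifest. Each group applies its
#' own within-module correlation shift, so downstream clustering-coefficient
#' features differ between groups by a controlled amount. Subject seeds are
#' derived deterministically from the spec seed.
#'
#' @param spec base [SyntheticSpec-class] (its groupEffect is overridden per
#'   group).
#' @param nPerGroup subjects per group.
#' @param groups named numeric vector: group label -> groupEffect.
#' @param dir output directory (created).
#' @return path of the written manifest.
#' @export
generateCohort <- function(spec, nPerGroup = 10L,
                           groups = c(NC = 0, AD = -0.2), dir) {
  stopifnot(nPerGroup >= 1L, length(groups) >= 1L, !is.null(names(groups)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(nPerGroup)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", g, i)
      sspec <- syntheticSpec(m = spec@m, T = spec@T, nModules = spec@nModules,
                             withinCorr = spec@withinCorr,
                             betweenCorr = spec@betweenCorr,
                             driftModel = spec@driftModel,
                             groupEffect = groups[[g]], noiseSd = spec@noiseSd,
                             seed = spec@seed + 7919L * k)
      f <- file.path(dir, paste0(sid, ".tsv"))
      writeRoiSeries(generateSubject(sspec, subjectId = sid), f)
      rows[[k]] <- data.frame(subject_id = sid, group = g,
                              path = basename(f))
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  writeManifest(manifest, mpath)
  bdLog("cohort written to %s: %d subjects, groups {%s}", dir, k,
        paste(names(groups), collapse = ", "))
  mpath
}

#' Ground-truth snapshot dynamics with a closed-form trajectory
#'
#' Simulates symmetric matrix-valued graph diffusion
#' \eqn{dX/dt = -(\beta/2)(L X + X L)} on a random connected graph with
#' Laplacian L, whose exact solution is
#' \eqn{X(t) = e^{-\beta L t/2} X_0 e^{-\beta L t/2}} (computed by
#' eigendecomposition). Returns observed snapshots at unit-spaced times plus
#' an evaluator giving the exact state at any time, which serves as the
#' oracle in dynamics-recovery tests.
#'
#' @param m number of nodes (>= 2).
#' @param nObs number of observed snapshots (at times 0, 1, ..., nObs-1).
#' @param seed integer seed for the graph, the initial matrix and the
#'   observation noise.
#' @param beta diffusion rate; the default scales the decay so roughly half
#'   of the transient happens inside the observed span.
#' @param noiseSd standard deviation of white observation noise added to the
#'   emitted snapshots (the evaluator stays exact); the default emulates
#'   small estimation noise so that more training snapshots genuinely carry
#'   more information.
#' @return list with \code{sequence} (a [SnapshotSequence-class],
#'   provenance "observed"), \code{exact} (function(t) -> m x m matrix) and
#'   \code{laplacian}.
#' @export
generateDynamicsTruth <- function(m = 5L, nObs = 10L, seed = 1L, beta = NULL,
                                  noiseSd = 0.02) {
  stopifnot(m >= 2L, nObs >= 2L, noiseSd >= 0)
  out <- withr::with_seed(seed, {
    repeat {
      A <- matrix(0, m, m)
      A[upper.tri(A)] <- as.numeric(runif(m * (m - 1) / 2) < 0.5)
      A <- A + t(A)
      if (all(colSums(A) > 0) &&
          igraph::is_connected(igraph::graph_from_adjacency_matrix(
            A, mode = "undirected"))) break
    }
    X0 <- matrix(runif(m * m, -0.5, 0.5), m, m)
    X0 <- symm(X0)
    diag(X0) <- 1
    list(A = A, X0 = X0)
  })
  L <- diag(colSums(out$A)) - out$A
  eg <- eigen(L, symmetric = TRUE)
  span <- nObs - 1
  if (is.null(beta)) beta <- 3 / (max(eg$values) * span)
  exact <- function(tt) {
    E <- eg$vectors %*% diag(exp(-beta * eg$values * tt / 2)) %*% t(eg$vectors)
    E %*% out$X0 %*% E
  }
  times <- seq(0, span)
  mats <- lapply(times, exact)
  if (noiseSd > 0)
    mats <- withr::with_seed(seed + 1L, lapply(mats, function(M)
      M + matrix(rnorm(m * m, sd = noiseSd), m, m)))
  list(sequence = new("SnapshotSequence", subjectId = "truth",
                      times = as.numeric(times), matrices = mats,
                      provenance = rep("observed", length(mats)),
                      nVolumes = as.numeric(nObs)),
       exact = exact, laplacian = L, beta = beta)
}
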