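bdVerbose(FALSE)

# BinaryGraph from an edge list given as a 2-column matrix (1-based)
makeGraph <- function(m, edges) {
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
  storage.mode(e) <- "integer"
  new("BinaryGraph", nNodes = as.integer(m), edges = e)
}

igraphToGraph <- function(ig, m = igraph::vcount(ig)) {
  makeGraph(m, igraph::as_edgelist(igraph::simplify(ig), names = FALSE))
}

adjacencyOf <- function(g) {
  A <- matrix(0L, g@nNodes, g@nNodes)
  A[g@edges] <- 1L
  A[g@edges[, c(2, 1), drop = FALSE]] <- 1L
  A
}

# independent transitivity oracle: triple enumeration
bruteClustering <- function(g) {
  A <- adjacencyOf(g)
  m <- nrow(A)
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(0)
  tri <- 0
  for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m)
    if (A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1
  3 * tri / triples
}

# independent path-length oracle: BFS over pairs, largest component
brutePathLength <- function(g) {
  A <- adjacencyOf(g)
  m <- nrow(A)
  bfs <- function(s) {
    d <- rep(Inf, m); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(A[v, ] > 0 & d > d[v] + 1)
      d[nb] <- d[v] + 1
      q <- c(q, nb)
    }
    d
  }
  D <- t(vapply(seq_len(m), bfs, numeric(m)))
  comp <- rep(NA_integer_, m); cid <- 0
  for (s in seq_len(m)) if (is.na(comp[s])) {
    cid <- cid + 1
    comp[is.finite(D[s, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  dd <- D[big, big][upper.tri(D[big, big])]
  mean(dd)
}

# hand-built model wrapper for analytic integrator checks
analyticModel <- function(m, d, operator, Wh, solver = "rk4", h = 0.2,
                          activation = "linear") {
  cg <- new("CouplingGraph", adjacency = matrix(0, m, m), operator = operator)
  w <- list(We = diag(1, m, d), be = rep(0, d), Wh = Wh, bh = rep(0, d),
            Wd = diag(1, d, m), bd = rep(0, m))
  cfg <- ndcnConfig(hiddenDim = d, odeSolver = solver, stepSize = h,
                    activation = activation)
  new("NdcnModel", weights = w, coupling = cg, config = cfg, x0 = diag(m),
      trainTimes = c(0, 1), timeSpan = c(0, 2), timeScale = 1,
      finalLoss = 0, lossHistory = 0)
}

randomSeries <- function(m, T, seed) {
  withr::with_seed(seed, RoiTimeSeries(matrix(rnorm(m * T), m, T)))
}
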