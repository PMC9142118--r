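#' Threshold a snapshot into an unweighted graph
#'
#' Proportional thresholding: the strongest \code{density} fraction of
#' off-diagonal absolute weights become edges. Ties at the cutoff are broken
#' by (row, column) lexicographic order of the upper-triangle pair, so the
#' edge set is identical on every run.
#'
#' @param snapshot square symmetric numeric matrix (a connectivity
#'   snapshot).
#' @param density fraction of possible edges kept, in (0, 1].
#' @return a [BinaryGraph-class].
#' @export
binarizeSnapshot <- function(snapshot, density = 0.15) {
  stopifnot(is.matrix(snapshot), nrow(snapshot) == ncol(snapshot))
  stopifnot(density > 0, density <= 1)
  m <- nrow(snapshot)
  W <- abs(symm(snapshot))
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  k <- floor(density * nrow(pairs) + 1e-9)
  if (k < 1L) stop("density ", density, " keeps zero edges on ", m, " nodes")
  w <- W[upper.tri(W)]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  edges <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  new("BinaryGraph", nNodes = m, edges = edges)
}

.asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(g@nNodes, directed = FALSE)
  if (nrow(g@edges) > 0L) ig <- igraph::add_edges(ig, t(g@edges))
  ig
}

.fromIgraph <- function(ig, nNodes) {
  e <- igraph::as_edgelist(ig, names = FALSE)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  new("BinaryGraph", nNodes = as.integer(nNodes), edges = e)
}

#' Global clustering coefficient (transitivity)
#'
#' The ratio of three times the number of closed triples (triangles) to the
#' number of connected triples, equivalently
#' \eqn{3 G_\triangle / \sum_i \binom{k_i}{2}}. Returns 0 for graphs with
#' no connected triples.
#'
#' @param g a [BinaryGraph-class] with at least 3 nodes.
#' @return transitivity in [0, 1].
#' @examples
#' k4 <- binarizeSnapshot(matrix(1, 4, 4), density = 1)
#' globalClustering(k4)  # 1
#' @export
globalClustering <- function(g) {
  stopifnot(is(g, "BinaryGraph"), g@nNodes >= 3L)
  v <- igraph::transitivity(.asIgraph(g), type = "global")
  if (is.nan(v)) 0 else v
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected ordered pairs. If the graph
#' is disconnected it is computed over the largest connected component, with
#' a logged warning (the usual brain-network convention).
#'
#' @param g a [BinaryGraph-class] with at least one edge.
#' @return mean shortest path length (>= 1).
#' @export
charPathLength <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  if (nrow(g@edges) == 0L) stop("edgeless graph has no path length")
  ig <- .asIgraph(g)
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    bdLog("charPathLength: graph disconnected (%d components); using largest",
          comp$no)
    big <- which.max(comp$csize)
    ig <- igraph::induced_subgraph(ig, which(comp$membership == big))
  }
  igraph::mean_distance(ig, directed = FALSE)
}

# no double-edge swap can alter a complete graph or a star
.swapImpossible <- function(g) {
  ne <- nrow(g@edges)
  if (ne == g@nNodes * (g@nNodes - 1) / 2) return(TRUE)
  any(tabulate(g@edges, nbins = g@nNodes) == ne)
}

#' Degree-preserving random reference graph
#'
#' Rewires the graph by repeated double-edge swaps (default 10 attempted
#' swaps per edge), which preserves every node's degree exactly — the null
#' model whose node count, average degree and degree distribution match the
#' graph of interest. Deterministic given the seed. Graphs admitting no
#' valid swap (e.g. a star) are returned unchanged with a warning.
#'
#' @param g a [BinaryGraph-class] with >= 2 edges.
#' @param nSwapsPerEdge attempted swaps per edge.
#' @param seed integer seed.
#' @return a rewired [BinaryGraph-class] with identical degree sequence.
#' @export
randomReference <- function(g, nSwapsPerEdge = 10L, seed = 1L) {
  stopifnot(is(g, "BinaryGraph"), nrow(g@edges) >= 2L)
  ig <- .asIgraph(g)
  rew <- withr::with_seed(seed,
    igraph::rewire(ig, igraph::keeping_degseq(
      niter = nSwapsPerEdge * nrow(g@edges))))
  out <- .fromIgraph(rew, g@nNodes)
  degOrig <- sort(tabulate(g@edges, nbins = g@nNodes))
  degNew <- sort(tabulate(out@edges, nbins = g@nNodes))
  stopifnot(identical(degOrig, degNew))   # invariant of the swap
  # a star (or any graph the swap cannot alter) comes back unchanged
  if (identical(out@edges, g@edges) && .swapImpossible(g))
    warning("no rewiring was possible; returning the input graph")
  out
}

#' Small-world indices against rewired null models
#'
#' Computes clustering C and characteristic path length L for the graph and
#' the means C_R, L_R over \code{nRandom} degree-preserving rewired
#' references, then the ratios gamma = C/C_R, lambda = L/L_R and the
#' small-world coefficient sigma = gamma/lambda. sigma > 1 indicates
#' small-world organization. If C_R is 0 the ratios are undefined and
#' returned as NA.
#'
#' @param g a [BinaryGraph-class].
#' @param nRandom number of null graphs (default 20).
#' @param seed master seed; null i uses seed + i.
#' @param nSwapsPerEdge swaps per edge for each null.
#' @return one-row data.frame with columns C, L, C_R, L_R, gamma, lambda,
#'   sigma, is_small_world.
#' @export
smallWorld <- function(g, nRandom = 20L, seed = 1L, nSwapsPerEdge = 10L) {
  C <- globalClustering(g)
  L <- charPathLength(g)
  refs <- lapply(seq_len(nRandom), function(i)
    suppressWarnings(randomReference(g, nSwapsPerEdge, seed = seed + i)))
  CR <- mean(vapply(refs, globalClustering, numeric(1)))
  LR <- mean(vapply(refs, charPathLength, numeric(1)))
  if (CR == 0 || LR == 0) {
    return(data.frame(C = C, L = L, C_R = CR, L_R = LR, gamma = NA_real_,
                      lambda = NA_real_, sigma = NA_real_,
                      is_small_world = NA))
  }
  gamma <- C / CR
  lambda <- L / LR
  sigma <- gamma / lambda
  data.frame(C = C, L = L, C_R = CR, L_R = LR, gamma = gamma,
             lambda = lambda, sigma = sigma, is_small_world = sigma > 1)
}

#' Small-world analysis of a snapshot sequence
#'
#' Binarizes every snapshot at the given density, runs [smallWorld()] on
#' each (null seeds derived as seed + snapshot index), and reports the
#' fraction of snapshots retaining the small-world property (sigma > 1),
#' in the conventional "percentage(count/total)" form.
#'
#' @param sequence a [SnapshotSequence-class].
#' @param density binarization density.
#' @param nRandom null graphs per snapshot.
#' @param seed master seed.
#' @return a list with \code{table} (one row per snapshot: time_index,
#'   provenance, C, L, C_R, L_R, gamma, lambda, sigma, is_small_world),
#'   \code{fraction}, \code{count}, \code{total} and \code{label} (e.g.
#'   "92.1\%(129/140)").
#' @export
smallWorldFraction <- function(sequence, density = 0.15, nRandom = 20L,
                               seed = 1L) {
  stopifnot(is(sequence, "SnapshotSequence"))
  n <- length(sequence)
  if (n == 0L) stop("empty snapshot sequence")
  rows <- lapply(seq_len(n), function(k) {
    g <- binarizeSnapshot(sequence@matrices[[k]], density)
    rec <- smallWorld(g, nRandom = nRandom, seed = seed + 1000L * k)
    cbind(data.frame(time_index = sequence@times[k],
                     provenance = sequence@provenance[k]), rec)
  })
  tab <- do.call(rbind, rows)
  count <- sum(tab$is_small_world, na.rm = TRUE)
  frac <- count / n
  list(table = tab, fraction = frac, count = count, total = n,
       label = sprintf("%.1f%%(%d/%d)", 100 * frac, count, n))
}
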