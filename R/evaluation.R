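#' Reference windowed network for a predicted snapshot
#'
#' For a prediction at volume index i, the comparison network is the Pearson
#' network of the BOLD segment starting at i - 3 with the training window
#' length, so that a length-6 window is centered near i. Indices whose
#' reference window would leave the series are an error; callers skip and
#' log them.
#'
#' @param series the [RoiTimeSeries-class] the references are cut from.
#' @param i volume index of the prediction (integer, 0-based).
#' @param windowLength training window length in volumes.
#' @return an observed [SnapshotSequence-class] snapshot matrix (m x m).
#' @export
referenceWindowNetwork <- function(series, i, windowLength = 6L) {
  stopifnot(is(series, "RoiTimeSeries"))
  i <- as.integer(i)
  start <- i - 3L
  T <- ncol(series@data)
  if (start < 0L || start + windowLength > T)
    stop("reference window [", start, ", ", start + windowLength,
         ") outside series [0, ", T, ")")
  .windowCorr(series@data[, (start + 1L):(start + windowLength), drop = FALSE])
}

#' L1 and L2 discrepancy between two snapshots
#'
#' Both losses are computed over the upper triangle excluding the diagonal
#' (connectivity matrices are symmetric and the diagonal is fixed):
#' l1 is the sum of absolute differences, l2 the square root of the sum of
#' squared differences.
#'
#' @param pred,ref m x m matrices.
#' @param perEdge divide by the number of upper-triangle entries (off by
#'   default; the unnormalized sums match the conventional scale on
#'   large networks).
#' @return named numeric vector c(l1 = , l2 = ).
#' @export
snapshotLoss <- function(pred, ref, perEdge = FALSE) {
  if (!all(dim(pred) == dim(ref)))
    stop("dimension mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(ref), collapse = "x"))
  d <- (pred - ref)[upper.tri(pred)]
  denom <- if (perEdge) length(d) else 1
  c(l1 = sum(abs(d)) / denom, l2 = sqrt(sum(d * d)) / denom)
}

#' Score predicted snapshots against reference windowed networks
#'
#' Pairs each predicted snapshot at volume index i with the reference
#' network starting at i - 3 (training window length), skipping indices
#' whose reference window would leave the series, and aggregates mean and
#' standard deviation of the L1/L2 losses.
#'
#' @param predicted a [SnapshotSequence-class] of in- or out-snapshots.
#' @param series the [RoiTimeSeries-class] providing reference segments; for
#'   out-snapshots it must extend past the trained span (only possible on
#'   synthetic data where the future is simulable).
#' @param windowLength training window length.
#' @param perEdge see [snapshotLoss()].
#' @return a list with \code{perSnapshot} (data.frame time_index, l1, l2),
#'   \code{meanL1}, \code{meanL2}, \code{sdL1}, \code{sdL2},
#'   \code{nSkipped}.
#' @export
evaluateSequence <- function(predicted, series, windowLength = 6L,
                             perEdge = FALSE) {
  stopifnot(is(predicted, "SnapshotSequence"), is(series, "RoiTimeSeries"))
  T <- ncol(series@data)
  rows <- list()
  skipped <- 0L
  for (k in seq_along(predicted@matrices)) {
    i <- round(predicted@times[k])
    start <- i - 3L
    if (start < 0L || start + windowLength > T) { skipped <- skipped + 1L; next }
    ref <- referenceWindowNetwork(series, i, windowLength)
    l <- snapshotLoss(predicted@matrices[[k]], ref, perEdge = perEdge)
    rows[[length(rows) + 1L]] <- data.frame(time_index = i, l1 = l[["l1"]],
                                            l2 = l[["l2"]])
  }
  if (length(rows) == 0L)
    stop("no feasible prediction/reference pairs",
         if (max(predicted@times) >= T)
           " (series does not extend far enough for out-snapshot references)"
         else "")
  per <- do.call(rbind, rows)
  if (skipped > 0) bdLog("evaluateSequence: skipped %d edge index(es)", skipped)
  list(perSnapshot = per,
       meanL1 = mean(per$l1), meanL2 = mean(per$l2),
       sdL1 = if (nrow(per) > 1) sd(per$l1) else 0,
       sdL2 = if (nrow(per) > 1) sd(per$l2) else 0,
       nSkipped = skipped)
}

#' Write a loss report as CSV / JSON
#'
#' @param report result of [evaluateSequence()].
#' @param csvPath,jsonPath output paths (either may be NULL).
#' @return invisibly, the report.
#' @export
writeLossReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.table(report$perSnapshot, csvPath, sep = ",", quote = FALSE,
                row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}

#' Window-size sensitivity sweep
#'
#' Refits the dynamics model for each window length and scores its
#' in-snapshots against the matching reference windows, producing the table
#' behind the usual "which window length minimizes the loss" figure.
#' Duplicate sizes are deduplicated with a warning.
#'
#' @param series an [RoiTimeSeries-class].
#' @param sizes window lengths to try.
#' @param step window step (fixed across sizes).
#' @param config an [NdcnConfig-class] used for every fit.
#' @param density coupling-graph density.
#' @return data.frame(size, mean_l1, mean_l2).
#' @export
windowSizeSweep <- function(series, sizes = c(4L, 6L, 8L), step = 5L,
                            config = ndcnConfig(), density = 0.15) {
  if (anyDuplicated(sizes)) {
    warning("duplicate window sizes removed")
    sizes <- unique(sizes)
  }
  rows <- lapply(sizes, function(sz) {
    scheme <- windowScheme(sz, step)
    seq <- buildObservedSnapshots(series, scheme)
    model <- fitNdcn(seq, buildCouplingGraph(seq, density), config)
    preds <- predictInSnapshots(model, subjectId = series@subjectId)
    rep <- evaluateSequence(preds, series, windowLength = sz)
    data.frame(size = sz, mean_l1 = rep$meanL1, mean_l2 = rep$meanL2)
  })
  do.call(rbind, rows)
}
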