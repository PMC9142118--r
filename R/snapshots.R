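#' Construct a sliding-window scheme
#'
#' Defaults follow the study protocol for 140-volume resting-state series:
#' window length 6 volumes, step 5 volumes.
#'
#' @param windowLength window length t in volumes.
#' @param step moving step s in volumes.
#' @return a validated [WindowScheme-class].
#' @export
windowScheme <- function(windowLength = 6L, step = 5L) {
  new("WindowScheme", windowLength = as.integer(windowLength),
      step = as.integer(step))
}

#' Number of sliding windows
#'
#' For a series of T volumes segmented into windows of length t moved by step
#' s, the number of fully contained windows is \eqn{\lfloor (T-t)/s \rfloor + 1},
#' with starts 0, s, 2s, ... Only whole windows count: a trailing partial
#' window is dropped.
#'
#' @param T series length in volumes.
#' @param scheme a [WindowScheme-class].
#' @return integer window count n.
#' @examples
#' windowCount(140, windowScheme(6, 5))  # 27
#' @export
windowCount <- function(T, scheme = windowScheme()) {
  stopifnot(is(scheme, "WindowScheme"))
  T <- as.integer(T)
  t <- scheme@windowLength
  if (t > T) stop("window length ", t, " exceeds series length ", T)
  as.integer((T - t) %/% scheme@step) + 1L
}

#' Slice a BOLD series into sliding windows
#'
#' Window k covers volume indices [k*s, k*s + t) on the 0-based volume axis
#' (half-open).
#'
#' @param series an [RoiTimeSeries-class].
#' @param scheme a [WindowScheme-class].
#' @return a list with one element per window, each a list of \code{start}
#'   (0-based start index) and \code{segment} (m x t matrix).
#' @export
sliceWindows <- function(series, scheme = windowScheme()) {
  stopifnot(is(series, "RoiTimeSeries"))
  T <- ncol(series@data)
  n <- windowCount(T, scheme)
  t <- scheme@windowLength
  s <- scheme@step
  lapply(seq_len(n) - 1L, function(k) {
    start <- k * s
    list(start = start, segment = series@data[, (start + 1L):(start + t), drop = FALSE])
  })
}

#' Pearson correlation of two signals
#'
#' Computed in the textbook product-moment form
#' \deqn{r = \frac{N\sum x_i y_i - \sum x_i \sum y_i}
#'   {\sqrt{N\sum x_i^2 - (\sum x_i)^2}\sqrt{N\sum y_i^2 - (\sum y_i)^2}}}{
#'   r = (N*sum(xy) - sum(x)sum(y)) / sqrt((N*sum(x^2)-sum(x)^2)(N*sum(y^2)-sum(y)^2))}
#' If either signal has zero variance within the window the correlation is
#' undefined; it is reported as 0 with a warning so that downstream matrices
#' stay finite.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  dx <- n * sum(x^2) - sum(x)^2
  dy <- n * sum(y^2) - sum(y)^2
  if (dx <= 0 || dy <= 0) {
    warning("zero-variance signal in correlation window; returning 0")
    return(0)
  }
  r <- num / (sqrt(dx) * sqrt(dy))
  min(1, max(-1, r))
}

# correlation matrix of an m x t segment with the zero-variance convention
.windowCorr <- function(segment) {
  sds <- apply(segment, 1L, sd)
  zv <- sds == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance region(s) in window; their correlations set to 0")
    R <- matrix(0, nrow(segment), nrow(segment))
    ok <- which(!zv)
    if (length(ok) >= 2)
      R[ok, ok] <- stats::cor(t(segment[ok, , drop = FALSE]))
  } else {
    R <- stats::cor(t(segment))
  }
  R[!is.finite(R)] <- 0
  R <- symm(pmax(pmin(R, 1), -1))
  diag(R) <- 1
  dimnames(R) <- NULL
  R
}

#' Build the observed snapshot sequence
#'
#' Slices the series with the window scheme and computes one Pearson
#' correlation network per window. Each snapshot's nominal time is the window
#' center, start + (t-1)/2, so that interpolation targets and reference
#' windows live on the same volume axis.
#'
#' @param series an [RoiTimeSeries-class].
#' @param scheme a [WindowScheme-class].
#' @return a [SnapshotSequence-class] of observed snapshots.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(3 * 12), 3, 12))
#' length(buildObservedSnapshots(ts, windowScheme(6, 5)))  # 2
#' @export
buildObservedSnapshots <- function(series, scheme = windowScheme()) {
  windows <- sliceWindows(series, scheme)
  t <- scheme@windowLength
  mats <- lapply(windows, function(w) .windowCorr(w$segment))
  times <- vapply(windows, function(w) w$start + (t - 1) / 2, numeric(1))
  names(mats) <- NULL
  bdLog("subject %s: %d observed snapshots (t=%d, s=%d)", series@subjectId,
        length(mats), t, scheme@step)
  new("SnapshotSequence", subjectId = series@subjectId, times = times,
      matrices = mats, provenance = rep("observed", length(mats)),
      nVolumes = as.numeric(ncol(series@data)))
}

#' Construct a snapshot sequence from matrices
#'
#' @param matrices list of square symmetric matrices.
#' @param times nominal times (volume units), strictly increasing.
#' @param provenance "observed", "in" or "out" (recycled).
#' @param subjectId subject identifier.
#' @param nVolumes acquisition span in volumes; defaults to
#'   \code{floor(max(times)) + 1}.
#' @return a [SnapshotSequence-class].
#' @export
SnapshotSequence <- function(matrices, times = seq_along(matrices) - 1,
                             provenance = "observed", subjectId = "subject",
                             nVolumes = NULL) {
  if (is.null(nVolumes))
    nVolumes <- if (length(times)) floor(max(times)) + 1 else 0
  new("SnapshotSequence", subjectId = subjectId, times = as.numeric(times),
      matrices = matrices,
      provenance = rep_len(provenance, length(matrices)),
      nVolumes = as.numeric(nVolumes))
}

#' Write / read a snapshot sequence as a directory of delimited matrices
#'
#' Each snapshot goes to \code{snapshot_<k>.tsv}; an \code{index.json} stores
#' subject id, times, provenance and the acquisition span.
#'
#' @param sequence a [SnapshotSequence-class].
#' @param dir directory to create/write into.
#' @return the directory, invisibly.
#' @export
writeSnapshots <- function(sequence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(sequence@matrices)) {
    write.table(format(sequence@matrices[[k]], digits = 17, trim = TRUE,
                       scientific = TRUE),
                file.path(dir, sprintf("snapshot_%03d.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  idx <- list(subject_id = sequence@subjectId, times = sequence@times,
              provenance = sequence@provenance, n_volumes = sequence@nVolumes)
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeSnapshots
#' @export
readSnapshots <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^snapshot_\\d+\\.tsv$", full.names = TRUE))
  mats <- lapply(files, function(f)
    as.matrix(read.table(f, sep = "\t", header = FALSE)))
  mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
  new("SnapshotSequence", subjectId = idx$subject_id, times = as.numeric(idx$times),
      matrices = mats, provenance = as.character(idx$provenance),
      nVolumes = as.numeric(idx$n_volumes))
}
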