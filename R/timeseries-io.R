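#' Construct an RoiTimeSeries
#'
#' @param data numeric matrix, regions x volumes.
#' @param subjectId subject identifier.
#' @param regionIds region labels; defaults to rownames(data) or
#'   \code{R1, R2, ...}.
#' @param trSeconds repetition time in seconds.
#' @return a validated [RoiTimeSeries-class].
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(20), 4, 5), subjectId = "s1")
#' nRegions(ts)
#' @export
RoiTimeSeries <- function(data, subjectId = "subject", regionIds = NULL,
                          trSeconds = 3.0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(regionIds)) {
    regionIds <- if (!is.null(rownames(data))) rownames(data)
                 else paste0("R", seq_len(nrow(data)))
  }
  rownames(data) <- regionIds
  new("RoiTimeSeries", subjectId = as.character(subjectId),
      regionIds = as.character(regionIds), data = data,
      trSeconds = as.numeric(trSeconds))
}

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read an ROI BOLD time-series matrix from delimited text
#'
#' Expects rows = regions and columns = volumes, with the region identifier in
#' the first column and no header. Tab-separated by default; comma-separated
#' files are detected by sniffing the first line.
#'
#' @param path path to the TSV/CSV file.
#' @param trSeconds repetition time in seconds (metadata).
#' @param subjectId subject identifier; defaults to the file name without
#'   extension.
#' @return a validated [RoiTimeSeries-class]. Regions with zero variance over
#'   the whole series trigger a warning (the correlation stage handles them).
#' @export
readRoiSeries <- function(path, trSeconds = 3.0, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniffSep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in ", path, ": rows have ", paste(unique(ncols), collapse = "/"),
         " fields")
  ids <- vapply(cells, `[[`, character(1), 1L)
  vals <- lapply(seq_along(cells), function(r) {
    v <- suppressWarnings(as.numeric(cells[[r]][-1]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of %s (value '%s')",
                   r, bad[1] + 1L, path, cells[[r]][bad[1] + 1L]))
    v
  })
  data <- do.call(rbind, vals)
  zv <- which(apply(data, 1L, function(x) sd(x) == 0))
  if (length(zv))
    warning("zero-variance region(s): ", paste(ids[zv], collapse = ", "))
  if (is.null(subjectId)) subjectId <- sub("\\.[^.]*$", "", basename(path))
  out <- RoiTimeSeries(data, subjectId = subjectId, regionIds = ids,
                       trSeconds = trSeconds)
  bdLog("read %s: %d regions x %d volumes", path, nrow(data), ncol(data))
  out
}

#' Write an ROI BOLD time-series matrix as tab-separated text
#'
#' Inverse of [readRoiSeries()]: region id in the first column, one row per
#' region, full double precision so that a read/write round trip reproduces
#' the matrix bit for bit.
#'
#' @param series an [RoiTimeSeries-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRoiSeries <- function(series, path) {
  stopifnot(is(series, "RoiTimeSeries"))
  m <- series@data
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(series@regionIds[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject manifest
#'
#' A manifest is a tab- or comma-separated table with header columns
#' \code{subject_id}, \code{group}, \code{path} listing one BOLD series file
#' per subject. Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @param checkPaths verify that every listed series file exists.
#' @return a data.frame with columns subject_id, group, path.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- .sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("manifest has no entries: ", path)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  if (checkPaths) {
    missing <- abs[!file.exists(abs)]
    if (length(missing)) stop("series file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  df$path <- abs
  bdLog("manifest %s: %d subjects, groups {%s}", path, nrow(df),
        paste(sort(unique(df$group)), collapse = ", "))
  df
}

#' Write a subject manifest
#'
#' @param manifest data.frame with columns subject_id, group, path.
#' @param path output file (TSV).
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(all(c("subject_id", "group", "path") %in% names(manifest)))
  write.table(manifest[, c("subject_id", "group", "path")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
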