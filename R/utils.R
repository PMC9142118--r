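.bd_verbose <- new.env(parent = emptyenv())
.bd_verbose$on <- TRUE

#' Control diagnostic logging
#'
#' All pipeline stages log to standard error. \code{bdVerbose(FALSE)} silences
#' them (tests do this).
#'
#' @param on logical; omit to query the current setting.
#' @return the current (possibly updated) setting, invisibly when setting.
#' @export
bdVerbose <- function(on) {
  if (missing(on)) return(.bd_verbose$on)
  stopifnot(is.logical(on), length(on) == 1L)
  .bd_verbose$on <- on
  invisible(on)
}

bdLog <- function(fmt, ...) {
  if (isTRUE(.bd_verbose$on)) message(sprintf(fmt, ...))
  invisible(NULL)
}

# symmetrize a square matrix
symm <- function(M) (M + t(M)) / 2
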