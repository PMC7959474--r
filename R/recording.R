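#' Recording: a time-stamped landmark stream from one measurement system
#'
#' An ordered sequence of frames, each holding the 3D position (mm) of every
#' hand landmark, plus trial metadata (measurement system, nominal frame
#' rate, subject/task/trial identifiers). Dropped frames are simply absent:
#' there is no NA padding, and times are strictly increasing.
#'
#' @slot times Numeric vector of frame times in seconds.
#' @slot positions Numeric matrix, one row per frame, columns
#'   \code{<landmark>_<axis>_mm} for every landmark in
#'   \code{\link{handLandmarks}}.
#' @slot metadata Named list (system, nominal_rate_hz, subject, task, trial,
#'   and anything a pipeline stage appends, e.g. \code{resampled_hz}).
#' @export
setClass("Recording", representation(times = "numeric",
                                     positions = "matrix",
                                     metadata = "list"))

setValidity("Recording", function(object) {
  if (nrow(object@positions) != length(object@times))
    return("number of frames in 'positions' must equal length of 'times'")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  .checkPosColumns(colnames(object@positions))
})

# column-layout check, memoised on the exact column vector (recordings in a
# study share one of a handful of layouts)
.checkPosColumns <- function(cols) {
  if (is.null(cols))
    return("position columns must be named <landmark>_<x|y|z>_mm")
  for (v in .cache$validatedCols) if (identical(v, cols)) return(TRUE)
  known <- .posColumns()
  if (!all(cols %in% known))
    return("unknown position column(s), expected <landmark>_<x|y|z>_mm")
  # canonical order and complete x/y/z triplets per landmark
  if (!identical(cols, known[known %in% cols]))
    return("position columns must be in canonical landmark order")
  tab <- tabulate((match(cols, known) - 1L) %/% 3L + 1L)
  if (!all(tab %in% c(0L, 3L)))
    return("each landmark needs all three of x/y/z columns")
  .cache$validatedCols <- c(.cache$validatedCols, list(cols))
  TRUE
}

#' Construct a Recording
#'
#' @param times Frame times, seconds, strictly increasing.
#' @param positions Frame-by-coordinate matrix (see
#'   \code{\linkS4class{Recording}}).
#' @param metadata Named list of trial metadata.
#' @return A validated \code{Recording}.
#' @export
recording <- function(times, positions, metadata = list()) {
  obj <- new("Recording", times = as.numeric(times),
             positions = positions, metadata = metadata)
  validObject(obj)
  obj
}

#' @rdname recording
#' @param x A \code{Recording}.
#' @export
recordingTimes <- function(x) x@times

#' @rdname recording
#' @export
recordingPositions <- function(x) x@positions

#' @rdname recording
#' @export
recordingMetadata <- function(x) x@metadata

#' @rdname recording
#' @export
nFrames <- function(x) length(x@times)

#' Positions of one landmark across frames
#'
#' @param x A \code{Recording}.
#' @param landmark Landmark name (see \code{\link{handLandmarks}}).
#' @return \code{nFrames x 3} matrix (x/y/z, mm).
#' @export
landmarkPositions <- function(x, landmark) {
  cols <- .lmCols(landmark)
  if (!all(cols %in% colnames(x@positions)))
    stop("unknown landmark: ", landmark)
  m <- x@positions[, cols, drop = FALSE]
  colnames(m) <- c("x_mm", "y_mm", "z_mm")
  m
}

setMethod("show", "Recording", function(object) {
  md <- object@metadata
  cat(sprintf("Recording: %d frames over %.3f s", nFrames(object),
              if (nFrames(object)) diff(range(object@times)) else 0))
  if (!is.null(md$system)) cat(sprintf(" [%s]", md$system))
  if (!is.null(md$nominal_rate_hz)) cat(sprintf(" nominal %g Hz", md$nominal_rate_hz))
  if (!is.null(md$resampled_hz)) cat(sprintf(", resampled at %g Hz", md$resampled_hz))
  cat("\n")
  if (!is.null(md$subject))
    cat(sprintf("  subject=%s task=%s trial=%s\n",
                md$subject, md$task %||% "?", md$trial %||% "?"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a Recording as wide CSV
#'
#' Column 1 is \code{time_s}, followed by \code{<landmark>_x_mm},
#' \code{<landmark>_y_mm}, \code{<landmark>_z_mm} per landmark. A dropped
#' frame is an absent row. Metadata travel in a JSON sidecar
#' (\code{<path>.meta.json}) written/read alongside unless \code{sidecar}
#' is \code{FALSE}.
#'
#' @param x A \code{Recording}.
#' @param path CSV file path.
#' @param sidecar Write/read the metadata sidecar.
#' @return \code{readRecording} returns a \code{Recording};
#'   \code{writeRecording} returns \code{path} invisibly.
#' @export
writeRecording <- function(x, path, sidecar = TRUE) {
  df <- data.table::data.table(time_s = x@times)
  df <- cbind(df, data.table::as.data.table(x@positions))
  data.table::fwrite(df, path)
  if (sidecar && length(x@metadata))
    jsonlite::write_json(x@metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, sidecar = TRUE) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df))
    stop("malformed recording CSV (no 'time_s' column): ", path)
  need <- intersect(.posColumns(), names(df))
  if (!length(need))
    stop("malformed recording CSV ", path, ": no landmark position columns")
  md <- list()
  sc <- paste0(path, ".meta.json")
  if (sidecar && file.exists(sc)) md <- jsonlite::read_json(sc, simplifyVector = TRUE)
  recording(df$time_s, as.matrix(df[, need, drop = FALSE]), as.list(md))
}
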