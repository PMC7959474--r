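#' @import methods
NULL

#' HandGeometry: per-finger bone segment lengths
#'
#' Defines the simulated skeleton. Non-thumb fingers have four segments
#' (metacarpal, proximal, intermediate, distal); the thumb has three bones
#' only (metacarpal, proximal, distal). All lengths are in mm and strictly
#' positive.
#'
#' @slot lengths Named list, one element per finger, each a named numeric
#'   vector of segment lengths in mm.
#' @export
setClass("HandGeometry", representation(lengths = "list"))

setValidity("HandGeometry", function(object) {
  lens <- object@lengths
  if (!setequal(names(lens), .FINGERS))
    return("geometry must define exactly the fingers: thumb, index, middle, ring, pinky")
  for (f in .FINGERS) {
    want <- if (f == "thumb") .SEGMENTS_THUMB else .SEGMENTS_FULL
    v <- lens[[f]]
    if (!is.numeric(v) || !setequal(names(v), want))
      return(sprintf("finger '%s' must have segments: %s", f, paste(want, collapse = ", ")))
    if (any(!is.finite(v)) || any(v <= 0))
      return(sprintf("finger '%s' has non-positive or non-finite segment length", f))
  }
  TRUE
})

#' Construct a HandGeometry
#'
#' @param lengths Named list of named numeric vectors: per finger, segment
#'   lengths in mm. See \code{\linkS4class{HandGeometry}} for required names.
#' @return A validated \code{HandGeometry}.
#' @export
#' @examples
#' g <- defaultHandGeometry()
#' segmentLengthsOf(g)$thumb
handGeometry <- function(lengths) {
  obj <- new("HandGeometry", lengths = lapply(lengths, function(v) v[sort(names(v))]))
  validObject(obj)
  obj
}

#' Segment lengths of a HandGeometry
#'
#' @param geometry A \code{HandGeometry}.
#' @return Named list of named numeric vectors (mm).
#' @export
segmentLengthsOf <- function(geometry) geometry@lengths

#' Default hand geometry
#'
#' Mean adult segment lengths used as the simulator's default skeleton; the
#' phalanx values follow published marker-based group means for ten adults,
#' the non-thumb metacarpals (which marker-based protocols often do not
#' report) use field-typical anatomical values.
#'
#' @return A \code{HandGeometry}.
#' @export
defaultHandGeometry <- function() {
  handGeometry(lapply(segmentLengthNorms(), function(x) x$mean))
}

#' Population norms for segment lengths
#'
#' Mean and between-subject standard deviation (mm) of each bone segment,
#' used by \code{\link{generateStudy}} to draw per-subject skeletons.
#'
#' @return Named list, one element per finger, each \code{list(mean=, sd=)}
#'   of named numeric vectors.
#' @export
segmentLengthNorms <- function() {
  list(
    thumb = list(
      mean = c(metacarpal = 38.12, proximal = 32.32, distal = 19.27),
      sd   = c(metacarpal = 11.15, proximal = 11.65, distal = 10.52)),
    index = list(
      mean = c(metacarpal = 65, proximal = 44.89, intermediate = 25.73, distal = 17.08),
      sd   = c(metacarpal = 6, proximal = 13.19, intermediate = 12.14, distal = 9.72)),
    middle = list(
      mean = c(metacarpal = 62, proximal = 50.59, intermediate = 30.21, distal = 17.71),
      sd   = c(metacarpal = 6, proximal = 13.07, intermediate = 12.07, distal = 11.57)),
    ring = list(
      mean = c(metacarpal = 55, proximal = 44.90, intermediate = 28.95, distal = 17.40),
      sd   = c(metacarpal = 6, proximal = 10.90, intermediate = 10.94, distal = 10.75)),
    pinky = list(
      mean = c(metacarpal = 50, proximal = 36.31, intermediate = 19.58, distal = 16.69),
      sd   = c(metacarpal = 6, proximal = 3.58, intermediate = 7.96, distal = 8.65))
  )
}

#' Draw a subject-specific geometry around the population norms
#'
#' Independent normal draws per segment, truncated at 1 mm to keep lengths
#' strictly positive.
#'
#' @param norms As returned by \code{\link{segmentLengthNorms}}.
#' @param sdScale Multiplier on the norm standard deviations (0 = every
#'   subject gets the mean skeleton).
#' @return A \code{HandGeometry}.
#' @export
drawHandGeometry <- function(norms = segmentLengthNorms(), sdScale = 1) {
  lens <- lapply(norms, function(x) {
    v <- stats::rnorm(length(x$mean), x$mean, x$sd * sdScale)
    names(v) <- names(x$mean)
    pmax(v, 1)
  })
  handGeometry(lens)
}

#' Write / read a HandGeometry as JSON
#'
#' Serialised as \code{{"finger": {"segment": length_mm}}}.
#'
#' @param geometry A \code{HandGeometry}.
#' @param path File path.
#' @return \code{readHandGeometry} returns a \code{HandGeometry};
#'   \code{writeHandGeometry} returns \code{path} invisibly.
#' @export
writeHandGeometry <- function(geometry, path) {
  jsonlite::write_json(lapply(geometry@lengths, as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHandGeometry
#' @export
readHandGeometry <- function(path) {
  raw <- jsonlite::read_json(path)
  handGeometry(lapply(raw, function(f) unlist(f)))
}

setMethod("show", "HandGeometry", function(object) {
  cat("HandGeometry (mm)\n")
  for (f in .FINGERS) {
    v <- object@lengths[[f]]
    cat(sprintf("  %-6s %s\n", f,
                paste(sprintf("%s=%.1f", names(v), v), collapse = " ")))
  }
})
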