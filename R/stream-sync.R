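#' SamplingTimeline: a rebuilt uniform-origin time vector
#'
#' Variable-rate streams are put on a common footing by rebuilding their time
#' vector from the inter-frame intervals: for \eqn{i} samples each interval
#' is \eqn{1/f_i} (the reciprocal instantaneous rate), and the rebuilt time
#' vector is the cumulative sum of the intervals starting at 0.
#'
#' @slot rawTimes Original timestamps (seconds), or \code{numeric(0)} when
#'   the timeline was built from device-reported rates.
#' @slot intervals Inter-frame intervals, seconds (length nFrames - 1).
#' @slot rebuiltTimes Cumulative-sum time vector starting at 0, length
#'   nFrames, strictly increasing.
#' @slot source \code{"timestamps"} or \code{"rates"}: which information the
#'   intervals came from.
#' @export
setClass("SamplingTimeline", representation(rawTimes = "numeric",
                                            intervals = "numeric",
                                            rebuiltTimes = "numeric",
                                            source = "character"))

setValidity("SamplingTimeline", function(object) {
  rt <- object@rebuiltTimes
  if (!length(rt) || rt[1] != 0) return("rebuiltTimes must start at 0")
  if (length(rt) > 1 && any(diff(rt) <= 0))
    return("rebuiltTimes must be strictly increasing")
  if (length(object@intervals) != length(rt) - 1)
    return("intervals must have one element fewer than rebuiltTimes")
  TRUE
})

setMethod("show", "SamplingTimeline", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "SamplingTimeline: %d frames over %.3f s (from %s), mean rate %.2f Hz, interval CV %.3f\n",
    length(object@rebuiltTimes), max(object@rebuiltTimes), object@source,
    1 / mean(iv), stats::sd(iv) / mean(iv)))
})

#' Rebuild the time vector of a stream
#'
#' When per-frame timestamps are available the intervals are their successive
#' differences (strictly more informative than a reported rate); otherwise
#' the intervals are the reciprocals of the device-reported instantaneous
#' frame rates. Either way the rebuilt time vector is the cumulative sum of
#' the intervals with a leading 0, so its total duration telescopes to the
#' last-minus-first raw timestamp when timestamps exist.
#'
#' @param x A \code{Recording}, a numeric vector of raw timestamps, or (with
#'   \code{rates=}) nothing.
#' @param rates Optional numeric vector of instantaneous frame rates (Hz),
#'   one per frame after the first, used when no timestamps exist.
#' @param nominalRate Nominal rate in Hz used only to warn about gaps longer
#'   than \code{gapFactor} nominal intervals (dropped frames).
#' @param gapFactor Gap-warning threshold, in nominal intervals.
#' @return A \code{SamplingTimeline}.
#' @export
#' @examples
#' tl <- buildTimeVector(c(0, 0.01, 0.03, 0.04))
#' tl@rebuiltTimes
buildTimeVector <- function(x = NULL, rates = NULL, nominalRate = NULL,
                            gapFactor = 5) {
  if (is(x, "Recording")) {
    if (is.null(nominalRate)) nominalRate <- x@metadata$nominal_rate_hz
    x <- x@times
  }
  if (!is.null(x)) {
    if (length(x) < 2)
      stop("insufficient data: need at least 2 frames to build a timeline")
    dts <- diff(x)
    bad <- which(dts <= 0)
    if (length(bad))
      stop(sprintf("non-increasing timestamps at index %d", bad[1] + 1L))
    tl <- new("SamplingTimeline", rawTimes = as.numeric(x), intervals = dts,
              rebuiltTimes = cumsum(c(0, dts)), source = "timestamps")
  } else if (!is.null(rates)) {
    if (length(rates) < 1)
      stop("insufficient data: need at least 1 instantaneous rate")
    if (any(rates <= 0)) stop("instantaneous rates must be > 0")
    dts <- 1 / rates
    tl <- new("SamplingTimeline", rawTimes = numeric(0), intervals = dts,
              rebuiltTimes = cumsum(c(0, dts)), source = "rates")
  } else {
    stop("supply either timestamps/a Recording or instantaneous rates")
  }
  if (!is.null(nominalRate)) {
    gaps <- which(tl@intervals > gapFactor / nominalRate)
    if (length(gaps))
      warning(sprintf("%d gap(s) longer than %gx the nominal interval (first at frame %d)",
                      length(gaps), gapFactor, gaps[1]))
  }
  tl
}

#' Resample a recording onto a uniform time grid
#'
#' Produces frames at \eqn{t = 0, 1/rate, 2/rate, \dots} up to the last
#' rebuilt time, linearly interpolating every landmark coordinate between the
#' bracketing source frames. The grid never extends beyond the source span
#' (no extrapolation); resampling a uniform-rate recording at its own rate
#' reproduces it to floating tolerance.
#'
#' @param x A \code{Recording}.
#' @param targetRate Target rate in Hz (> 0), default 150.
#' @param timeline Optional \code{SamplingTimeline}; rebuilt from the
#'   recording's timestamps when omitted.
#' @return A \code{Recording} on the uniform grid, with \code{resampled_hz}
#'   recorded in its metadata.
#' @export
resampleUniform <- function(x, targetRate = 150, timeline = NULL) {
  stopifnot(is(x, "Recording"))
  if (!is.numeric(targetRate) || targetRate <= 0)
    stop("'targetRate' must be > 0")
  if (is.null(timeline))
    timeline <- suppressWarnings(buildTimeVector(x))
  src <- timeline@rebuiltTimes
  if (length(src) != nFrames(x))
    stop("timeline length does not match the recording")
  grid <- seq(0, src[length(src)] + 1e-12, by = 1 / targetRate)
  grid <- grid[grid <= src[length(src)] + 1e-12]
  P <- x@positions
  # vectorised linear interpolation of all coordinate columns at once
  # (source times are strictly increasing, grid never exceeds their span)
  idx <- findInterval(grid, src)
  idx <- pmin(pmax(idx, 1L), length(src) - 1L)
  w <- (grid - src[idx]) / (src[idx + 1L] - src[idx])
  w <- pmin(pmax(w, 0), 1)
  out <- P[idx, , drop = FALSE] * (1 - w) + P[idx + 1L, , drop = FALSE] * w
  md <- x@metadata
  md$resampled_hz <- targetRate
  md$source_mean_rate_hz <- 1 / mean(timeline@intervals)
  md$source_interval_cv <- if (length(timeline@intervals) > 1)
    stats::sd(timeline@intervals) / mean(timeline@intervals) else 0
  recording(grid, out, md)
}

#' Time-normalise a trajectory onto a 0-100% grid
#'
#' Resamples an angle trajectory onto \code{nPoints} equally spaced
#' fractions of the trial duration (the biomechanics convention is 101
#' points, i.e. 0-100% in 1% steps), linearly interpolated, endpoints
#' preserved exactly. Normalisation makes trials performed at different
#' speeds directly comparable and is idempotent for a matching
#' \code{nPoints}.
#'
#' @param trajectory An \code{\link{AngleTrajectory}} with >= 2 samples.
#' @param nPoints Number of grid points (>= 2), default 101.
#' @return An \code{AngleTrajectory} whose times are percent of trial
#'   duration (\code{timeUnit == "percent"}).
#' @export
timeNormalize <- function(trajectory, nPoints = 101) {
  stopifnot(is(trajectory, "AngleTrajectory"))
  if (!is.numeric(nPoints) || nPoints < 2)
    stop("'nPoints' must be >= 2")
  tt <- trajectory@times
  if (length(tt) < 2) stop("need at least 2 samples to time-normalise")
  frac <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
  grid <- seq(0, 1, length.out = nPoints)
  a <- stats::approx(frac, trajectory@angles, xout = grid, rule = 2)$y
  a[1] <- trajectory@angles[1]
  a[nPoints] <- trajectory@angles[length(tt)]
  angleTrajectory(trajectory@joint, grid * 100, a, timeUnit = "percent")
}
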