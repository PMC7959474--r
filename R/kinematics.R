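#' AngleTrajectory: a per-joint time series of angles
#'
#' @slot joint Joint label.
#' @slot times Sample times (seconds, or percent when time-normalised).
#' @slot angles Angles in degrees, within [0, 180].
#' @slot timeUnit \code{"s"} or \code{"percent"}.
#' @export
setClass("AngleTrajectory", representation(joint = "character",
                                           times = "numeric",
                                           angles = "numeric",
                                           timeUnit = "character"))

setValidity("AngleTrajectory", function(object) {
  if (length(object@times) != length(object@angles))
    return("times and angles must have the same length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(object@angles < -1e-9 | object@angles > 180 + 1e-9))
    return("angles must lie within [0, 180] degrees")
  TRUE
})

setMethod("show", "AngleTrajectory", function(object) {
  cat(sprintf("AngleTrajectory '%s': %d samples, range [%.2f, %.2f] deg\n",
              object@joint, length(object@angles),
              min(object@angles), max(object@angles)))
})

#' Construct an AngleTrajectory
#'
#' @param joint Joint label.
#' @param times Sample times.
#' @param angles Angles in degrees.
#' @param timeUnit \code{"s"} (default) or \code{"percent"}.
#' @return A validated \code{AngleTrajectory}.
#' @export
angleTrajectory <- function(joint, times, angles, timeUnit = "s") {
  obj <- new("AngleTrajectory", joint = joint, times = as.numeric(times),
             angles = as.numeric(angles), timeUnit = timeUnit)
  validObject(obj)
  obj
}

#' Three-point joint angle
#'
#' The angle at the middle point of an articulated chain a -> b -> c: the
#' angle between the segment vectors b - a and c - b, computed as the arccos
#' of their normalised dot product. 0 degrees means the two segments are
#' collinear (straight chain); the result always lies in [0, 180]. The
#' arccos argument is clamped to [-1, 1] to guard against floating-point
#' overshoot on near-collinear points. The angle is invariant under global
#' rotation, translation and uniform scaling of the three points.
#'
#' @param a,b,c Numeric 3-vectors (or matrices with one row per frame and 3
#'   columns) of positions in mm.
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' jointAngle(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1))   # 90
jointAngle <- function(a, b, c) {
  if (is.null(dim(a))) {
    a <- matrix(a, 1); b <- matrix(b, 1); c <- matrix(c, 1)
    single <- TRUE
  } else single <- FALSE
  u <- b - a
  v <- c - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  bad <- which(nu == 0 | nv == 0)
  if (length(bad))
    stop(sprintf("degenerate geometry: zero-length segment at frame %d", bad[1]))
  arg <- rowSums(u * v) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, arg))) / .DEG
  if (single) ang[1] else ang
}

#' Joint-angle trajectories of a recording
#'
#' Applies the three-point angle to every flexion joint of every finger in
#' every frame: the MCP angle from (wrist, MCP, PIP), the PIP angle from
#' (MCP, PIP, DIP), the DIP angle from (PIP, DIP, tip), and analogously for
#' the thumb's CMC/MCP/IP chain. Frames in which any required landmark is
#' missing (NA) are skipped for that joint with a warning; a joint whose
#' landmarks are missing in every frame is an error.
#'
#' @param x A \code{Recording}.
#' @param joints Joint names to compute; defaults to all 15 flexion joints.
#' @return Named list of \code{\link{AngleTrajectory}} objects on the
#'   recording's time base.
#' @export
angleTrajectories <- function(x, joints = handJoints()) {
  stopifnot(is(x, "Recording"))
  explicit <- !missing(joints)
  triples <- .jointTriples()
  triples <- triples[triples$joint %in% joints, , drop = FALSE]
  if (!nrow(triples)) stop("no known joints requested")
  have <- colnames(x@positions)
  avail <- paste0(triples$a, "_x_mm") %in% have &
    paste0(triples$b, "_x_mm") %in% have &
    paste0(triples$c, "_x_mm") %in% have
  if (explicit && !all(avail))
    stop("joint '", triples$joint[!avail][1],
         "': required landmarks absent from the recording")
  triples <- triples[avail, , drop = FALSE]
  if (!nrow(triples)) stop("recording holds no complete joint chain")
  out <- list()
  for (i in seq_len(nrow(triples))) {
    j <- triples$joint[i]
    A <- landmarkPositions(x, triples$a[i])
    B <- landmarkPositions(x, triples$b[i])
    C <- landmarkPositions(x, triples$c[i])
    ok <- stats::complete.cases(A) & stats::complete.cases(B) &
      stats::complete.cases(C)
    if (!any(ok))
      stop("joint '", j, "' has no frame with all landmarks present")
    if (!all(ok))
      warning(sprintf("joint '%s': skipped %d frame(s) with missing landmarks",
                      j, sum(!ok)))
    ang <- jointAngle(A[ok, , drop = FALSE], B[ok, , drop = FALSE],
                      C[ok, , drop = FALSE])
    out[[j]] <- angleTrajectory(j, x@times[ok], ang)
  }
  out
}

#' Per-segment lengths of a recording
#'
#' Euclidean distance between the joint centres bounding each bone segment,
#' evaluated per frame and summarised as mean and sample sd. Intended for
#' static trials. Marker-based protocols typically do not instrument the
#' non-thumb metacarpals; use \code{dropReferenceMetacarpals} (or the
#' summary-level rule in \code{\link{summarizeSegmentLengths}}) to reproduce
#' that reporting convention.
#'
#' @param x A \code{Recording}.
#' @param dropReferenceMetacarpals Drop non-thumb metacarpal segments (the
#'   reference-system reporting rule).
#' @return \code{data.frame} with columns finger, segment, n, mean_mm,
#'   sd_mm, min_mm, max_mm, degenerate (TRUE when any frame had coincident
#'   joint centres).
#' @export
segmentLengths <- function(x, dropReferenceMetacarpals = FALSE) {
  stopifnot(is(x, "Recording"))
  pairs <- .segmentPairs()
  if (dropReferenceMetacarpals)
    pairs <- pairs[!(pairs$segment == "metacarpal" & pairs$finger != "thumb"), ]
  have <- colnames(x@positions)
  pairs <- pairs[paste0(pairs$from, "_x_mm") %in% have &
                   paste0(pairs$to, "_x_mm") %in% have, , drop = FALSE]
  if (!nrow(pairs)) stop("recording holds no complete segment")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    A <- landmarkPositions(x, pairs$from[i])
    B <- landmarkPositions(x, pairs$to[i])
    ok <- stats::complete.cases(A) & stats::complete.cases(B)
    d <- sqrt(rowSums((B[ok, , drop = FALSE] - A[ok, , drop = FALSE])^2))
    data.frame(finger = pairs$finger[i], segment = pairs$segment[i],
               n = length(d), mean_mm = mean(d),
               sd_mm = if (length(d) > 1) stats::sd(d) else 0,
               min_mm = min(d), max_mm = max(d),
               degenerate = any(d == 0))
  })
  do.call(rbind, res)
}

#' Range of motion of a trajectory
#'
#' ROM is the maximum minus the minimum angle attained over the trial; it is
#' invariant under time reparameterisation (movement speed).
#'
#' @param trajectory An \code{\link{AngleTrajectory}} (>= 1 sample), or a
#'   bare numeric vector of angles.
#' @return One-row \code{data.frame}: joint, angle_min, angle_max, rom
#'   (degrees).
#' @export
#' @examples
#' tr <- angleTrajectory("index_mcp", c(0, 1, 2), c(9.62, 78.01, 9.62))
#' rom(tr)$rom   # 68.39
rom <- function(trajectory) {
  if (is(trajectory, "AngleTrajectory")) {
    a <- trajectory@angles
    j <- trajectory@joint
  } else {
    a <- as.numeric(trajectory)
    j <- NA_character_
  }
  if (!length(a)) stop("empty trajectory")
  data.frame(joint = j, angle_min = min(a), angle_max = max(a),
             rom = max(a) - min(a))
}

#' Reference-minus-test difference in range of motion
#'
#' The sign convention throughout the package is reference system minus
#' test system (gold standard minus candidate), so a positive difference
#' means the test system under-measured the movement.
#'
#' @param romReference,romTest Non-negative ROM values in degrees.
#' @return \code{romReference - romTest}, degrees.
#' @export
#' @examples
#' romDifference(72.15, 43.86)   # 28.29
romDifference <- function(romReference, romTest) {
  if (any(romReference < 0) || any(romTest < 0))
    stop("ROM values must be non-negative")
  romReference - romTest
}

#' Per-trial summary metrics of a trajectory
#'
#' Besides ROM, the agreement stage can pair trials on the peak angle or on
#' the mean angle over a common time window. The mean responds one-to-one to
#' an additive measurement bias, which ROM (a max-minus-min) cancels by
#' construction.
#'
#' @param trajectory An \code{AngleTrajectory}.
#' @param window Optional \code{c(t0, t1)} restricting the samples used for
#'   the mean (seconds).
#' @return Named numeric: rom, peak, mean.
#' @export
trajectoryMetrics <- function(trajectory, window = NULL) {
  a <- trajectory@angles
  tt <- trajectory@times
  m <- if (is.null(window)) mean(a) else {
    sel <- tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12
    mean(a[sel])
  }
  c(rom = max(a) - min(a), peak = max(a), mean = m)
}
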