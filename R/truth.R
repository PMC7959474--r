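#' TruthTrajectories: noise-free ground-truth joint angles for one trial
#'
#' Holds a dense sampling of the true joint-angle trajectories together with
#' the generating task profile, so the truth can also be evaluated in closed
#' form at arbitrary times (\code{\link{truthAngles}}) -- e.g. at the exact
#' frame times a simulated sensor happens to sample.
#'
#' @slot profile The generating \code{TaskProfile}.
#' @slot speed Per-trial speed multiplier on the cycle duration.
#' @slot duration Trial duration in seconds.
#' @slot times Dense time grid, seconds.
#' @slot angles Matrix \code{length(times) x nJoints}, degrees; columns named
#'   by joint (all 16 degrees of freedom, non-moving joints at rest).
#' @export
setClass("TruthTrajectories", representation(profile = "TaskProfile",
                                             speed = "numeric",
                                             duration = "numeric",
                                             times = "numeric",
                                             angles = "matrix"))

#' Generate ground-truth trajectories for a task
#'
#' Each movement cycle is a raised-cosine rise from the rest angle to the
#' peak amplitude and back: within a cycle of duration \eqn{c} the angle is
#' \eqn{rest + (amp - rest)(1 - \cos(2\pi t/c))/2}, so the trajectory starts
#' and ends at rest, attains the amplitude once per cycle (at the cycle
#' midpoint) and is continuously differentiable throughout.
#'
#' @param profile A \code{\link{taskProfile}}.
#' @param dt Dense grid step in seconds (> 0).
#' @param speed Multiplier on the cycle duration (movement speed is not
#'   fixed across trials; 1 = nominal).
#' @return A \code{TruthTrajectories}.
#' @export
#' @examples
#' tp <- defaultTaskProfiles()$index_flexion
#' tr <- generateTruth(tp)
#' max(tr@angles[, "index_pip"])   # peak amplitude
generateTruth <- function(profile, dt = 1 / 600, speed = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (speed <= 0) stop("'speed' must be > 0")
  dur <- if (profile@task == "static") profile@staticDuration * speed else
    profile@nCycles * profile@cycleDuration * speed
  times <- seq(0, dur, by = dt)
  if (times[length(times)] < dur) times <- c(times, dur)
  obj <- new("TruthTrajectories", profile = profile, speed = speed,
             duration = dur, times = times,
             angles = .truthAngleMatrix(profile, speed, times))
  obj
}

# closed-form evaluation of the raised-cosine protocol at arbitrary times
.truthAngleMatrix <- function(profile, speed, times) {
  allJoints <- handJoints(includeAbduction = TRUE)
  A <- matrix(0, length(times), length(allJoints),
              dimnames = list(NULL, allJoints))
  if (!length(profile@amplitude)) return(A)
  if (profile@task == "static") {
    for (j in names(profile@restAngle)) A[, j] <- profile@restAngle[[j]]
    return(A)
  }
  cyc <- profile@cycleDuration * speed
  shape <- 0.5 * (1 - cos(2 * pi * times / cyc))
  for (j in names(profile@amplitude)) {
    r <- profile@restAngle[[j]]
    A[, j] <- r + (profile@amplitude[[j]] - r) * shape
  }
  A
}

#' Evaluate ground-truth angles at arbitrary times
#'
#' Uses the closed form of the raised-cosine protocol, not interpolation of
#' the dense grid, so values are exact at any time within the trial.
#'
#' @param truth A \code{TruthTrajectories}.
#' @param times Numeric vector of times in seconds (within [0, duration]).
#' @return Matrix \code{length(times) x nJoints}, degrees.
#' @export
truthAngles <- function(truth, times) {
  if (any(times < -1e-9 | times > truth@duration + 1e-9))
    stop("requested times fall outside the trial interval")
  .truthAngleMatrix(truth@profile, truth@speed, pmin(pmax(times, 0), truth@duration))
}

setMethod("show", "TruthTrajectories", function(object) {
  cat(sprintf("TruthTrajectories '%s': %.2f s (speed x%.2f), %d dense samples\n",
              object@profile@task, object@duration, object@speed,
              length(object@times)))
})

#' Render a sensor's view of a ground-truth trial
#'
#' Simulates one measurement system observing the true movement. Frame times
#' are cumulative sums of inter-frame intervals with mean
#' \code{1/nominalRate}; with a positive jitter CV the intervals are gamma
#' distributed (a simple strictly-positive interval law), with CV 0 they are
#' exactly constant. At each frame the true joint angles are evaluated in
#' closed form, the sensor's per-joint angular bias is added (the physical
#' result is clamped into the model's valid angle range), the pose is
#' rendered by \code{\link{forwardPose}}, and isotropic Gaussian positional
#' noise is added to every landmark coordinate. Frames are then dropped
#' independently with the sensor's dropout probability; the first and last
#' frame are kept so both systems span the trial interval (trial start/end
#' are synchronised programmatically).
#'
#' @param truth A \code{TruthTrajectories}.
#' @param geometry A \code{HandGeometry}.
#' @param sensor A \code{SensorModel}.
#' @param seed Integer seed; the interval, noise and dropout draws use
#'   independent sub-streams derived from it.
#' @param wristOrigin Wrist position, mm.
#' @param fingers Fingers to render (default all); see
#'   \code{\link{forwardPose}}.
#' @return A \code{Recording} with system metadata attached.
#' @export
renderStream <- function(truth, geometry, sensor, seed,
                         wristOrigin = c(0, 0, 0), fingers = .FINGERS) {
  stopifnot(is(truth, "TruthTrajectories"), is(sensor, "SensorModel"))
  seeds <- .splitSeed(seed, 3)
  dur <- truth@duration
  mu <- 1 / sensor@nominalRate

  if (sensor@intervalJitterCV <= 0) {
    times <- seq(0, dur + 1e-12, by = mu)
  } else {
    cv <- sensor@intervalJitterCV
    shape <- 1 / cv^2
    nDraw <- ceiling(dur / mu * (1 + 4 * cv)) + 20
    times <- withSeed(seeds[1], {
      iv <- stats::rgamma(nDraw, shape = shape, scale = mu / shape)
      cumsum(c(0, iv))
    })
    times <- times[times <= dur - 1e-12]
    # trial start/end are synchronised programmatically across systems, so
    # the stream always closes with a frame at the trial end
    times <- c(times, dur)
  }
  n <- length(times)

  A <- truthAngles(truth, times)
  if (length(sensor@angularBias)) {
    for (j in names(sensor@angularBias))
      A[, j] <- A[, j] + sensor@angularBias[[j]]
    flex <- handJoints()
    A[, flex] <- pmin(pmax(A[, flex], 0), 180 - 1e-6)
    A[, "thumb_abduction"] <- pmin(pmax(A[, "thumb_abduction"], -90 + 1e-6),
                                   90 - 1e-6)
  }
  P <- forwardPose(geometry, A, wristOrigin, fingers = fingers)
  if (sensor@positionalNoiseSD > 0) {
    P <- P + withSeed(seeds[2], matrix(
      stats::rnorm(length(P), 0, sensor@positionalNoiseSD), nrow(P), ncol(P)))
  }
  keep <- rep(TRUE, n)
  if (sensor@dropoutProb > 0) {
    keep <- withSeed(seeds[3], stats::runif(n) >= sensor@dropoutProb)
    keep[c(1, n)] <- TRUE
  }
  recording(times[keep], P[keep, , drop = FALSE],
            metadata = list(system = sensor@label,
                            nominal_rate_hz = sensor@nominalRate,
                            task = truth@profile@task,
                            duration_s = dur,
                            seed = seed))
}

# evaluate 'expr' under a temporary RNG state seeded with 'seed'
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seeds, kept below 2^31
.splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
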