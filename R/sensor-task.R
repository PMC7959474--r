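#' SensorModel: statistical model of one measurement system
#'
#' Captures the sampling and error structure the analysis pipeline has to
#' cope with: nominal frame rate, inter-frame interval jitter (coefficient of
#' variation; 0 gives a perfectly constant rate), isotropic positional noise,
#' a per-joint additive angular bias applied to the true angles before the
#' pose is rendered, and an independent per-frame dropout probability.
#'
#' @slot nominalRate Frames per second (> 0).
#' @slot intervalJitterCV CV of inter-frame intervals (>= 0).
#' @slot positionalNoiseSD Isotropic landmark noise sd, mm (>= 0).
#' @slot angularBias Named numeric, degrees added per joint (may be empty).
#' @slot dropoutProb Per-frame dropout probability in [0, 1).
#' @slot label System label used in outputs ("reference"/"test").
#' @export
setClass("SensorModel", representation(nominalRate = "numeric",
                                       intervalJitterCV = "numeric",
                                       positionalNoiseSD = "numeric",
                                       angularBias = "numeric",
                                       dropoutProb = "numeric",
                                       label = "character"))

setValidity("SensorModel", function(object) {
  if (object@nominalRate <= 0) return("nominalRate must be > 0")
  if (object@intervalJitterCV < 0) return("intervalJitterCV must be >= 0")
  if (object@positionalNoiseSD < 0) return("positionalNoiseSD must be >= 0")
  if (object@dropoutProb < 0 || object@dropoutProb >= 1)
    return("dropoutProb must lie in [0, 1)")
  bad <- setdiff(names(object@angularBias), handJoints(includeAbduction = TRUE))
  if (length(bad)) return(paste0("unknown joint in angularBias: ", bad[1]))
  TRUE
})

#' Construct a SensorModel
#'
#' @param nominalRate Frames per second.
#' @param intervalJitterCV Coefficient of variation of inter-frame intervals.
#' @param positionalNoiseSD Isotropic positional noise sd in mm.
#' @param angularBias Named numeric vector of per-joint additive biases
#'   (degrees).
#' @param dropoutProb Per-frame dropout probability.
#' @param label System label.
#' @return A validated \code{SensorModel}.
#' @export
sensorModel <- function(nominalRate, intervalJitterCV = 0,
                        positionalNoiseSD = 0, angularBias = numeric(0),
                        dropoutProb = 0, label = "sensor") {
  obj <- new("SensorModel", nominalRate = nominalRate,
             intervalJitterCV = intervalJitterCV,
             positionalNoiseSD = positionalNoiseSD,
             angularBias = angularBias, dropoutProb = dropoutProb,
             label = label)
  validObject(obj)
  obj
}

#' Default sensor models for the paired-systems study
#'
#' \code{referenceSensor} emulates a marker-based optical system: constant
#' 150 Hz, small isotropic noise, no bias, no dropout. \code{testSensor}
#' emulates a markerless tracker: nominal 120 Hz with jittery intervals,
#' larger positional noise, occasional dropped frames, and a joint-dependent
#' angular bias whose signs follow the error structure reported for such
#' devices (distal joints under-read, MCP joints over-read). Noise
#' magnitudes are model placeholders, not device claims; see the methods
#' vignette.
#'
#' @return A \code{SensorModel}.
#' @export
referenceSensor <- function() {
  sensorModel(150, intervalJitterCV = 0, positionalNoiseSD = 0.15,
              dropoutProb = 0, label = "reference")
}

#' @rdname referenceSensor
#' @export
testSensor <- function() {
  bias <- c(thumb_cmc = 5, thumb_mcp = -5, thumb_ip = -6,
            index_mcp = 6, index_pip = -2, index_dip = -3,
            middle_mcp = 5, middle_pip = -10, middle_dip = -4,
            ring_mcp = 2, ring_pip = -8, ring_dip = -5,
            pinky_mcp = 4, pinky_pip = -8, pinky_dip = -3)
  sensorModel(120, intervalJitterCV = 0.2, positionalNoiseSD = 0.5,
              angularBias = bias, dropoutProb = 0.02, label = "test")
}

#' Zero-noise copy of a sensor model
#'
#' Keeps the nominal rate and label but removes jitter, noise, bias and
#' dropout; used for null-pipeline checks.
#'
#' @param sensor A \code{SensorModel}.
#' @return A \code{SensorModel}.
#' @export
noiselessSensor <- function(sensor) {
  sensorModel(sensor@nominalRate, 0, 0, numeric(0), 0, sensor@label)
}

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel '%s': %g Hz, jitter CV %g, noise %g mm, dropout %g\n",
              object@label, object@nominalRate, object@intervalJitterCV,
              object@positionalNoiseSD, object@dropoutProb))
  if (length(object@angularBias))
    cat("  angular bias on", length(object@angularBias), "joint(s)\n")
})

#' TaskProfile: one movement task of the protocol
#'
#' Describes a cyclic movement: which joints move, from which rest angle to
#' which peak amplitude, over how many cycles of what duration. Each cycle is
#' a smooth raised-cosine rise from rest to amplitude and back; the static
#' task holds the rest pose.
#'
#' @slot task Task name, e.g. "index_flexion", "thumb_abduction", "static".
#' @slot nCycles Number of movement cycles (>= 1; ignored for static).
#' @slot cycleDuration Seconds per cycle (> 0).
#' @slot amplitude Named numeric, peak angle in degrees per moving joint.
#' @slot restAngle Named numeric, rest angle per moving joint (same names).
#' @slot staticDuration Seconds held for the static task.
#' @export
setClass("TaskProfile", representation(task = "character",
                                       nCycles = "numeric",
                                       cycleDuration = "numeric",
                                       amplitude = "numeric",
                                       restAngle = "numeric",
                                       staticDuration = "numeric"))

setValidity("TaskProfile", function(object) {
  if (object@nCycles < 1) return("nCycles must be >= 1")
  if (object@cycleDuration <= 0) return("cycleDuration must be > 0")
  if (object@staticDuration <= 0) return("staticDuration must be > 0")
  if (!setequal(names(object@amplitude), names(object@restAngle)))
    return("amplitude and restAngle must name the same joints")
  if (length(object@amplitude) &&
      any(object@amplitude < object@restAngle[names(object@amplitude)]))
    return("amplitudes must be >= rest angles")
  bad <- setdiff(names(object@amplitude), handJoints(includeAbduction = TRUE))
  if (length(bad)) return(paste0("unknown joint: ", bad[1]))
  TRUE
})

#' Construct a TaskProfile
#'
#' @param task Task name.
#' @param amplitude,restAngle Named numeric vectors over the moving joints,
#'   degrees.
#' @param nCycles Cycles per trial.
#' @param cycleDuration Seconds per cycle.
#' @param staticDuration Seconds (static task only).
#' @return A validated \code{TaskProfile}.
#' @export
taskProfile <- function(task, amplitude = numeric(0), restAngle = numeric(0),
                        nCycles = 3, cycleDuration = 2, staticDuration = 3) {
  if (length(amplitude)) restAngle <- restAngle[names(amplitude)]
  obj <- new("TaskProfile", task = task, nCycles = nCycles,
             cycleDuration = cycleDuration, amplitude = amplitude,
             restAngle = restAngle, staticDuration = staticDuration)
  validObject(obj)
  obj
}

#' Joints whose movement a task targets
#'
#' @param profile A \code{TaskProfile}.
#' @param flexionOnly Drop the thumb abduction degree of freedom (which is
#'   not a three-point angle) from the result.
#' @return Character vector of joint names.
#' @export
taskJoints <- function(profile, flexionOnly = TRUE) {
  j <- names(profile@amplitude)
  if (flexionOnly) j <- setdiff(j, "thumb_abduction")
  j
}

#' The default movement protocol
#'
#' Six dynamic tasks -- flexion/extension of each of the four fingers, thumb
#' flexion, and thumb abduction/adduction -- each performed as three
#' raised-cosine cycles, plus one static rest-pose task. Rest and peak
#' angles are chosen to give per-joint ranges of motion in the ballpark
#' reported for healthy adults with marker-based capture.
#'
#' @param includeStatic Append the static task profile.
#' @return Named list of \code{TaskProfile}s.
#' @export
defaultTaskProfiles <- function(includeStatic = FALSE) {
  fingerAmp <- c(mcp = 90, pip = 100, dip = 70)
  rest <- 10
  profs <- list()
  for (f in .NON_THUMB) {
    joints <- paste(f, names(fingerAmp), sep = "_")
    profs[[paste0(f, "_flexion")]] <- taskProfile(
      paste0(f, "_flexion"),
      amplitude = stats::setNames(unname(fingerAmp), joints),
      restAngle = stats::setNames(rep(rest, 3), joints))
  }
  profs$thumb_flexion <- taskProfile(
    "thumb_flexion",
    amplitude = c(thumb_cmc = 45, thumb_mcp = 60, thumb_ip = 75),
    restAngle = c(thumb_cmc = 10, thumb_mcp = 10, thumb_ip = 10))
  profs$thumb_abduction <- taskProfile(
    "thumb_abduction",
    amplitude = c(thumb_cmc = 52, thumb_mcp = 60, thumb_ip = 48,
                  thumb_abduction = 40),
    restAngle = c(thumb_cmc = 10, thumb_mcp = 10, thumb_ip = 10,
                  thumb_abduction = 0))
  if (includeStatic) profs$static <- staticTaskProfile()
  profs
}

#' @rdname defaultTaskProfiles
#' @param duration Seconds the rest pose is held.
#' @export
staticTaskProfile <- function(duration = 3) {
  joints <- handJoints()
  taskProfile("static",
              amplitude = stats::setNames(rep(10, length(joints)), joints),
              restAngle = stats::setNames(rep(10, length(joints)), joints),
              nCycles = 1, cycleDuration = duration,
              staticDuration = duration)
}

setMethod("show", "TaskProfile", function(object) {
  cat(sprintf("TaskProfile '%s': %g cycle(s) x %g s", object@task,
              object@nCycles, object@cycleDuration))
  if (length(object@amplitude))
    cat(sprintf(", %d joint(s), peak %g deg", length(object@amplitude),
                max(object@amplitude)))
  cat("\n")
})
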