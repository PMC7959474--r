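#' TrialBundle: one trial observed by both systems, with ground truth
#'
#' @slot reference The constant-rate reference \code{Recording}.
#' @slot test The variable-rate test \code{Recording}.
#' @slot truth The generating \code{TruthTrajectories} (noise-free), or an
#'   empty placeholder when a bundle is re-read from disk.
#' @slot geometry The subject's \code{HandGeometry}.
#' @slot seed Integer seed the bundle was generated from.
#' @slot metadata Named list: subject, task, trial, type
#'   ("dynamic"/"static").
#' @export
setClass("TrialBundle", representation(reference = "Recording",
                                       test = "Recording",
                                       truth = "ANY",
                                       geometry = "ANY",
                                       seed = "numeric",
                                       metadata = "list"))

setValidity("TrialBundle", function(object) {
  tr <- object@reference@times
  tt <- object@test@times
  if (length(tr) < 2 || length(tt) < 2)
    return("both recordings need at least two frames")
  TRUE
})

setMethod("show", "TrialBundle", function(object) {
  md <- object@metadata
  cat(sprintf("TrialBundle subject=%s task=%s trial=%s (%s)\n",
              md$subject %||% "?", md$task %||% "?", md$trial %||% "?",
              md$type %||% "dynamic"))
  cat(sprintf("  reference: %d frames | test: %d frames\n",
              nFrames(object@reference), nFrames(object@test)))
})

#' Generate a complete synthetic paired-systems study
#'
#' Emulates the shape of a two-system validation protocol: every subject
#' receives a randomised skeleton drawn around the population norms, performs
#' one static trial and, per dynamic trial, every movement task, each
#' observed simultaneously by the reference and the test sensor. With the
#' defaults (10 subjects, 2 trials, 6 tasks) this yields 120 dynamic and 10
#' static bundles. Output is fully deterministic given \code{baseSeed}.
#'
#' @param nSubjects Number of subjects (>= 1).
#' @param trialsPerSubject Dynamic trials per subject (>= 1).
#' @param profiles Named list of dynamic \code{TaskProfile}s.
#' @param referenceSensor,testSensor The two \code{SensorModel}s.
#' @param baseSeed Integer master seed.
#' @param geometryNorms Population norms for per-subject skeleton draws.
#' @param includeStatic Add one static trial per subject.
#' @param speedRange Range of the per-trial uniform speed multiplier on the
#'   cycle duration (movement speed is not fixed).
#' @return List of \code{TrialBundle}s (dynamic first, then static).
#' @export
#' @examples
#' bundles <- generateStudy(nSubjects = 1, trialsPerSubject = 1,
#'                          profiles = defaultTaskProfiles()["index_flexion"],
#'                          baseSeed = 1, includeStatic = FALSE)
#' bundles[[1]]
generateStudy <- function(nSubjects = 10, trialsPerSubject = 2,
                          profiles = defaultTaskProfiles(),
                          referenceSensor = handkin::referenceSensor(),
                          testSensor = handkin::testSensor(),
                          baseSeed = 1,
                          geometryNorms = segmentLengthNorms(),
                          includeStatic = TRUE,
                          speedRange = c(0.8, 1.25)) {
  if (nSubjects < 1) stop("'nSubjects' must be >= 1")
  if (trialsPerSubject < 1) stop("'trialsPerSubject' must be >= 1")
  if (!length(profiles)) stop("at least one task profile is required")

  nTasks <- length(profiles)
  nPerSubject <- trialsPerSubject * nTasks + as.integer(includeStatic)
  # one seed per subject geometry + 4 per bundle (speed, truth grid unused,
  # reference render, test render)
  seeds <- .splitSeed(baseSeed, nSubjects * (1 + 4 * nPerSubject))
  si <- 0L
  nextSeed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  bundles <- list()
  statics <- list()
  for (s in seq_len(nSubjects)) {
    geom <- withSeed(nextSeed(), drawHandGeometry(geometryNorms))
    subj <- sprintf("S%02d", s)
    for (trial in seq_len(trialsPerSubject)) {
      for (taskName in names(profiles)) {
        sSpeed <- nextSeed(); sTruth <- nextSeed()
        sRef <- nextSeed(); sTest <- nextSeed()
        speed <- withSeed(sSpeed, stats::runif(1, speedRange[1], speedRange[2]))
        truth <- generateTruth(profiles[[taskName]], speed = speed)
        bundles[[length(bundles) + 1L]] <- .makeBundle(
          truth, geom, referenceSensor, testSensor, sRef, sTest,
          list(subject = subj, task = taskName, trial = trial,
               type = "dynamic"), sTruth)
      }
    }
    if (includeStatic) {
      sSpeed <- nextSeed(); sTruth <- nextSeed()
      sRef <- nextSeed(); sTest <- nextSeed()
      truth <- generateTruth(staticTaskProfile())
      statics[[length(statics) + 1L]] <- .makeBundle(
        truth, geom, referenceSensor, testSensor, sRef, sTest,
        list(subject = subj, task = "static", trial = 1, type = "static"),
        sTruth)
    }
  }
  c(bundles, statics)
}

.makeBundle <- function(truth, geometry, refSensor, testSensor,
                        seedRef, seedTest, metadata, bundleSeed) {
  ref <- renderStream(truth, geometry, refSensor, seedRef)
  tst <- renderStream(truth, geometry, testSensor, seedTest)
  ref@metadata <- c(ref@metadata, metadata)
  tst@metadata <- c(tst@metadata, metadata)
  new("TrialBundle", reference = ref, test = tst, truth = truth,
      geometry = geometry, seed = bundleSeed, metadata = metadata)
}

#' Write a ground truth table as long CSV
#'
#' Columns \code{joint,time_s,angle_deg}, one row per joint and dense-grid
#' time point.
#'
#' @param truth A \code{TruthTrajectories}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  A <- truth@angles
  df <- data.table::data.table(
    joint = rep(colnames(A), each = nrow(A)),
    time_s = rep(truth@times, ncol(A)),
    angle_deg = as.vector(A))
  data.table::fwrite(df, path)
  invisible(path)
}
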