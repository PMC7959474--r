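#' PipelineConfig: end-to-end analysis settings
#'
#' All defaults are explicit and are echoed (with a config fingerprint) into
#' every output the pipeline writes.
#'
#' @slot targetRate Uniform resampling rate, Hz (default 150).
#' @slot normPoints Time-normalisation grid size (default 101).
#' @slot alpha Significance level for the proportional-bias test.
#' @slot poolingRule ROM pooling across trials for the summary table
#'   ("mean", "median", "max").
#' @slot agreementMetric Per-trial quantity paired in the Bland-Altman
#'   analysis: "rom" (default), "peak", or "mean" (mean angle over the
#'   common time window; the metric that responds one-to-one to an additive
#'   bias).
#' @slot signConvention Difference sign, reference system first by default.
#' @slot smoothCutoffHz Low-pass cutoff applied to resampled recordings
#'   before angle computation (\code{NA} = no filtering, the default).
#' @slot seed Integer seed recorded with outputs.
#' @export
setClass("PipelineConfig", representation(targetRate = "numeric",
                                          normPoints = "numeric",
                                          alpha = "numeric",
                                          poolingRule = "character",
                                          agreementMetric = "character",
                                          signConvention = "character",
                                          smoothCutoffHz = "numeric",
                                          seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  if (object@targetRate <= 0) return("targetRate must be > 0")
  if (object@normPoints < 2) return("normPoints must be >= 2")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (!object@poolingRule %in% c("mean", "median", "max"))
    return("poolingRule must be mean/median/max")
  if (!object@agreementMetric %in% c("rom", "peak", "mean"))
    return("agreementMetric must be rom/peak/mean")
  if (!object@signConvention %in% c("reference_minus_test",
                                    "test_minus_reference"))
    return("unknown signConvention")
  if (!is.na(object@smoothCutoffHz) && object@smoothCutoffHz <= 0)
    return("smoothCutoffHz must be positive (or NA for no filtering)")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param targetRate,normPoints,alpha,poolingRule,agreementMetric,signConvention,smoothCutoffHz,seed
#'   See \code{\linkS4class{PipelineConfig}}.
#' @return A validated \code{PipelineConfig}.
#' @export
pipelineConfig <- function(targetRate = 150, normPoints = 101, alpha = 0.05,
                           poolingRule = "mean", agreementMetric = "rom",
                           signConvention = "reference_minus_test",
                           smoothCutoffHz = NA_real_, seed = 1) {
  obj <- new("PipelineConfig", targetRate = targetRate,
             normPoints = normPoints, alpha = alpha,
             poolingRule = poolingRule, agreementMetric = agreementMetric,
             signConvention = signConvention,
             smoothCutoffHz = as.numeric(smoothCutoffHz), seed = seed)
  validObject(obj)
  obj
}

.configList <- function(config) {
  list(targetRate = config@targetRate, normPoints = config@normPoints,
       alpha = config@alpha, poolingRule = config@poolingRule,
       agreementMetric = config@agreementMetric,
       signConvention = config@signConvention,
       smoothCutoffHz = config@smoothCutoffHz, seed = config@seed)
}

# FNV-1a fingerprint of the serialised config, hex string
configHash <- function(config) {
  s <- jsonlite::toJSON(.configList(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves to stay exact
    hLo <- h %% 65536
    hHi <- (h - hLo) / 65536
    h <- (hLo * 16777619 + ((hHi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  hLo <- h %% 65536
  sprintf("%04x%04x", (h - hLo) / 65536, hLo)
}

.taskJointsFromName <- function(task) {
  if (task %in% c("thumb_flexion", "thumb_abduction"))
    return(c("thumb_cmc", "thumb_mcp", "thumb_ip"))
  if (grepl("_flexion$", task)) {
    f <- sub("_flexion$", "", task)
    if (f %in% .NON_THUMB) return(paste(f, c("mcp", "pip", "dip"), sep = "_"))
  }
  if (task == "static") return(handJoints())
  handJoints()
}

#' Analyse a set of trial bundles in memory
#'
#' Runs the full comparison pipeline on paired recordings: rebuild the test
#' stream's timeline and resample both streams to the target rate, compute
#' joint-angle trajectories, extract per-trial ROM/peak/mean metrics per
#' joint, and run a Bland-Altman analysis per task and joint across trials.
#' Static bundles feed the segment-length summary instead.
#'
#' @param bundles List of \code{TrialBundle}s (ground truth not required).
#' @param config A \code{\link{pipelineConfig}}.
#' @return List with elements \code{rom_records} (per trial/joint/system),
#'   \code{rom_table}, \code{agreement} (one row per task/joint),
#'   \code{agreement_results} (the \code{AgreementResult} objects),
#'   \code{ba_points} (per-pair means/differences for plotting),
#'   \code{segment_records}, \code{segment_summary}, \code{trial_log},
#'   and \code{counters}.
#' @export
analyzeBundles <- function(bundles, config = pipelineConfig()) {
  validObject(config)
  romRows <- list(); segRows <- list(); logRows <- list()
  nFailed <- 0L
  for (b in bundles) {
    md <- b@metadata
    res <- tryCatch(
      .analyzeOneBundle(b, config),
      error = function(e) {
        warning(sprintf("trial subject=%s task=%s trial=%s skipped: %s",
                        md$subject %||% "?", md$task %||% "?",
                        md$trial %||% "?", conditionMessage(e)))
        NULL
      })
    if (is.null(res)) {
      nFailed <- nFailed + 1L
      next
    }
    romRows <- c(romRows, list(res$rom))
    if (!is.null(res$segments)) segRows <- c(segRows, list(res$segments))
    logRows <- c(logRows, list(res$log))
  }
  romRecords <- if (length(romRows)) do.call(rbind, romRows) else NULL
  segRecords <- if (length(segRows)) do.call(rbind, segRows) else NULL
  trialLog <- if (length(logRows)) do.call(rbind, logRows) else NULL

  agreementRows <- NULL; baPoints <- NULL; agreementResults <- list()
  dyn <- if (!is.null(romRecords))
    romRecords[romRecords$type == "dynamic", , drop = FALSE] else NULL
  if (!is.null(dyn) && nrow(dyn)) {
    keys <- unique(dyn[, c("task", "joint")])
    metricCol <- switch(config@agreementMetric, rom = "rom", peak = "peak",
                        mean = "mean_angle")
    for (i in seq_len(nrow(keys))) {
      tk <- keys$task[i]; j <- keys$joint[i]
      sub <- dyn[dyn$task == tk & dyn$joint == j, , drop = FALSE]
      ref <- sub[sub$system == "reference", , drop = FALSE]
      tst <- sub[sub$system == "test", , drop = FALSE]
      key <- paste(ref$subject, ref$trial)
      tst <- tst[match(key, paste(tst$subject, tst$trial)), , drop = FALSE]
      ok <- !is.na(tst$rom)
      if (sum(ok) < 2) next
      ba <- blandAltman(ref[[metricCol]][ok], tst[[metricCol]][ok],
                        labels = list(task = tk, joint = j,
                                      metric = config@agreementMetric),
                        signConvention = config@signConvention)
      agreementResults[[paste(tk, j, sep = ".")]] <- ba
      row <- agreementAsRow(ba)
      row$trend <- as.character(trendInterpretation(ba, config@alpha))
      agreementRows <- rbind(agreementRows, row)
      sgn <- if (config@signConvention == "reference_minus_test") 1 else -1
      baPoints <- rbind(baPoints, data.frame(
        task = tk, joint = j, subject = ref$subject[ok],
        trial = ref$trial[ok],
        pair_mean = (ref[[metricCol]][ok] + tst[[metricCol]][ok]) / 2,
        pair_diff = sgn * (ref[[metricCol]][ok] - tst[[metricCol]][ok]),
        bias = ba@bias, loa_low = ba@loa[1], loa_high = ba@loa[2]))
    }
  }

  segmentSummary <- if (!is.null(segRecords))
    summarizeSegmentLengths(segRecords) else NULL

  list(rom_records = romRecords,
       rom_table = if (!is.null(dyn) && nrow(dyn))
         romTable(dyn, pooling = config@poolingRule) else NULL,
       agreement = agreementRows,
       agreement_results = agreementResults,
       ba_points = baPoints,
       segment_records = segRecords,
       segment_summary = segmentSummary,
       trial_log = trialLog,
       counters = c(n_success = length(logRows), n_failed = nFailed),
       config = .configList(config),
       config_hash = configHash(config))
}

.analyzeOneBundle <- function(b, config) {
  md <- b@metadata
  type <- md$type %||% "dynamic"
  tlTest <- suppressWarnings(buildTimeVector(b@test))
  refR <- resampleUniform(b@reference, config@targetRate)
  tstR <- resampleUniform(b@test, config@targetRate, timeline = tlTest)
  if (!is.na(config@smoothCutoffHz)) {
    refR <- smoothRecording(refR, config@smoothCutoffHz)
    tstR <- smoothRecording(tstR, config@smoothCutoffHz)
  }

  logRow <- data.frame(
    subject = md$subject %||% NA, task = md$task %||% NA,
    trial = md$trial %||% NA, type = type,
    test_mean_rate_hz = tstR@metadata$source_mean_rate_hz,
    test_interval_cv = tstR@metadata$source_interval_cv,
    ref_frames = nFrames(b@reference), test_frames = nFrames(b@test))

  segs <- NULL
  if (type == "static") {
    segs <- rbind(
      cbind(segmentLengths(refR), system = "reference"),
      cbind(segmentLengths(tstR), system = "test"))
    segs$subject <- md$subject %||% NA
  }

  joints <- .taskJointsFromName(md$task %||% "static")
  window <- c(0, min(max(refR@times), max(tstR@times)))
  romRows <- list()
  for (sys in c("reference", "test")) {
    rec <- if (sys == "reference") refR else tstR
    trajs <- angleTrajectories(rec, joints)
    for (j in names(trajs)) {
      met <- trajectoryMetrics(trajs[[j]], window = window)
      r <- rom(trajs[[j]])
      romRows[[length(romRows) + 1L]] <- data.frame(
        subject = md$subject %||% NA, task = md$task %||% NA,
        trial = md$trial %||% NA, type = type, system = sys, joint = j,
        angle_min = r$angle_min, angle_max = r$angle_max, rom = r$rom,
        peak = met[["peak"]], mean_angle = met[["mean"]])
    }
  }
  list(rom = do.call(rbind, romRows), segments = segs, log = logRow)
}

#' Simulate a study and write it to disk
#'
#' Generates the synthetic study deterministically from \code{baseSeed} and
#' writes one reference and one test CSV per trial (wide landmark format,
#' with JSON metadata sidecars), optionally the ground-truth angle tables,
#' and a manifest listing every file together with the configuration echo,
#' its fingerprint and the package version.
#'
#' @param outDir Output directory (created if needed).
#' @param baseSeed Master seed.
#' @param config A \code{PipelineConfig} (echoed into the manifest).
#' @param writeTruthFiles Also write per-trial truth CSVs (long format,
#'   \code{joint,time_s,angle_deg}) at the truth grid rate.
#' @param ... Passed to \code{\link{generateStudy}}.
#' @return The manifest, invisibly.
#' @export
simulateStudy <- function(outDir, baseSeed = 1, config = pipelineConfig(),
                          writeTruthFiles = FALSE, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  bundles <- generateStudy(baseSeed = baseSeed, ...)
  entries <- list()
  for (b in bundles) {
    md <- b@metadata
    id <- sprintf("%s_T%d_%s", md$subject, md$trial, md$task)
    refPath <- file.path(outDir, paste0(id, "_reference.csv"))
    tstPath <- file.path(outDir, paste0(id, "_test.csv"))
    writeRecording(b@reference, refPath)
    writeRecording(b@test, tstPath)
    entry <- list(id = id, subject = md$subject, task = md$task,
                  trial = md$trial, type = md$type,
                  reference = basename(refPath), test = basename(tstPath))
    if (writeTruthFiles) {
      trPath <- file.path(outDir, paste0(id, "_truth.csv"))
      writeTruth(b@truth, trPath)
      entry$truth <- basename(trPath)
    }
    entries[[length(entries) + 1L]] <- entry
  }
  manifest <- list(
    package = "handkin",
    version = as.character(utils::packageVersion("handkin")),
    base_seed = baseSeed,
    config = .configList(config),
    config_hash = configHash(config),
    n_dynamic = sum(vapply(bundles, function(b) b@metadata$type == "dynamic",
                           logical(1))),
    n_static = sum(vapply(bundles, function(b) b@metadata$type == "static",
                          logical(1))),
    trials = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyse a simulated study directory
#'
#' Reads the manifest and every trial's recordings, skips (and counts)
#' trials whose files are missing or malformed, runs
#' \code{\link{analyzeBundles}}, and writes the ROM records and table, the
#' agreement table, the Bland-Altman point data, the segment-length summary
#' and a JSON echo of the configuration and success/failure counters.
#'
#' @param inDir Directory written by \code{\link{simulateStudy}}.
#' @param outDir Output directory.
#' @param config A \code{PipelineConfig}.
#' @return The analysis list (see \code{\link{analyzeBundles}}), invisibly.
#' @export
analyzeStudy <- function(inDir, outDir, config = pipelineConfig()) {
  manPath <- file.path(inDir, "manifest.json")
  if (!file.exists(manPath)) stop("no manifest.json in ", inDir)
  manifest <- jsonlite::read_json(manPath, simplifyVector = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bundles <- list(); nMissing <- 0L
  for (e in manifest$trials) {
    refPath <- file.path(inDir, e$reference)
    tstPath <- file.path(inDir, e$test)
    if (!file.exists(refPath) || !file.exists(tstPath)) {
      warning("trial ", e$id, " skipped: missing recording file")
      nMissing <- nMissing + 1L
      next
    }
    ref <- readRecording(refPath)
    tst <- readRecording(tstPath)
    md <- list(subject = e$subject, task = e$task, trial = e$trial,
               type = e$type)
    bundles[[length(bundles) + 1L]] <- new(
      "TrialBundle", reference = ref, test = tst, truth = NULL,
      geometry = NULL, seed = NA_real_, metadata = md)
  }
  res <- analyzeBundles(bundles, config)
  res$counters["n_missing"] <- nMissing

  wr <- function(df, name) if (!is.null(df))
    data.table::fwrite(data.table::as.data.table(df),
                       file.path(outDir, name))
  wr(res$rom_records, "rom_records.csv")
  wr(res$rom_table, "rom_table.csv")
  wr(res$agreement, "agreement.csv")
  wr(res$ba_points, "ba_points.csv")
  wr(res$segment_summary, "segment_summary.csv")
  wr(res$trial_log, "trial_log.csv")
  jsonlite::write_json(
    list(package = "handkin",
         version = as.character(utils::packageVersion("handkin")),
         config = res$config, config_hash = res$config_hash,
         counters = as.list(res$counters)),
    file.path(outDir, "analysis.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(res)
}

#' Write a human-readable study report
#'
#' Collates the analysis outputs into one plain-text summary: the
#' segment-length table, the pooled ROM comparison table, and one
#' Bland-Altman block per task and joint. Regenerating from identical
#' inputs yields identical bytes.
#'
#' @param inDir Directory written by \code{\link{analyzeStudy}}.
#' @param outFile Path of the report file to write.
#' @return \code{outFile}, invisibly.
#' @export
reportStudy <- function(inDir, outFile) {
  aj <- file.path(inDir, "analysis.json")
  if (!file.exists(aj)) stop("no analysis outputs in ", inDir)
  meta <- jsonlite::read_json(aj, simplifyVector = TRUE)
  lines <- c("Paired-systems hand kinematics study report",
             sprintf("package handkin %s | config %s", meta$version,
                     meta$config_hash),
             sprintf("trials analysed: %s successful, %s failed, %s missing",
                     meta$counters$n_success %||% 0,
                     meta$counters$n_failed %||% 0,
                     meta$counters$n_missing %||% 0), "")
  segPath <- file.path(inDir, "segment_summary.csv")
  if (file.exists(segPath)) {
    seg <- data.table::fread(segPath, data.table = FALSE)
    lines <- c(lines, "Segment lengths, across-subject mean (sd), mm:",
               sprintf("  %-7s %-12s test %7.2f (%5.2f)   reference %s",
                       seg$finger, seg$segment, seg$test_mean_mm,
                       seg$test_sd_mm,
                       ifelse(is.na(seg$reference_mean_mm), "   --",
                              sprintf("%7.2f (%5.2f)", seg$reference_mean_mm,
                                      seg$reference_sd_mm))), "")
  }
  romPath <- file.path(inDir, "rom_table.csv")
  if (file.exists(romPath)) {
    romT <- data.table::fread(romPath, data.table = FALSE)
    lines <- c(lines, "Range of motion (pooled across trials), degrees:",
               sprintf("  %-16s %-10s test %7.2f  reference %7.2f  diff %7.2f",
                       romT$task, romT$joint, romT$rom_test,
                       romT$rom_reference, romT$difference), "")
  }
  agrPath <- file.path(inDir, "agreement.csv")
  if (file.exists(agrPath)) {
    agr <- data.table::fread(agrPath, data.table = FALSE)
    lines <- c(lines, "Bland-Altman agreement per task and joint:")
    for (i in seq_len(nrow(agr))) {
      a <- agr[i, , drop = FALSE]
      lines <- c(lines, sprintf(
        "  %s / %s (n=%d, metric=%s): bias %.2f [CI %.2f, %.2f], LoA [%.2f, %.2f], r=%s, P=%s -> %s",
        a$task, a$joint, a$n, a$metric, a$bias, a$ci_low, a$ci_high,
        a$loa_low, a$loa_high,
        ifelse(a$r_defined, sprintf("%.4f", a$r), "undef"),
        ifelse(a$r_defined, sprintf("%.4f", a$p), "undef"), a$trend))
    }
  }
  writeLines(lines, outFile)
  invisible(outFile)
}

#' Published example ROM comparison table
#'
#' A small bundled example of the field's standard reporting format: pooled
#' per-joint range of motion for a markerless tracker (LMC) and a
#' marker-based system (QTM) over six movement tasks, with the
#' reference-minus-test column. Useful for exercising
#' \code{\link{romDifference}} and table utilities without running a study.
#'
#' @return \code{data.frame}: task, joint, rom_lmc, rom_qtm, qtm_minus_lmc.
#' @export
exampleRomTable <- function() {
  path <- system.file("extdata", "rom_comparison_example.csv",
                      package = "handkin")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
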