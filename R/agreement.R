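#' AgreementResult: Bland-Altman agreement between two measurement systems
#'
#' Holds the full Bland-Altman summary for one set of paired measurements:
#' the mean difference (bias), the sample sd of the differences, the limits
#' of agreement (bias +/- 1.96 sd by convention), the 95% t-based confidence
#' interval of the bias, and the Pearson correlation of the per-pair
#' differences against the per-pair means, whose significance flags a
#' proportional bias (the difference growing with the magnitude measured).
#'
#' @slot n Number of pairs.
#' @slot bias Mean difference, degrees.
#' @slot sdDiff Sample sd (n - 1) of the differences.
#' @slot loa Numeric length-2: lower and upper limit of agreement.
#' @slot ciBias Numeric length-2: 95% CI of the bias.
#' @slot r Pearson correlation of differences vs means (NaN when the
#'   differences or means are constant: undefined, never reported as 0).
#' @slot p Two-sided p-value of r (t transform, n - 2 df).
#' @slot rDefined Whether r could be computed.
#' @slot signConvention \code{"reference_minus_test"} (default) or
#'   \code{"test_minus_reference"}.
#' @slot labels Named list describing what was paired (joint, task, metric,
#'   ...).
#' @export
setClass("AgreementResult", representation(n = "numeric", bias = "numeric",
                                           sdDiff = "numeric",
                                           loa = "numeric",
                                           ciBias = "numeric",
                                           r = "numeric", p = "numeric",
                                           rDefined = "logical",
                                           signConvention = "character",
                                           labels = "list"))

setValidity("AgreementResult", function(object) {
  if (length(object@loa) != 2 || length(object@ciBias) != 2)
    return("loa and ciBias must have length 2")
  if (object@loa[1] > object@bias + 1e-12 || object@loa[2] < object@bias - 1e-12)
    return("limits of agreement must bracket the bias")
  if (object@rDefined && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
    return("r must lie in [-1, 1]")
  TRUE
})

setMethod("show", "AgreementResult", function(object) {
  lab <- object@labels
  hdr <- if (length(lab)) paste0(" [", paste(sprintf("%s=%s", names(lab), unlist(lab)),
                                             collapse = " "), "]") else ""
  cat(sprintf("Bland-Altman agreement (n=%d)%s\n", object@n, hdr))
  cat(sprintf("  bias %.3f deg (95%% CI %.3f to %.3f), sd of differences %.3f\n",
              object@bias, object@ciBias[1], object@ciBias[2], object@sdDiff))
  cat(sprintf("  limits of agreement %.3f to %.3f\n",
              object@loa[1], object@loa[2]))
  if (object@rDefined)
    cat(sprintf("  trend: r = %.4f, P = %.4f\n", object@r, object@p))
  else cat("  trend: r undefined (constant differences or means)\n")
})

#' Bland-Altman analysis of paired measurements
#'
#' For pairs \eqn{(x_i, y_i)} (reference, test) the per-pair difference is
#' \eqn{d_i = x_i - y_i} under the default sign convention and the per-pair
#' mean is \eqn{m_i = (x_i + y_i)/2}. The bias is \eqn{\bar d}; the limits
#' of agreement are \eqn{\bar d \pm 1.96\, s_d} with \eqn{s_d} the sample sd
#' of the differences; the bias CI is
#' \eqn{\bar d \pm t_{0.975, n-1}\, s_d/\sqrt n}; and the trend statistic is
#' the Pearson correlation of \eqn{(m_i, d_i)} with a two-sided p-value from
#' the t transform on \eqn{n - 2} df. With fewer than 3 pairs (or constant
#' differences/means) r and p are undefined and flagged, never zero.
#'
#' The result is invariant to the order of the pairs; swapping reference and
#' test negates the bias and r and mirrors the limits of agreement.
#'
#' @param reference,test Numeric vectors of paired measurements (equal
#'   length >= 2), reference (gold-standard) system first.
#' @param labels Named list recorded in the result (joint, task, ...).
#' @param signConvention \code{"reference_minus_test"} (default, matching
#'   the package-wide reference-minus-test reporting) or
#'   \code{"test_minus_reference"}.
#' @param loaMultiplier Multiplier on \eqn{s_d} for the limits of agreement
#'   (1.96, the large-sample 95% convention).
#' @param conf Confidence level of the bias CI.
#' @return An \code{\link{AgreementResult}}.
#' @export
#' @examples
#' ba <- blandAltman(c(10, 20, 30, 40, 50), c(12, 19, 33, 36, 55))
#' ba
blandAltman <- function(reference, test, labels = list(),
                        signConvention = c("reference_minus_test",
                                           "test_minus_reference"),
                        loaMultiplier = 1.96, conf = 0.95) {
  signConvention <- match.arg(signConvention)
  if (length(reference) != length(test))
    stop("'reference' and 'test' must have the same length")
  n <- length(reference)
  if (n < 2) stop("need at least 2 pairs")
  if (anyNA(reference) || anyNA(test)) stop("paired values must not be NA")
  d <- if (signConvention == "reference_minus_test") reference - test
       else test - reference
  m <- (reference + test) / 2
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  loa <- bias + c(-1, 1) * loaMultiplier * sdDiff
  alpha <- 1 - conf
  ci <- bias + c(-1, 1) * stats::qt(1 - alpha / 2, n - 1) * sdDiff / sqrt(n)
  r <- NaN; p <- NaN; rDefined <- FALSE
  if (n >= 3 && sdDiff > 0 && stats::sd(m) > 0) {
    r <- stats::cor(m, d)
    if (is.finite(r) && abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
      rDefined <- TRUE
    } else if (is.finite(r)) {
      p <- 0
      rDefined <- TRUE
    }
  }
  new("AgreementResult", n = n, bias = bias, sdDiff = sdDiff, loa = loa,
      ciBias = ci, r = r, p = p, rDefined = rDefined,
      signConvention = signConvention, labels = labels)
}

#' Interpret the trend of a Bland-Altman result
#'
#' A significant correlation between per-pair differences and means marks a
#' proportional bias: the disagreement grows with the magnitude being
#' measured. The test is strict (\eqn{p < \alpha}); an undefined r yields
#' \code{"no_trend"} with an attribute flag.
#'
#' @param result An \code{AgreementResult}.
#' @param alpha Significance level (default 0.05).
#' @return \code{"proportional_bias"} or \code{"no_trend"}; when r was
#'   undefined the result carries \code{attr(, "undefined") = TRUE}.
#' @export
trendInterpretation <- function(result, alpha = 0.05) {
  stopifnot(is(result, "AgreementResult"))
  if (!result@rDefined) {
    out <- "no_trend"
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (result@p < alpha) "proportional_bias" else "no_trend"
}

#' One-row data.frame view of an AgreementResult
#'
#' @param result An \code{AgreementResult}.
#' @return \code{data.frame} with the labels and all summary fields.
#' @export
agreementAsRow <- function(result) {
  lab <- result@labels
  base <- if (length(lab)) as.data.frame(lab, stringsAsFactors = FALSE)
          else data.frame(row.names = 1)
  cbind(base, data.frame(
    n = result@n, bias = result@bias, sd_diff = result@sdDiff,
    loa_low = result@loa[1], loa_high = result@loa[2],
    ci_low = result@ciBias[1], ci_high = result@ciBias[2],
    r = result@r, p = result@p, r_defined = result@rDefined))
}

#' Summarise segment lengths across subjects, per system
#'
#' Takes per-subject, per-system segment-length records (one mean length per
#' subject/finger/segment/system) and reports the across-subject mean and
#' sample sd side by side for the two systems. Following the usual
#' marker-based reporting rule, metacarpal segments of the reference system
#' are dropped for all fingers but the thumb. Cells with no data are omitted
#' with a warning.
#'
#' @param records \code{data.frame} with columns subject, system, finger,
#'   segment, mean_mm.
#' @param referenceLabel,testLabel System labels in \code{records}.
#' @param applyMetacarpalRule Apply the reference-metacarpal reporting rule.
#' @return \code{data.frame}: finger, segment, test_mean_mm, test_sd_mm,
#'   reference_mean_mm, reference_sd_mm (NA where a system does not report
#'   the segment).
#' @export
summarizeSegmentLengths <- function(records, referenceLabel = "reference",
                                    testLabel = "test",
                                    applyMetacarpalRule = TRUE) {
  need <- c("subject", "system", "finger", "segment", "mean_mm")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (applyMetacarpalRule) {
    drop <- records$system == referenceLabel &
      records$segment == "metacarpal" & records$finger != "thumb"
    records <- records[!drop, , drop = FALSE]
  }
  agg <- stats::aggregate(mean_mm ~ finger + segment + system, records,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v) else 0))
  agg <- do.call(data.frame, agg)
  names(agg)[4:5] <- c("mean_mm", "sd_mm")
  cells <- unique(records[, c("finger", "segment")])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    f <- cells$finger[i]; sgm <- cells$segment[i]
    row <- data.frame(finger = f, segment = sgm,
                      test_mean_mm = NA_real_, test_sd_mm = NA_real_,
                      reference_mean_mm = NA_real_, reference_sd_mm = NA_real_)
    for (sys in c(testLabel, referenceLabel)) {
      hit <- agg[agg$finger == f & agg$segment == sgm & agg$system == sys, ]
      pre <- if (sys == testLabel) "test" else "reference"
      if (nrow(hit)) {
        row[[paste0(pre, "_mean_mm")]] <- hit$mean_mm
        row[[paste0(pre, "_sd_mm")]] <- hit$sd_mm
      }
    }
    out <- rbind(out, row)
  }
  segOrder <- c("distal", "intermediate", "proximal", "metacarpal")
  out[order(match(out$finger, .FINGERS), match(out$segment, segOrder)), ,
      drop = FALSE]
}

#' Per-joint ROM comparison table
#'
#' Pools per-trial ROM records into one row per task and joint with the test
#' and reference system side by side and their difference (reference minus
#' test). The pooling rule across trials/subjects is configurable because
#' published tables rarely state it; the default is the mean.
#'
#' @param romRecords \code{data.frame} with columns system, task, joint, rom
#'   (one row per trial).
#' @param pooling \code{"mean"}, \code{"median"} or \code{"max"} (pooled
#'   max-min is not available from per-trial ROMs; "max" pools the per-trial
#'   ROM maxima).
#' @param referenceLabel,testLabel System labels.
#' @return \code{data.frame}: task, joint, rom_test, rom_reference,
#'   difference. Joints present for only one system are omitted with a
#'   warning.
#' @export
romTable <- function(romRecords, pooling = c("mean", "median", "max"),
                     referenceLabel = "reference", testLabel = "test") {
  pooling <- match.arg(pooling)
  need <- c("system", "task", "joint", "rom")
  if (!all(need %in% names(romRecords)))
    stop("romRecords must have columns: ", paste(need, collapse = ", "))
  poolFun <- switch(pooling, mean = mean, median = stats::median, max = max)
  agg <- stats::aggregate(rom ~ task + joint + system, romRecords, poolFun)
  out <- NULL
  keys <- unique(agg[, c("task", "joint")])
  for (i in seq_len(nrow(keys))) {
    tk <- keys$task[i]; j <- keys$joint[i]
    ref <- agg$rom[agg$task == tk & agg$joint == j & agg$system == referenceLabel]
    tst <- agg$rom[agg$task == tk & agg$joint == j & agg$system == testLabel]
    if (!length(ref) || !length(tst)) {
      warning(sprintf("task %s joint %s present for only one system; row omitted",
                      tk, j))
      next
    }
    out <- rbind(out, data.frame(task = tk, joint = j, rom_test = tst,
                                 rom_reference = ref,
                                 difference = romDifference(ref, tst)))
  }
  out
}
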