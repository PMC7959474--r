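# Landmark topology and forward kinematics of the simulated hand.
#
# Coordinate frame (device frame): +X from ulnar to radial styloid, +Z from the
# wrist towards the metacarpal heads, +Y the common perpendicular. The palm lies
# in the X-Z plane at rest; flexion rotates each finger chain within its own
# sagittal plane (the plane spanned by the finger's metacarpal direction and
# +Y), thumb abduction rotates the whole thumb chain within the palm plane.

.FINGERS <- c("thumb", "index", "middle", "ring", "pinky")
.NON_THUMB <- c("index", "middle", "ring", "pinky")
.SEGMENTS_FULL <- c("metacarpal", "proximal", "intermediate", "distal")
.SEGMENTS_THUMB <- c("metacarpal", "proximal", "distal")

# resting azimuth of each finger's metacarpal direction in the palm (X-Z)
# plane, degrees about +Y measured from +Z towards +X
.AZIMUTH_DEG <- c(thumb = 50, index = 15, middle = 0, ring = -15, pinky = -30)

# carpal offset: distance from the wrist joint centre to the metacarpal base
# (thumb: to the CMC joint centre), mm
.BASE_OFFSET_MM <- c(thumb = 15, index = 20, middle = 20, ring = 20, pinky = 20)

.DEG <- pi / 180

#' Landmark labels of the hand model
#'
#' The model tracks 25 joint-centre landmarks: the wrist, and per finger an
#' ordered chain from the palm outwards. Non-thumb fingers carry a metacarpal
#' base, MCP, PIP and DIP joint centres and the fingertip; the thumb, which
#' has one bone fewer, carries CMC, MCP and IP joint centres and the tip.
#'
#' @return Character vector of landmark names, wrist first, then each finger
#'   chain in proximal-to-distal order.
#' @export
#' @examples
#' handLandmarks()
handLandmarks <- function() {
  out <- "wrist"
  for (f in .FINGERS) {
    out <- c(out, paste(f, .chainSuffixes(f), sep = "_"))
  }
  out
}

.chainSuffixes <- function(finger) {
  if (finger == "thumb") c("cmc", "mcp", "ip", "tip") else c("base", "mcp", "pip", "dip", "tip")
}

#' Joint labels of the hand model
#'
#' @param includeAbduction Logical; append the thumb abduction degree of
#'   freedom (a palm-plane rotation, not a three-point flexion angle).
#' @return Character vector of joint names: three flexion joints per finger
#'   (thumb CMC/MCP/IP; otherwise MCP/PIP/DIP), optionally plus
#'   \code{"thumb_abduction"}.
#' @export
handJoints <- function(includeAbduction = FALSE) {
  out <- c("thumb_cmc", "thumb_mcp", "thumb_ip")
  for (f in .NON_THUMB) out <- c(out, paste(f, c("mcp", "pip", "dip"), sep = "_"))
  if (includeAbduction) out <- c(out, "thumb_abduction")
  out
}

# (a, b, c) landmark triple defining each flexion joint: the joint angle is
# the angle between vectors b-a and c-b
.jointTriples <- function() {
  if (!is.null(.cache$jointTriples)) return(.cache$jointTriples)
  rows <- list(
    c("thumb_cmc", "wrist", "thumb_cmc", "thumb_mcp"),
    c("thumb_mcp", "thumb_cmc", "thumb_mcp", "thumb_ip"),
    c("thumb_ip", "thumb_mcp", "thumb_ip", "thumb_tip")
  )
  for (f in .NON_THUMB) {
    rows <- c(rows, list(
      c(paste0(f, "_mcp"), "wrist", paste0(f, "_mcp"), paste0(f, "_pip")),
      c(paste0(f, "_pip"), paste0(f, "_mcp"), paste0(f, "_pip"), paste0(f, "_dip")),
      c(paste0(f, "_dip"), paste0(f, "_pip"), paste0(f, "_dip"), paste0(f, "_tip"))
    ))
  }
  m <- do.call(rbind, rows)
  .cache$jointTriples <- data.frame(joint = m[, 1], a = m[, 2], b = m[, 3],
                                    c = m[, 4], stringsAsFactors = FALSE)
  .cache$jointTriples
}

# consecutive landmark pairs defining each bone segment
.segmentPairs <- function() {
  rows <- list()
  for (f in .FINGERS) {
    chain <- paste(f, .chainSuffixes(f), sep = "_")
    segs <- if (f == "thumb") .SEGMENTS_THUMB else .SEGMENTS_FULL
    for (i in seq_along(segs)) {
      rows <- c(rows, list(c(f, segs[i], chain[i], chain[i + 1])))
    }
  }
  m <- do.call(rbind, rows)
  data.frame(finger = m[, 1], segment = m[, 2], from = m[, 3], to = m[, 4],
             stringsAsFactors = FALSE)
}

.cache <- new.env(parent = emptyenv())

.posColumns <- function() {
  if (is.null(.cache$posColumns)) {
    lm <- handLandmarks()
    .cache$posColumns <-
      paste0(rep(lm, each = 3), rep(c("_x_mm", "_y_mm", "_z_mm"), length(lm)))
  }
  .cache$posColumns
}

.lmCols <- function(landmark) paste0(landmark, c("_x_mm", "_y_mm", "_z_mm"))

#' Forward kinematics: landmark positions from joint angles
#'
#' Places every landmark of the hand in 3D given segment lengths and joint
#' angles. Each finger flexes in a fixed sagittal plane containing its
#' metacarpal direction; a flexion angle of 0 means the adjacent segments are
#' collinear (straight finger). Thumb abduction rotates the whole thumb chain
#' within the palm plane about the wrist before flexion is applied, so it
#' leaves the thumb's three-point flexion angles unchanged.
#'
#' Distances between consecutive landmarks equal the configured segment
#' lengths exactly, and re-deriving angles from the returned positions (see
#' \code{\link{jointAngle}}) reproduces the inputs to floating precision.
#'
#' @param geometry A \code{\link{HandGeometry}}.
#' @param angles Either a named numeric vector of joint angles in degrees
#'   (one pose) or a numeric matrix with one row per frame and joint names as
#'   columns. Valid names are \code{handJoints(includeAbduction = TRUE)};
#'   absent joints are held at 0. Flexion angles must lie in [0, 180);
#'   thumb abduction in (-90, 90).
#' @param wristOrigin Numeric 3-vector, wrist position in mm.
#' @param fingers Fingers to place (default all five); the wrist is always
#'   included. Restricting the set mimics a partial marker set and reduces
#'   cost in large simulations.
#' @return For a vector input, a landmarks x 3 matrix of positions (rows
#'   named by landmark, columns x/y/z, mm). For a matrix input, an
#'   \code{nFrames x (3 nLandmarks)} matrix with columns
#'   \code{<landmark>_<axis>_mm}.
#' @export
#' @examples
#' g <- defaultHandGeometry()
#' p <- forwardPose(g, c(index_pip = 90))
#' p["index_tip", ]
forwardPose <- function(geometry, angles, wristOrigin = c(0, 0, 0),
                        fingers = .FINGERS) {
  stopifnot(is(geometry, "HandGeometry"))
  validObject(geometry)
  if (!length(fingers) || !all(fingers %in% .FINGERS))
    stop("'fingers' must be a non-empty subset of: ",
         paste(.FINGERS, collapse = ", "))
  single <- is.null(dim(angles))
  A <- if (single) {
    if (length(angles) && is.null(names(angles)))
      stop("'angles' must be named by joint")
    matrix(angles, nrow = 1, dimnames = list(NULL, names(angles)))
  } else {
    as.matrix(angles)
  }
  allJoints <- handJoints(includeAbduction = TRUE)
  unknown <- setdiff(colnames(A), allJoints)
  if (length(unknown)) stop("unknown joint(s): ", paste(unknown, collapse = ", "))
  n <- nrow(A)
  full <- matrix(0, n, length(allJoints), dimnames = list(NULL, allJoints))
  full[, colnames(A)] <- A

  flex <- full[, handJoints(), drop = FALSE]
  if (any(flex < 0) || any(flex >= 180))
    stop("flexion angles must lie in [0, 180) degrees")
  abd <- full[, "thumb_abduction"]
  if (any(abs(abd) >= 90))
    stop("thumb abduction must lie in (-90, 90) degrees")
  if (length(wristOrigin) != 3 || !is.numeric(wristOrigin))
    stop("'wristOrigin' must be a numeric 3-vector")

  landmarks <- c("wrist", unlist(lapply(intersect(.FINGERS, fingers),
                                        function(f) paste(f, .chainSuffixes(f),
                                                          sep = "_"))))
  cols <- paste0(rep(landmarks, each = 3),
                 rep(c("_x_mm", "_y_mm", "_z_mm"), length(landmarks)))
  P <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  put <- function(lm, xyz) P[, .lmCols(lm)] <<- xyz
  W <- matrix(rep(as.numeric(wristOrigin), each = n), n, 3)
  put("wrist", W)

  lens <- segmentLengthsOf(geometry)
  for (f in intersect(.FINGERS, fingers)) {
    az <- .AZIMUTH_DEG[[f]] * .DEG
    if (f == "thumb") {
      azv <- az + abd * .DEG   # per-frame azimuth after abduction
      u <- cbind(sin(azv), 0, cos(azv))
      phi1 <- flex[, "thumb_cmc"] * .DEG
      phi2 <- phi1 + flex[, "thumb_mcp"] * .DEG
      phi3 <- phi2 + flex[, "thumb_ip"] * .DEG
      dirAt <- function(phi) cbind(sin(azv) * cos(phi), sin(phi), cos(azv) * cos(phi))
      cmc <- W + .BASE_OFFSET_MM[["thumb"]] * u
      mcp <- cmc + lens$thumb[["metacarpal"]] * dirAt(phi1)
      ip  <- mcp + lens$thumb[["proximal"]] * dirAt(phi2)
      tip <- ip + lens$thumb[["distal"]] * dirAt(phi3)
      put("thumb_cmc", cmc); put("thumb_mcp", mcp)
      put("thumb_ip", ip); put("thumb_tip", tip)
    } else {
      u <- c(sin(az), 0, cos(az))
      phi1 <- flex[, paste0(f, "_mcp")] * .DEG
      phi2 <- phi1 + flex[, paste0(f, "_pip")] * .DEG
      phi3 <- phi2 + flex[, paste0(f, "_dip")] * .DEG
      dirAt <- function(phi) cbind(sin(az) * cos(phi), sin(phi), cos(az) * cos(phi))
      base <- W + matrix(rep(.BASE_OFFSET_MM[[f]] * u, each = n), n, 3)
      mcp <- base + matrix(rep(lens[[f]][["metacarpal"]] * u, each = n), n, 3)
      pip <- mcp + lens[[f]][["proximal"]] * dirAt(phi1)
      dip <- pip + lens[[f]][["intermediate"]] * dirAt(phi2)
      tip <- dip + lens[[f]][["distal"]] * dirAt(phi3)
      put(paste0(f, "_base"), base); put(paste0(f, "_mcp"), mcp)
      put(paste0(f, "_pip"), pip); put(paste0(f, "_dip"), dip)
      put(paste0(f, "_tip"), tip)
    }
  }

  if (single) {
    matrix(P[1, ], nrow = length(landmarks), ncol = 3, byrow = TRUE,
           dimnames = list(landmarks, c("x_mm", "y_mm", "z_mm")))
  } else {
    P
  }
}

#' Recover the thumb abduction angle from landmark positions
#'
#' The abduction degree of freedom is a rotation of the thumb chain within the
#' palm (X-Z) plane, so it is recovered as the azimuth of the wrist-to-CMC
#' direction relative to the resting thumb azimuth. Unlike the three-point
#' flexion angles this is only meaningful in the device coordinate frame.
#'
#' @param positions A single-pose landmark matrix as returned by
#'   \code{\link{forwardPose}} (25 x 3, rows named by landmark).
#' @return Signed abduction angle in degrees.
#' @export
thumbAbductionAngle <- function(positions) {
  v <- positions["thumb_cmc", ] - positions["wrist", ]
  az <- atan2(v[[1]], v[[3]]) / .DEG
  unname(az - .AZIMUTH_DEG[["thumb"]])
}
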