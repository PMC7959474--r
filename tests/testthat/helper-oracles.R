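# Independent oracles and small fixtures used across the test files.

# Independent three-point angle: atan2 of the cross-product magnitude and the
# dot product -- a different numerical route than the package's clamped
# arccos of the normalised dot product.
oracleAngleDeg <- function(a, b, c) {
  u <- b - a
  v <- c - b
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

# Independent Bland-Altman from explicit sums (textbook formulas), not
# reusing mean()/sd()/cor().
oracleBlandAltman <- function(ref, tst) {
  n <- length(ref)
  d <- ref - tst
  m <- (ref + tst) / 2
  bias <- sum(d) / n
  sdd <- sqrt((sum(d^2) - n * bias^2) / (n - 1))
  loa <- c(bias - 1.96 * sdd, bias + 1.96 * sdd)
  ci <- bias + c(-1, 1) * qt(0.975, n - 1) * sdd / sqrt(n)
  sxy <- sum(m * d) - sum(m) * sum(d) / n
  sxx <- sum(m^2) - sum(m)^2 / n
  syy <- sum(d^2) - sum(d)^2 / n
  r <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NaN
  p <- if (is.finite(r) && abs(r) < 1 && n >= 3) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  } else NaN
  list(n = n, bias = bias, sd = sdd, loa = loa, ci = ci, r = r, p = p)
}

# small hand geometry with easy numbers (index segments 40/25/20 as in the
# straight-finger identity checks)
toyGeometry <- function() {
  handGeometry(list(
    thumb = c(metacarpal = 40, proximal = 30, distal = 20),
    index = c(metacarpal = 60, proximal = 40, intermediate = 25, distal = 20),
    middle = c(metacarpal = 60, proximal = 45, intermediate = 28, distal = 18),
    ring = c(metacarpal = 55, proximal = 42, intermediate = 26, distal = 17),
    pinky = c(metacarpal = 50, proximal = 35, intermediate = 20, distal = 16)))
}

# a random valid joint-angle set
randomAngleSet <- function() {
  joints <- handJoints()
  a <- setNames(runif(length(joints), 1, 110), joints)
  c(a, thumb_abduction = runif(1, -35, 35))
}

# random 3D rotation matrix via QR
randomRotation <- function() {
  qr <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# recompute all flexion angles from a single-pose landmark matrix
poseAngles <- function(pose, joints = handJoints()) {
  triples <- handkin:::.jointTriples()
  triples <- triples[triples$joint %in% joints, ]
  out <- setNames(numeric(nrow(triples)), triples$joint)
  for (i in seq_len(nrow(triples))) {
    out[i] <- jointAngle(pose[triples$a[i], ], pose[triples$b[i], ],
                         pose[triples$c[i], ])
  }
  out
}
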