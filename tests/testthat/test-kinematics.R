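test_that("three-point angles handle collinear and orthogonal cases", {
  expect_equal(jointAngle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), 0)
  expect_equal(jointAngle(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)), 90)
  expect_error(jointAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 1)),
               "degenerate")
})

test_that("three-point angles match an independent oracle on 1000 random triples", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    a <- rnorm(3, sd = 50); b <- rnorm(3, sd = 50); c <- rnorm(3, sd = 50)
    worst <- max(worst, abs(jointAngle(a, b, c) - oracleAngleDeg(a, b, c)))
  }
  expect_lt(worst, 1e-9)
})

test_that("three-point angles are invariant under rotation, translation and scaling", {
  set.seed(21)
  for (i in 1:25) {
    a <- rnorm(3, sd = 40); b <- rnorm(3, sd = 40); c <- rnorm(3, sd = 40)
    base <- jointAngle(a, b, c)
    R <- randomRotation(); shift <- rnorm(3, sd = 100); s <- runif(1, 0.1, 8)
    tf <- function(p) s * as.vector(R %*% p) + shift
    expect_equal(jointAngle(tf(a), tf(b), tf(c)), base, tolerance = 1e-8)
  }
})

test_that("angle trajectories recover a constant pose and simulator truth", {
  g <- toyGeometry()
  n <- 30
  A <- matrix(0, n, 1, dimnames = list(NULL, "index_pip"))
  A[, 1] <- 30
  P <- forwardPose(g, A)
  rec <- recording(seq_len(n) / 150, P, list())
  tr <- angleTrajectories(rec, "index_pip")$index_pip
  expect_equal(tr@angles, rep(30, n), tolerance = 1e-9)

  truth <- generateTruth(defaultTaskProfiles()$middle_flexion)
  rec2 <- renderStream(truth, g, sensorModel(150, label = "ref"), seed = 2)
  trajs <- angleTrajectories(rec2)
  truthA <- truthAngles(truth, rec2@times)
  for (j in c("middle_mcp", "middle_pip", "middle_dip"))
    expect_lt(max(abs(trajs[[j]]@angles - truthA[, j])), 1e-9)
})

test_that("frames with missing landmarks are skipped with a warning", {
  g <- toyGeometry()
  truth <- generateTruth(defaultTaskProfiles()$index_flexion)
  rec <- renderStream(truth, g, sensorModel(150, label = "ref"), seed = 2)
  P <- rec@positions
  P[5, handkin:::.lmCols("index_pip")] <- NA
  rec2 <- recording(rec@times, P, rec@metadata)
  expect_warning(tr <- angleTrajectories(rec2, "index_pip"), "skipped")
  expect_equal(length(tr$index_pip@angles), nFrames(rec) - 1)
})

test_that("segment lengths reproduce the 3-4-5 triangle and the geometry", {
  p1 <- c(0, 0, 0); p2 <- c(3, 4, 0)
  expect_equal(sqrt(sum((p2 - p1)^2)), 5)
  g <- toyGeometry()
  truth <- generateTruth(staticTaskProfile())
  rec <- renderStream(truth, g, sensorModel(150, label = "ref"), seed = 4)
  segs <- segmentLengths(rec)
  lens <- segmentLengthsOf(g)
  for (i in seq_len(nrow(segs)))
    expect_equal(segs$mean_mm[i], lens[[segs$finger[i]]][[segs$segment[i]]],
                 tolerance = 1e-10)
  expect_true(all(segs$sd_mm < 1e-10))
  expect_false(any(segs$degenerate))
  # reference reporting rule: no non-thumb metacarpals
  segsRef <- segmentLengths(rec, dropReferenceMetacarpals = TRUE)
  expect_false(any(segsRef$segment == "metacarpal" & segsRef$finger != "thumb"))
  expect_true(any(segsRef$segment == "metacarpal" & segsRef$finger == "thumb"))
})

test_that("noisy static trials recover the configured geometry within sampling error", {
  g <- toyGeometry()
  truth <- generateTruth(staticTaskProfile(duration = 4))
  rec <- renderStream(truth, g, sensorModel(150, 0, 0.5, label = "tst"),
                      seed = 6)
  segs <- segmentLengths(rec)
  lens <- segmentLengthsOf(g)
  for (i in seq_len(nrow(segs))) {
    tol <- 3 * segs$sd_mm[i] / sqrt(segs$n[i]) + 0.02
    expect_lt(abs(segs$mean_mm[i] - lens[[segs$finger[i]]][[segs$segment[i]]]),
              tol + 0.05)
  }
})

test_that("ROM is max minus min and speed-invariant", {
  expect_equal(rom(rep(12, 5))$rom, 0)
  tr <- angleTrajectory("index_mcp", c(0, 0.5, 1), c(9.62, 78.01, 9.62))
  expect_equal(rom(tr)$rom, 68.39, tolerance = 1e-12)
  # raised-cosine truth attains amplitude - rest
  tp <- taskProfile("index_flexion", amplitude = c(index_pip = 80),
                    restAngle = c(index_pip = 5))
  truth <- generateTruth(tp, dt = 1 / 1200)
  expect_equal(rom(truth@angles[, "index_pip"])$rom, 75, tolerance = 1e-6)
  # reparameterising time leaves ROM unchanged
  warped <- angleTrajectory("index_pip", (truth@times / 6)^2 + 0:(length(truth@times) - 1) * 1e-9,
                            truth@angles[, "index_pip"])
  expect_equal(rom(warped)$rom, rom(truth@angles[, "index_pip"])$rom)
  expect_error(rom(numeric(0)), "empty")
})

test_that("ROM differences follow the reference-minus-test convention", {
  expect_equal(romDifference(72.15, 43.86), 28.29, tolerance = 1e-12)
  expect_equal(romDifference(42.44, 54.10), -11.66, tolerance = 1e-12)
  expect_equal(romDifference(30, 30), 0)
  expect_error(romDifference(-1, 5), "non-negative")
})
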