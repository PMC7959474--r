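test_that("a straight finger is a collinear chain with the configured segment lengths", {
  g <- toyGeometry()
  pose <- forwardPose(g, setNames(numeric(0), character(0)))
  M <- pose["index_mcp", ]; P <- pose["index_pip", ]
  D <- pose["index_dip", ]; T <- pose["index_tip", ]
  expect_equal(sqrt(sum((P - M)^2)), 40, tolerance = 1e-12)
  expect_equal(sqrt(sum((D - P)^2)), 25, tolerance = 1e-12)
  expect_equal(sqrt(sum((T - D)^2)), 20, tolerance = 1e-12)
  # collinear: every recomputed flexion angle is 0 (to the acos precision
  # floor near a unit dot product, ~1e-6 degrees)
  expect_lt(max(abs(poseAngles(pose))), 1e-5)
  # and the chain is geometrically collinear: cross products vanish
  u <- P - M; v <- D - P
  expect_lt(max(abs(c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                      u[1] * v[2] - u[2] * v[1]))), 1e-9)
})

test_that("a 90-degree PIP flexion is recovered exactly from the pose", {
  pose <- forwardPose(toyGeometry(), c(index_pip = 90))
  ang <- jointAngle(pose["index_mcp", ], pose["index_pip", ],
                    pose["index_dip", ])
  expect_equal(ang, 90, tolerance = 1e-9)
  others <- poseAngles(pose, setdiff(handJoints(), "index_pip"))
  expect_lt(max(abs(others)), 1e-5)
})

test_that("forward pose and angle recovery round-trip to < 1e-9 degrees", {
  g <- toyGeometry()
  set.seed(7)
  for (rep in 1:20) {
    a <- randomAngleSet()
    pose <- forwardPose(g, a)
    rec <- poseAngles(pose)
    expect_lt(max(abs(rec - a[names(rec)])), 1e-9)
    expect_equal(thumbAbductionAngle(pose), a[["thumb_abduction"]],
                 tolerance = 1e-9)
  }
})

test_that("segment lengths are conserved in every pose", {
  g <- toyGeometry()
  set.seed(11)
  pairs <- handkin:::.segmentPairs()
  lens <- segmentLengthsOf(g)
  for (rep in 1:10) {
    pose <- forwardPose(g, randomAngleSet())
    for (i in seq_len(nrow(pairs))) {
      d <- sqrt(sum((pose[pairs$to[i], ] - pose[pairs$from[i], ])^2))
      expect_equal(d, lens[[pairs$finger[i]]][[pairs$segment[i]]],
                   tolerance = 1e-10)
    }
  }
})

test_that("recomputed flexion angles are invariant under rigid motion", {
  g <- toyGeometry()
  set.seed(13)
  a <- randomAngleSet()
  pose <- forwardPose(g, a)
  R <- randomRotation()
  shift <- c(100, -50, 30)
  moved <- sweep(pose %*% t(R), 2, -shift)
  dimnames(moved) <- dimnames(pose)
  expect_equal(poseAngles(moved), poseAngles(pose), tolerance = 1e-9)
})

test_that("invalid angles and geometries are rejected", {
  g <- toyGeometry()
  expect_error(forwardPose(g, c(index_mcp = -5)), "flexion")
  expect_error(forwardPose(g, c(index_mcp = 180)), "flexion")
  expect_error(forwardPose(g, c(thumb_abduction = 95)), "abduction")
  expect_error(forwardPose(g, c(elbow = 10)), "unknown joint")
  badLens <- segmentLengthsOf(g)
  badLens$index[["proximal"]] <- -1
  expect_error(handGeometry(badLens), "non-positive")
  badLens2 <- segmentLengthsOf(g)
  badLens2$thumb <- c(metacarpal = 40, proximal = 30, intermediate = 10,
                      distal = 20)
  expect_error(handGeometry(badLens2), "thumb")
})

test_that("the landmark topology has the expected chain structure", {
  lm <- handLandmarks()
  expect_length(lm, 25)
  expect_identical(lm[1], "wrist")
  expect_false(any(duplicated(lm)))
  # thumb has one joint fewer than the other fingers
  expect_length(grep("^thumb_", lm), 4)
  for (f in c("index", "middle", "ring", "pinky"))
    expect_length(grep(paste0("^", f, "_"), lm), 5)
  expect_length(handJoints(), 15)
})

test_that("geometry JSON round-trips", {
  g <- toyGeometry()
  path <- withr::local_tempfile(fileext = ".json")
  writeHandGeometry(g, path)
  g2 <- readHandGeometry(path)
  expect_equal(segmentLengthsOf(g2), segmentLengthsOf(g), tolerance = 1e-12)
})

test_that("subject geometry draws stay positive and track the norms", {
  set.seed(5)
  draws <- replicate(200, segmentLengthsOf(drawHandGeometry())$index[["proximal"]])
  expect_true(all(draws > 0))
  norms <- segmentLengthNorms()
  expect_equal(mean(draws), norms$index$mean[["proximal"]],
               tolerance = 0.15)
})
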