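test_that("raised-cosine truth attains its extrema and cycle count by construction", {
  tp <- taskProfile("index_flexion",
                    amplitude = c(index_pip = 80),
                    restAngle = c(index_pip = 5),
                    nCycles = 3, cycleDuration = 2)
  tr <- generateTruth(tp, dt = 1 / 300)
  a <- tr@angles[, "index_pip"]
  expect_equal(max(a), 80, tolerance = 1e-9)
  expect_equal(min(a), 5, tolerance = 1e-9)
  expect_equal(a[1], 5, tolerance = 1e-9)
  expect_equal(a[length(a)], 5, tolerance = 1e-9)
  # exactly 3 interior local maxima
  peaks <- which(diff(sign(diff(a))) == -2)
  expect_length(peaks, 3)
  # maxima at odd multiples of half the cycle duration
  expect_equal(tr@times[peaks + 1], c(1, 3, 5), tolerance = 1 / 300)
})

test_that("a task with amplitude equal to rest is constant with zero ROM", {
  tp <- taskProfile("index_flexion",
                    amplitude = c(index_mcp = 15),
                    restAngle = c(index_mcp = 15))
  tr <- generateTruth(tp)
  expect_equal(diff(range(tr@angles[, "index_mcp"])), 0)
  expect_equal(rom(tr@angles[, "index_mcp"])$rom, 0)
})

test_that("a noiseless constant-rate stream reproduces the truth exactly", {
  g <- toyGeometry()
  tp <- defaultTaskProfiles()$index_flexion
  tr <- generateTruth(tp)
  sensor <- sensorModel(150, 0, 0, numeric(0), 0, "ref")
  rec <- renderStream(tr, g, sensor, seed = 1)
  expect_equal(diff(rec@times), rep(1 / 150, nFrames(rec) - 1),
               tolerance = 1e-12)
  trajs <- angleTrajectories(rec, c("index_mcp", "index_pip", "index_dip"))
  truthA <- truthAngles(tr, rec@times)
  for (j in names(trajs))
    expect_lt(max(abs(trajs[[j]]@angles - truthA[, j])), 1e-9)
})

test_that("an additive angular bias shifts only the biased joint", {
  g <- toyGeometry()
  tr <- generateTruth(defaultTaskProfiles()$index_flexion)
  sensor <- sensorModel(150, 0, 0, c(index_pip = 10), 0, "tst")
  rec <- renderStream(tr, g, sensor, seed = 1)
  trajs <- angleTrajectories(rec, c("index_mcp", "index_pip", "index_dip"))
  truthA <- truthAngles(tr, rec@times)
  expect_lt(max(abs(trajs$index_pip@angles - (truthA[, "index_pip"] + 10))),
            1e-9)
  expect_lt(max(abs(trajs$index_mcp@angles - truthA[, "index_mcp"])), 1e-9)
  expect_lt(max(abs(trajs$index_dip@angles - truthA[, "index_dip"])), 1e-9)
})

test_that("jittered intervals keep the requested mean frame rate", {
  g <- toyGeometry()
  tp <- taskProfile("index_flexion", amplitude = c(index_pip = 60),
                    restAngle = c(index_pip = 5), nCycles = 5,
                    cycleDuration = 2)
  sensor <- sensorModel(120, intervalJitterCV = 0.2, label = "tst")
  rates <- vapply(1:100, function(k) {
    rec <- renderStream(generateTruth(tp, dt = 1 / 120), g, sensor,
                        seed = 42 + k, fingers = "index")
    (nFrames(rec) - 1) / diff(range(rec@times))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 120) / 120, 0.05)
  # and the interval CV is near the requested one on average
  rec <- renderStream(generateTruth(tp, dt = 1 / 120), g, sensor, seed = 42,
                      fingers = "index")
  iv <- diff(rec@times)
  expect_equal(sd(iv) / mean(iv), 0.2, tolerance = 0.05)
})

test_that("dropout and jitter never reorder frames and keep the trial span", {
  g <- toyGeometry()
  tr <- generateTruth(defaultTaskProfiles()$index_flexion)
  sensor <- sensorModel(120, 0.3, 0.5, numeric(0), dropoutProb = 0.1,
                        label = "tst")
  for (k in 1:10) {
    rec <- renderStream(tr, g, sensor, seed = k, fingers = "index")
    expect_true(all(diff(rec@times) > 0))
    expect_equal(rec@times[1], 0)
    expect_lt(tr@duration - max(rec@times), 1 / 120 + 1e-9)
  }
})

test_that("the default study has the protocol shape and is seed-deterministic", {
  b1 <- generateStudy(nSubjects = 2, trialsPerSubject = 2, baseSeed = 9)
  types <- vapply(b1, function(b) b@metadata$type, character(1))
  expect_equal(sum(types == "dynamic"), 2 * 2 * 6)
  expect_equal(sum(types == "static"), 2)
  b2 <- generateStudy(nSubjects = 2, trialsPerSubject = 2, baseSeed = 9)
  expect_identical(b1[[1]]@test@positions, b2[[1]]@test@positions)
  expect_identical(b1[[20]]@reference@times, b2[[20]]@reference@times)
  b3 <- generateStudy(nSubjects = 2, trialsPerSubject = 2, baseSeed = 10)
  expect_false(identical(b1[[1]]@test@positions, b3[[1]]@test@positions))
})

test_that("a minimal study yields a single bundle with consistent spans", {
  b <- generateStudy(nSubjects = 1, trialsPerSubject = 1,
                     profiles = defaultTaskProfiles()["index_flexion"],
                     baseSeed = 3, includeStatic = FALSE)
  expect_length(b, 1)
  ref <- b[[1]]@reference; tst <- b[[1]]@test
  expect_lt(abs(max(ref@times) - max(tst@times)),
            1 / min(120, 150) + 1e-9)
  expect_equal(min(ref@times), 0)
  expect_equal(min(tst@times), 0)
})

test_that("study generation rejects degenerate shapes", {
  expect_error(generateStudy(nSubjects = 0), "nSubjects")
  expect_error(generateStudy(trialsPerSubject = 0), "trialsPerSubject")
  expect_error(generateTruth(defaultTaskProfiles()$index_flexion, dt = 0),
               "dt")
})
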