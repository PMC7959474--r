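test_that("timeline reconstruction is the cumulative sum of intervals", {
  tl <- buildTimeVector(c(0, 1 / 150, 2 / 150, 3 / 150))
  expect_equal(tl@rebuiltTimes, c(0, 1, 2, 3) / 150, tolerance = 1e-15)
  tl2 <- buildTimeVector(c(0.5, 0.51, 0.53, 0.54))
  expect_equal(tl2@rebuiltTimes, c(0, 0.01, 0.03, 0.04), tolerance = 1e-12)
  expect_identical(tl2@source, "timestamps")
  # from instantaneous rates instead of timestamps
  tl3 <- buildTimeVector(rates = c(100, 50, 100))
  expect_equal(tl3@rebuiltTimes, c(0, 0.01, 0.03, 0.04), tolerance = 1e-12)
  expect_identical(tl3@source, "rates")
})

test_that("rebuilt duration telescopes to last minus first timestamp", {
  set.seed(42)
  raw <- 3.7 + cumsum(rgamma(400, shape = 25, scale = (1 / 120) / 25))
  tl <- buildTimeVector(raw)
  expect_lt(abs(max(tl@rebuiltTimes) - (max(raw) - min(raw))), 1e-12)
})

test_that("timeline errors name the offending input", {
  expect_error(buildTimeVector(c(0)), "insufficient")
  expect_error(buildTimeVector(c(0, 0.01, 0.01, 0.02)),
               "non-increasing timestamps at index 3")
  expect_error(buildTimeVector(), "supply either")
  expect_warning(buildTimeVector(c(0, 0.01, 0.2, 0.21), nominalRate = 100),
                 "gap")
})

test_that("identity resampling reproduces a uniform recording", {
  g <- toyGeometry()
  tr <- generateTruth(defaultTaskProfiles()$index_flexion)
  rec <- renderStream(tr, g, sensorModel(150, label = "ref"), seed = 1)
  res <- resampleUniform(rec, 150)
  expect_equal(nFrames(res), nFrames(rec))
  expect_lt(max(abs(res@positions - rec@positions)), 1e-12)
  expect_equal(res@metadata$resampled_hz, 150)
})

test_that("linear signals are resampled exactly from irregular sampling", {
  set.seed(8)
  times <- sort(runif(40, 0, 2))
  times <- c(0, times, 2)
  P <- matrix(rep(times * 10, 3), ncol = 3)   # x(t) = 10 t mm on each axis
  colnames(P) <- handkin:::.lmCols("wrist")
  rec <- recording(times, P, list())
  res <- resampleUniform(rec, 150)
  expect_lt(max(abs(res@positions[, 1] - res@times * 10)), 1e-10)
})

test_that("a jittered sinusoid resampled to 150 Hz stays within RMSE 0.1", {
  set.seed(42)
  mu <- 1 / 60
  iv <- rgamma(200, shape = 25, scale = mu / 25)   # CV 0.2, mean rate 60 Hz
  times <- cumsum(c(0, iv))
  sig <- 45 * sin(2 * pi * times)
  P <- matrix(rep(sig, 3), ncol = 3)
  colnames(P) <- handkin:::.lmCols("wrist")
  rec <- recording(times, P, list())
  res <- resampleUniform(rec, 150)
  truth <- 45 * sin(2 * pi * res@times)
  rmse <- sqrt(mean((res@positions[, 1] - truth)^2))
  expect_lt(rmse, 0.1)
})

test_that("time normalisation preserves endpoints and constants", {
  tr <- angleTrajectory("index_pip", c(0, 0.4, 1.1, 2.0), c(5, 40, 80, 12))
  n2 <- timeNormalize(tr, nPoints = 2)
  expect_equal(n2@angles, c(5, 12))
  expect_equal(n2@times, c(0, 100))
  const <- angleTrajectory("index_pip", 0:10, rep(33, 11))
  expect_equal(timeNormalize(const)@angles, rep(33, 101))
  expect_error(timeNormalize(tr, nPoints = 1), "nPoints")
})

test_that("time normalisation is speed-invariant and idempotent", {
  tp <- defaultTaskProfiles()$index_flexion
  slow <- generateTruth(tp, dt = 1 / 600, speed = 1.5)
  fast <- generateTruth(tp, dt = 1 / 600, speed = 0.7)
  tS <- angleTrajectory("index_pip", slow@times, slow@angles[, "index_pip"])
  tF <- angleTrajectory("index_pip", fast@times, fast@angles[, "index_pip"])
  nS <- timeNormalize(tS); nF <- timeNormalize(tF)
  expect_lt(sqrt(mean((nS@angles - nF@angles)^2)), 0.1)
  again <- timeNormalize(nS, 101)
  expect_equal(again@angles, nS@angles, tolerance = 1e-9)
  expect_identical(nS@timeUnit, "percent")
})

test_that("low-pass smoothing removes noise without biasing a slow signal", {
  set.seed(3)
  fs <- 150
  times <- seq(0, 2, by = 1 / fs)
  clean <- 50 + 40 * sin(2 * pi * 0.8 * times)
  noisy <- clean + rnorm(length(times), 0, 1)
  P <- matrix(rep(noisy, 3), ncol = 3)
  colnames(P) <- handkin:::.lmCols("wrist")
  rec <- recording(times, P, list())
  sm <- smoothRecording(rec, cutoffHz = 10)
  resid <- sm@positions[, 1] - clean
  expect_lt(sd(resid), 0.5)            # noise attenuated
  expect_lt(abs(mean(resid)), 0.1)     # no systematic shift
  expect_error(smoothRecording(rec, cutoffHz = 100), "Nyquist")
})
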