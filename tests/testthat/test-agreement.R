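test_that("perfect agreement gives zero bias, zero-width limits and undefined r", {
  ba <- blandAltman(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(ba@bias, 0)
  expect_equal(ba@loa[2] - ba@loa[1], 0)
  expect_false(ba@rDefined)
  expect_true(is.nan(ba@r))
  out <- trendInterpretation(ba)
  expect_equal(as.character(out), "no_trend")
  expect_true(attr(out, "undefined"))
})

test_that("all Bland-Altman fields match the formula oracle on a worked pair set", {
  ref <- c(10, 20, 30, 40, 50)
  tst <- c(12, 19, 33, 36, 55)
  ba <- blandAltman(ref, tst)
  o <- oracleBlandAltman(ref, tst)
  expect_equal(ba@bias, o$bias, tolerance = 1e-12)
  expect_equal(ba@sdDiff, o$sd, tolerance = 1e-12)
  expect_equal(ba@loa, o$loa, tolerance = 1e-12)
  expect_equal(ba@ciBias, o$ci, tolerance = 1e-12)
  expect_equal(ba@r, o$r, tolerance = 1e-12)
  expect_equal(ba@p, o$p, tolerance = 1e-12)
})

test_that("Bland-Altman matches the oracle on random paired sets of many sizes", {
  set.seed(17)
  worst <- 0
  for (k in 1:120) {
    n <- sample(3:50, 1)
    ref <- runif(n, 0, 120)
    tst <- ref + rnorm(n, sample(c(-10, 0, 10), 1), runif(1, 0.5, 8))
    ba <- blandAltman(ref, tst)
    o <- oracleBlandAltman(ref, tst)
    worst <- max(worst,
                 abs(ba@bias - o$bias), abs(ba@sdDiff - o$sd),
                 max(abs(ba@loa - o$loa)), max(abs(ba@ciBias - o$ci)),
                 abs(ba@r - o$r), abs(ba@p - o$p))
  }
  expect_lt(worst, 1e-10)
})

test_that("pair order does not matter and swapping systems mirrors the result", {
  set.seed(23)
  ref <- runif(20, 20, 100)
  tst <- ref + rnorm(20, 3, 4)
  ba <- blandAltman(ref, tst)
  perm <- sample(20)
  ba2 <- blandAltman(ref[perm], tst[perm])
  expect_equal(ba2@bias, ba@bias, tolerance = 1e-12)
  expect_equal(ba2@loa, ba@loa, tolerance = 1e-12)
  expect_equal(ba2@r, ba@r, tolerance = 1e-12)
  swapped <- blandAltman(tst, ref)
  expect_equal(swapped@bias, -ba@bias, tolerance = 1e-12)
  expect_equal(swapped@loa, -rev(ba@loa), tolerance = 1e-12)
  expect_equal(swapped@r, -ba@r, tolerance = 1e-12)
  expect_equal(swapped@p, ba@p, tolerance = 1e-12)
  # explicit sign convention flag does the same
  conv <- blandAltman(ref, tst, signConvention = "test_minus_reference")
  expect_equal(conv@bias, -ba@bias, tolerance = 1e-12)
})

test_that("trend interpretation uses a strict alpha threshold", {
  set.seed(31)
  m <- runif(18, 10, 100)
  d <- 0.3 * m + rnorm(18, 0, 2)       # strong proportional bias
  ba <- blandAltman(m + d / 2, m - d / 2)
  expect_equal(trendInterpretation(ba), "proportional_bias")
  dFlat <- rnorm(18, 5, 2)             # no trend
  baFlat <- blandAltman(m + dFlat / 2, m - dFlat / 2)
  expect_equal(as.character(trendInterpretation(baFlat)), "no_trend")
  # p exactly equal to alpha is not a trend
  expect_equal(as.character(trendInterpretation(ba, alpha = ba@p)),
               "no_trend")
  expect_equal(trendInterpretation(ba, alpha = ba@p * 1.0001),
               "proportional_bias")
})

test_that("small or degenerate pair sets are handled as specified", {
  ba2 <- blandAltman(c(10, 20), c(11, 19))
  expect_false(ba2@rDefined)
  expect_equal(ba2@bias, 0)
  # constant non-zero differences: bias defined, r undefined
  baC <- blandAltman(c(10, 20, 30), c(5, 15, 25))
  expect_equal(baC@bias, 5)
  expect_false(baC@rDefined)
  expect_error(blandAltman(1, numeric(0)), "same length")
  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("segment-length summaries pool per-subject means with the metacarpal rule", {
  recs <- expand.grid(subject = c("S01", "S02"),
                      system = c("reference", "test"),
                      finger = c("thumb", "index"),
                      segment = c("metacarpal", "proximal"),
                      stringsAsFactors = FALSE)
  recs$mean_mm <- c(1:nrow(recs)) + 30
  out <- summarizeSegmentLengths(recs)
  expect_true(all(is.na(out$reference_mean_mm[out$finger == "index" &
                                                out$segment == "metacarpal"])))
  expect_false(any(is.na(out$test_mean_mm)))
  thumbProx <- out[out$finger == "thumb" & out$segment == "proximal", ]
  sub <- recs[recs$finger == "thumb" & recs$segment == "proximal" &
                recs$system == "reference", ]
  expect_equal(thumbProx$reference_mean_mm, mean(sub$mean_mm))
  expect_equal(thumbProx$reference_sd_mm, sd(sub$mean_mm))
  # a single subject reports sd 0; identical subjects give sd exactly 0
  one <- recs[recs$subject == "S01", ]
  outOne <- summarizeSegmentLengths(one)
  expect_true(all(outOne$test_sd_mm == 0))
  two <- rbind(one, transform(one, subject = "S03"))
  outTwo <- summarizeSegmentLengths(two)
  expect_true(all(outTwo$test_sd_mm == 0))
})

test_that("the ROM table difference column is exactly reference minus test", {
  recs <- data.frame(
    system = rep(c("reference", "test"), each = 2),
    task = "middle_flexion",
    joint = rep(c("middle_pip", "middle_dip"), 2),
    rom = c(105.10, 21.38, 43.59, 33.80))
  out <- romTable(recs)
  expect_equal(out$difference[out$joint == "middle_pip"], 61.51,
               tolerance = 1e-12)
  expect_equal(out$difference[out$joint == "middle_dip"], -12.42,
               tolerance = 1e-12)
  same <- recs; same$rom[3:4] <- same$rom[1:2]
  expect_true(all(romTable(same)$difference == 0))
  # unmatched joints are dropped with a warning
  recs2 <- recs[-4, ]
  expect_warning(out2 <- romTable(recs2), "omitted")
  expect_false("middle_dip" %in% out2$joint)
})

test_that("the bundled example table is consistent with romDifference", {
  tab <- exampleRomTable()
  expect_equal(nrow(tab), 18)
  expect_equal(romDifference(tab$rom_qtm, tab$rom_lmc), tab$qtm_minus_lmc,
               tolerance = 5e-3)
})
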