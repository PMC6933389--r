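test_that("aligned averaging shifts frame indices correctly", {
  # integer-valued movies: frame f has constant value f
  m1 <- Movie(array(rep(1:30, each = 16), c(4, 4, 30)), frameRateHz = 10)
  m2 <- Movie(array(rep(101:130, each = 16), c(4, 4, 30)), frameRateHz = 10)
  out <- averageAlignedTrials(list(bareTrial(m1, 15), bareTrial(m2, 25)))
  expect_identical(nFrames(out$movie), 20L)      # 30 - shift of 10
  expect_identical(out$anchorFrame, 15L)
  # output frame k = mean(m1[k], m2[k + 10])
  vals <- movieData(out$movie)[1, 1, ]
  expect_equal(vals, ((1:20) + (111:130)) / 2)
})

test_that("averaging one trial or identical trials is the identity", {
  m <- Movie(array(rnorm(4 * 4 * 20), c(4, 4, 20)), frameRateHz = 10)
  one <- averageAlignedTrials(list(bareTrial(m, 5)))
  expect_identical(movieData(one$movie), movieData(m))
  four <- averageAlignedTrials(replicate(4, bareTrial(m, 5)))
  expect_equal(movieData(four$movie), movieData(m))
  expect_error(averageAlignedTrials(list()), "empty")
  expect_error(
    averageAlignedTrials(list(bareTrial(m, NA_integer_))), "anchorFrame")
})

test_that("dF/F0 windows have the exact frame counts at 125 Hz", {
  a <- array(100, c(4, 4, 1000))
  mp <- computeActivityMap(Movie(a), anchorFrame = 600)
  expect_identical(mp@responseFrames, 200L)
  expect_identical(mp@baselineFrames, 125L)
  expect_equal(mapValues(mp), matrix(0, 4, 4))  # constant movie: zero map
})

test_that("dF/F0 is (R - B) / B on the configured windows", {
  a <- array(100, c(4, 4, 1000))
  anchor <- 600L
  a[2, 3, (anchor + 1):(anchor + 200)] <- 105  # response window only
  mp <- computeActivityMap(Movie(a), anchor)
  expect_equal(mapValues(mp)[2, 3], 0.05)
  expect_equal(sum(mapValues(mp) != 0), 1L)
})

test_that("window overruns raise errors naming the bounds", {
  a <- array(100, c(4, 4, 700))
  expect_error(computeActivityMap(Movie(a), 100), "baseline window")
  expect_error(computeActivityMap(Movie(a), 600), "response window")
})

test_that("dF/F0 is invariant to positive rescaling of the movie", {
  set.seed(6)
  a <- array(100 + rnorm(4 * 4 * 1000, 0, 5), c(4, 4, 1000))
  m1 <- computeActivityMap(Movie(a), 600)
  m2 <- computeActivityMap(Movie(a * 3.7), 600)
  expect_equal(mapValues(m1), mapValues(m2), tolerance = 1e-12)
})

test_that("near-zero baselines are floored, zeroed and flagged", {
  a <- array(100, c(4, 4, 1000))
  a[1, 1, ] <- 1e-4  # far below 1% of the global median
  mp <- computeActivityMap(Movie(a), 600)
  expect_true(mp@flagged[1, 1])
  expect_equal(mapValues(mp)[1, 1], 0)
})

test_that("ROI summaries report mean dF/F0 per glomerulus", {
  vals <- matrix(0, 32, 32)
  vals[12, 16] <- 0.42
  mp <- bareMap(vals)
  one <- new("GlomerulusSet",
             rois = data.frame(id = 1L, x = 15, y = 11, peak = 0.42),
             masks = list((16L - 1L) * 32L + 12L),
             amplitudes = matrix(0.42, 1, 1), view = "dorsal",
             frameDim = c(32L, 32L))
  expect_equal(mapSummary(mp, one)$mean_dff, 0.42)  # single-pixel ROI

  # a synthetic blob is recovered up to edge dilution of the disk ROI
  map <- oneBlobMap(x = 16, y = 12, amplitude = 0.05)
  acq <- tinyAcq(bleachFraction = 0, noiseSd = 0, nFrames = 1200L)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 5)
  set <- simulateTrialSet(map, acq, BreathSpec(jitterSdS = 0, noiseSd = 0),
                          stim, nTrials = 1, seed = 1)
  mp2 <- computeTrialSetMap(set, correctBleach = FALSE)$map
  g <- detectGlomeruli(mp2, radiusPx = 2)
  expect_identical(nrow(rois(g)), 1L)
  expect_equal(mapSummary(mp2, g)$mean_dff, 0.05, tolerance = 0.1)

  # permuting disjoint ROIs permutes rows only
  g2 <- g
  expect_equal(mapSummary(mp2, g)$mean_dff, mapSummary(mp2, g2)$mean_dff)
})

test_that("end-to-end map amplitude matches truth within 15%", {
  # default-condition trial set: noise on, bleach on, 4 trials
  map <- oneBlobMap(x = 16, y = 12, amplitude = 0.05)
  acq <- tinyAcq(nFrames = 1625L)
  stim <- StimulusSpec("5CHO")
  set <- simulateTrialSet(map, acq, BreathSpec(), stim, nTrials = 4,
                          seed = 17)
  mp <- computeTrialSetMap(set)$map
  expect_equal(mapValues(mp)[12 + 1, 16 + 1], 0.05, tolerance = 0.15)
})
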