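test_that("medial layout is the dorsal layout reflected and translated", {
  p0 <- generateMapPair(1, "5CHO", apOffsetPx = 0L, seed = 1)
  H <- p0$dorsal@frameDim[1L]
  expect_equal(p0$medial@glomeruli$x, p0$dorsal@glomeruli$x)
  expect_equal(p0$medial@glomeruli$y, (H - 1) - p0$dorsal@glomeruli$y)

  p <- generateMapPair(5, paste0(3:7, "CHO"), apOffsetPx = 12L, seed = 2)
  expect_equal(p$medial@glomeruli$x, p$dorsal@glomeruli$x + 12)
  expect_equal(p$medial@glomeruli$y, (H - 1) - p$dorsal@glomeruli$y)
  expect_identical(p$medial@tuning, p$dorsal@tuning)  # homologous tuning
  expect_true(p$medial@flipApplied)
})

test_that("map-pair generation is deterministic and bounded", {
  a <- generateMapPair(8, paste0(3:7, "CHO"), seed = 7)
  b <- generateMapPair(8, paste0(3:7, "CHO"), seed = 7)
  expect_identical(a$dorsal@glomeruli, b$dorsal@glomeruli)
  expect_identical(a$dorsal@tuning, b$dorsal@tuning)
  expect_error(generateMapPair(500, "5CHO", frameDim = c(64L, 64L),
                               seed = 1),
               "overcrowded")
  expect_error(generateMapPair(2, "5CHO", apOffsetPx = 40L, marginPx = 10))
})

test_that("chemotopic tuning drifts monotonically along the axis", {
  for (seed in c(7, 21, 99)) {
    p <- generateMapPair(8, paste0(3:7, "CHO"), seed = seed)
    for (spec in p) {
      proj <- spec@glomeruli$x  # axis (1, 0): anterior-posterior columns
      best <- proj[apply(spec@tuning, 2L, which.max)]
      expect_true(all(diff(best) >= 0) || all(diff(best) <= 0))
      # each odorant has a fully tuned glomerulus
      expect_equal(unname(apply(spec@tuning, 2L, max)), rep(0.08, 5))
    }
  }
})

test_that("noiseless jitter-free breathing has exact cycle structure", {
  br <- generateBreathTrace(BreathSpec(rateHz = 2, jitterSdS = 0,
                                       noiseSd = 0), 13)
  on <- inhalationOnsets(br)
  expect_length(on, 26)  # 2 Hz x 13 s
  expect_equal(unique(round(diff(on), 9)), 0.5)  # all periods 1/rate
  en <- inhalationEnds(br)
  expect_true(all(en > on[seq_along(en)]))
  expect_equal(en - on[seq_along(en)], rep(0.35 / 2, length(en)))
})

test_that("breath generation is deterministic under a seed", {
  a <- generateBreathTrace(BreathSpec(seed = 5), 13)
  b <- generateBreathTrace(BreathSpec(seed = 5), 13)
  expect_identical(a@samples, b@samples)
  expect_identical(inhalationOnsets(a), inhalationOnsets(b))
})

test_that("stimulus schedules on the first inhalation end after request", {
  tr <- eventTrace(onsets = c(4.5, 4.8, 5.3), ends = c(4.9, 5.2, 5.7))
  expect_equal(scheduleStimulus(StimulusSpec("x", requestedOnsetS = 5.0), tr),
               5.2)
  expect_equal(scheduleStimulus(StimulusSpec("x", requestedOnsetS = 5.2), tr),
               5.2)  # inclusive boundary
  # earlier request is floored at the minimum prestimulus period
  got <- scheduleStimulus(StimulusSpec("x", requestedOnsetS = 3.0,
                                       minPrestimulusS = 4), tr)
  expect_equal(got, 4.9)
  expect_gte(got, 4)
  expect_error(scheduleStimulus(StimulusSpec("x", requestedOnsetS = 6), tr),
               "no inhalation end")
})

test_that("rendering with zero amplitude, noise and bleach is static", {
  map <- oneBlobMap(amplitude = 0)
  acq <- tinyAcq(bleachFraction = 0, noiseSd = 0, nFrames = 900L)
  br <- generateBreathTrace(BreathSpec(jitterSdS = 0, noiseSd = 0), 900 / 125)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 4)
  tr <- renderTrial(map, acq, br, stim, scheduleStimulus(stim, br))
  a <- movieData(tr@movie)
  expect_equal(max(apply(a, c(1, 2), stats::var)), 0)
})

test_that("windowed dF/F0 at a blob centre equals the tuning amplitude", {
  map <- oneBlobMap(x = 16, y = 12, amplitude = 0.05)
  acq <- tinyAcq(bleachFraction = 0, noiseSd = 0, nFrames = 1200L)
  br <- generateBreathTrace(BreathSpec(jitterSdS = 0, noiseSd = 0), 1200 / 125)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 5)
  tr <- renderTrial(map, acq, br, stim, scheduleStimulus(stim, br))
  a <- movieData(tr@movie)
  anchor <- tr@truth$anchorFrame
  px <- a[12 + 1, 16 + 1, ]  # 0-based centre -> 1-based index
  R <- mean(px[(anchor + 1):(anchor + 200)])
  B <- mean(px[(anchor - 175 + 1):(anchor - 50)])
  expect_equal((R - B) / B, 0.05, tolerance = 0.01)
})

test_that("bleaching factor follows its closed form", {
  map <- oneBlobMap(amplitude = 0)
  acq <- tinyAcq(bleachFraction = 0.2, bleachTauS = 5, noiseSd = 0,
                 nFrames = 1625L)
  br <- generateBreathTrace(BreathSpec(jitterSdS = 0, noiseSd = 0), 13)
  stim <- StimulusSpec("5CHO")
  tr <- renderTrial(map, acq, br, stim, scheduleStimulus(stim, br))
  a <- movieData(tr@movie)
  tLast <- (1625 - 1) / 125
  expect_equal(mean(a[, , 1625]) / mean(a[, , 1]),
               1 - 0.2 * (1 - exp(-tLast / 5)), tolerance = 1e-9)
})

test_that("trial rendering is deterministic and mirror-consistent", {
  pair <- generateMapPair(3, "5CHO", apOffsetPx = 4L, frameDim = c(32L, 32L),
                          marginPx = 10, minSepPx = 6, seed = 3)
  acq <- tinyAcq(bleachFraction = 0, noiseSd = 0, nFrames = 1000L)
  br <- generateBreathTrace(BreathSpec(jitterSdS = 0, noiseSd = 0), 8)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 4.2)
  on <- scheduleStimulus(stim, br)
  d <- movieData(renderTrial(pair$dorsal, acq, br, stim, on)@movie)
  m <- movieData(renderTrial(pair$medial, acq, br, stim, on)@movie)
  d2 <- movieData(renderTrial(pair$dorsal, acq, br, stim, on)@movie)
  expect_identical(d, d2)
  # fractional response of the medial view equals the flipped, shifted
  # dorsal response (frame / first frame removes the baseline field)
  f <- 700L  # a frame well inside the response
  respD <- d[, , f] / d[, , 1] - 1
  respM <- m[, , f] / m[, , 1] - 1
  respM <- respM[32:1, ]                       # undo dorso-ventral flip
  expect_equal(respM[, (4 + 1):32], respD[, 1:(32 - 4)], tolerance = 1e-9)
})

test_that("trial sets share stimulus but vary breath and noise", {
  map <- oneBlobMap()
  acq <- tinyAcq(nFrames = 1200L)
  set <- simulateTrialSet(map, acq, BreathSpec(), StimulusSpec("5CHO"),
                          nTrials = 3, seed = 9)
  expect_length(set, 3)
  onsets <- vapply(set, function(t) t@onsetS, numeric(1))
  expect_gt(stats::sd(onsets), 0)  # independent breath jitter
  set2 <- simulateTrialSet(map, acq, BreathSpec(), StimulusSpec("5CHO"),
                           nTrials = 3, seed = 9)
  expect_identical(movieData(set[[2]]@movie), movieData(set2[[2]]@movie))
})
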