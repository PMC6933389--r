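test_that("block partition tiles the frame exactly", {
  b <- partitionBlocks(c(128, 128), 4)
  expect_identical(nrow(b), 1024L)
  b8 <- partitionBlocks(c(8, 8), 4)
  expect_identical(nrow(b8), 4L)
  expect_identical(unlist(b8[1, c("row0", "row1", "col0", "col1")],
                          use.names = FALSE),
                   c(1L, 4L, 1L, 4L))
  # exact cover, no overlap
  cover <- matrix(0L, 8, 8)
  for (i in seq_len(nrow(b8)))
    cover[b8$row0[i]:b8$row1[i], b8$col0[i]:b8$col1[i]] <-
      cover[b8$row0[i]:b8$row1[i], b8$col0[i]:b8$col1[i]] + 1L
  expect_true(all(cover == 1L))
  expect_error(partitionBlocks(c(10, 8), 4), "remainders 2, 0")
})

test_that("exponential fit recovers a noiseless decay to 0.1%", {
  t <- (0:1624) / 125
  y <- 100 * exp(-t / 5) + 50
  fit <- fitBlockExponential(y, 125)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 100, tolerance = 1e-3)
  expect_equal(fit$tau_s, 5, tolerance = 1e-3)
  expect_equal(fit$offset, 50, tolerance = 1e-3)
  expect_identical(fit$n_fit, 485L)  # exactly head + tail samples
})

test_that("a constant trace yields a degenerate, non-converged fit", {
  fit <- fitBlockExponential(rep(100, 600), 125)
  expect_false(fit$converged)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$offset, 100)
  expect_error(fitBlockExponential(rep(1, 485), 125), "need more than")
})

test_that("correcting a pure fitted-shape trace flattens it to the plateau", {
  t <- (0:999) / 125
  fit <- fitBlockExponential(3 * (80 * exp(-t / 4) + 40), 125)
  k <- 1.7
  trace <- k * (fit$amplitude * exp(-t / fit$tau_s) + fit$offset)
  corrected <- correctPixel(trace, fit, 125)
  expect_equal(corrected, rep(k * fit$offset, length(t)), tolerance = 1e-6)
  # zero-amplitude (non-converged) fit passes through unchanged
  flat <- fitBlockExponential(rep(100, 600), 125)
  expect_identical(correctPixel(trace, flat, 125), trace)
})

test_that("non-positive first frames are skipped and flagged", {
  t <- (0:999) / 125
  fit <- fitBlockExponential(80 * exp(-t / 4) + 40, 125)
  trace <- c(-1, rep(50, 999))
  out <- correctPixel(trace, fit, 125)
  expect_true(isTRUE(attr(out, "skipped")))
  expect_equal(as.numeric(out), trace)
})

test_that("block-noise score separates seamless from blocky movies", {
  set.seed(4)
  # smooth movie: slowly varying spatial ramp + mild noise
  H <- 32; W <- 32; Tn <- 40
  ramp <- outer(seq(0, 1, length.out = H), seq(0, 2, length.out = W), "+")
  smooth <- array(ramp, c(H, W, Tn)) +
    array(rnorm(H * W * Tn, 0, 0.05), c(H, W, Tn))
  sc <- blockNoiseScore(smooth, 4)
  expect_gt(sc, 0.8); expect_lt(sc, 1.2)
  # per-block i.i.d. offsets create strong boundary contrast
  offsets <- matrix(rnorm(64, 0, 5), 8, 8)
  blocky <- smooth + array(offsets[rep(1:8, each = 4), rep(1:8, each = 4)],
                           c(H, W, Tn))
  expect_gt(blockNoiseScore(blocky, 4), 2)
  # uniform movie: score 1 by convention
  expect_equal(blockNoiseScore(array(7, c(8, 8, 5)), 4), 1)
})

test_that("correction is idempotent in the limit", {
  map <- oneBlobMap()
  acq <- tinyAcq(nFrames = 1000L)  # bleach 0.2, tau 5, default noise
  set.seed(11)
  br <- generateBreathTrace(BreathSpec(), 8)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 4.2)
  tr <- renderTrial(map, acq, br, stim, scheduleStimulus(stim, br))
  bc1 <- bleachCorrect(tr@movie, computeScore = FALSE)
  bc2 <- bleachCorrect(bc1$movie, computeScore = FALSE)
  rel <- sqrt(mean((movieData(bc2$movie) - movieData(bc1$movie))^2)) /
    sqrt(mean(movieData(bc1$movie)^2))
  expect_lt(rel, 0.005)
})

test_that("tau is recovered per block on a default synthetic trial", {
  map <- oneBlobMap()
  acq <- tinyAcq(nFrames = 1625L)  # bleach 0.2, tau 5, default noise
  set.seed(21)
  br <- generateBreathTrace(BreathSpec(), 13)
  stim <- StimulusSpec("5CHO")
  tr <- renderTrial(map, acq, br, stim, scheduleStimulus(stim, br))
  bc <- bleachCorrect(tr@movie, computeScore = FALSE)
  fits <- bc$report@fits
  expect_true(all(fits$converged))
  expect_lt(median(abs(fits$tau_s - 5) / 5), 0.05)
})

test_that("correcting a bleach-free trial barely changes its map", {
  map <- oneBlobMap()
  acq <- tinyAcq(nFrames = 1000L, bleachFraction = 0)
  set.seed(31)
  stim <- StimulusSpec("5CHO", requestedOnsetS = 4.2)
  set <- simulateTrialSet(map, acq, BreathSpec(), stim, nTrials = 2,
                          seed = 31)
  m0 <- computeTrialSetMap(set, correctBleach = FALSE)$map
  m1 <- computeTrialSetMap(set, correctBleach = TRUE)$map
  rel <- sqrt(mean((mapValues(m1) - mapValues(m0))^2)) /
    sqrt(mean(mapValues(m0)^2))
  expect_lt(rel, 0.01)
})
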