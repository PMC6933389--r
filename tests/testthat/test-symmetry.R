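test_that("the medial flip is an involution that moves rows only", {
  v <- matrix(0, 16, 16); v[3, 7] <- 1
  m <- bareMap(v, view = "medial")
  f <- flipMedial(m)
  expect_equal(which(mapValues(f) == 1, arr.ind = TRUE)[1, ],
               c(row = 16 - 3 + 1, col = 7))
  expect_warning(ff <- flipMedial(f), "already flipped")
  expect_identical(mapValues(ff), v)
  expect_false(ff@flipped)
})

test_that("A-P registration recovers constructed shifts and is NCC-invariant", {
  set.seed(12)
  base <- matrix(0, 48, 48)
  for (i in 1:5) {
    x <- sample(10:30, 1); y <- sample(5:43, 1)
    base <- base + 0.05 * outer(exp(-((1:48) - y)^2 / 8),
                                exp(-((1:48) - x)^2 / 8))
  }
  shift <- function(m, s) {
    out <- matrix(0, nrow(m), ncol(m))
    out[, (1 + s):ncol(m)] <- m[, 1:(ncol(m) - s)]
    out
  }
  expect_identical(registerApOffset(base, base)@apShiftPx, 0L)
  expect_equal(registerApOffset(base, base)@score, 1)
  r <- registerApOffset(base, shift(base, 12), maxShiftPx = 20)
  expect_lte(abs(r@apShiftPx - 12L), 1L)
  # additive offsets do not change the optimum (NCC invariance)
  r2 <- registerApOffset(base, shift(base, 12) + 3.25, maxShiftPx = 20)
  expect_identical(r2@apShiftPx, r@apShiftPx)
  expect_error(registerApOffset(base * 0, base * 0), "zero-variance")
})

test_that("glomerulus detection finds isolated blobs and merges close ones", {
  expect_identical(nrow(rois(detectGlomeruli(bareMap(matrix(0, 64, 64))))),
                   0L)
  blob <- function(m, x, y, a, s = 2) {
    m + a * outer(exp(-((1:nrow(m)) - 1 - y)^2 / (2 * s^2)),
                  exp(-((1:ncol(m)) - 1 - x)^2 / (2 * s^2)))
  }
  set.seed(3)
  centers <- cbind(x = c(12, 30, 50, 12, 30, 50, 20, 42),
                   y = c(12, 14, 12, 40, 44, 46, 28, 30))
  v <- matrix(rnorm(64 * 64, 0, 3e-4), 64, 64)
  for (i in 1:8) v <- blob(v, centers[i, 1], centers[i, 2], 0.05)
  g <- detectGlomeruli(bareMap(v))
  expect_identical(nrow(rois(g)), 8L)
  err <- vapply(seq_len(8), function(i)
    min(sqrt((rois(g)$x - centers[i, 1])^2 +
             (rois(g)$y - centers[i, 2])^2)), numeric(1))
  expect_lt(max(err), 1)
  # two blobs 2 px apart merge into a single ROI (higher-peak priority)
  v2 <- blob(blob(matrix(0, 64, 64), 20, 20, 0.05), 22, 20, 0.04)
  expect_identical(nrow(rois(detectGlomeruli(bareMap(v2)))), 1L)
})

test_that("ensemble matching is one-to-one, gated and tuning-correlated", {
  amp <- matrix(c(1, 0.2, 0.1,
                  0.2, 1, 0.3,
                  0.1, 0.3, 1), 3, byrow = TRUE) * 0.08
  d <- bareGlomSet(x = c(10, 25, 40), y = c(10, 30, 20), amp)
  idReg <- new("Registration", apShiftPx = 0L, score = 1)
  p <- matchEnsembles(d, d, idReg)
  expect_identical(nrow(p), 3L)
  expect_equal(p$distance_px, rep(0, 3))
  expect_equal(p$tuning_cor, rep(1, 3))
  # a shifted copy matches through the registration
  m <- bareGlomSet(x = c(10, 25, 40) + 6, y = c(10, 30, 20), amp)
  p2 <- matchEnsembles(d, m, new("Registration", apShiftPx = 6L, score = 1))
  expect_identical(nrow(p2), 3L)
  # an extra spurious ROI stays unmatched
  m3 <- bareGlomSet(x = c(10, 25, 40, 60) + 6, y = c(10, 30, 20, 55),
                    rbind(amp, 0.001))
  p3 <- matchEnsembles(d, m3,
                       new("Registration", apShiftPx = 6L, score = 1))
  expect_identical(nrow(p3), 3L)
  expect_false(4L %in% p3$medial_id)
  # far-apart ROIs beyond the gate are rejected
  p4 <- matchEnsembles(d, m, idReg, gatePx = 2)
  expect_identical(nrow(p4), 0L)
  # empty sets give an empty table
  e <- bareGlomSet(numeric(0), numeric(0),
                   matrix(numeric(0), 0, 3))
  expect_identical(nrow(matchEnsembles(d, e, idReg)), 0L)
})

test_that("chemotopic argmax positions are monotone for gradient tuning", {
  # positions ordered along x; tuning peaks advance along the panel
  x <- c(10, 20, 30, 40, 50)
  amp <- 0.08 * exp(-outer(x, x, "-")^2 / 200)
  colnames(amp) <- paste0(3:7, "CHO")
  g <- bareGlomSet(x = x, y = rep(20, 5), amp)
  ch <- chemotopyShift(g, paste0(3:7, "CHO"))
  expect_true(ch$monotone)
  expect_true(all(ch$table$present))
  expect_true(all(diff(ch$table$projection) >= 0))
  expect_error(chemotopyShift(g, "3CHO"), "at least 3")
  # an unresponsive odorant is marked absent and skipped
  amp2 <- amp; amp2[, 2] <- 0
  g2 <- bareGlomSet(x = x, y = rep(20, 5), amp2)
  ch2 <- chemotopyShift(g2, paste0(3:7, "CHO"), responseFloor = 1e-6)
  expect_false(ch2$table$present[2])
  expect_true(ch2$monotone)
})

test_that("shuffled tuning rarely looks chemotopic", {
  x <- seq(8, 56, length.out = 8)
  amp <- 0.08 * exp(-outer(x, seq(8, 56, length.out = 5), "-")^2 / 150)
  monotone <- vapply(1:40, function(seed) {
    set.seed(seed)
    shuf <- apply(amp, 2L, sample)  # permute glomeruli per odorant
    colnames(shuf) <- paste0(3:7, "CHO")
    chemotopyShift(bareGlomSet(x, rep(20, 8), shuf),
                   paste0(3:7, "CHO"))$monotone
  }, logical(1))
  expect_lt(mean(monotone), 0.5)
})

test_that("concentration-response counts are stable for saturating tuning", {
  mk <- function(a) bareGlomSet(c(10, 25, 40), c(10, 30, 20),
                                matrix(a, 3, 1,
                                       dimnames = list(NULL, "EC")))
  sets <- list("0.02" = mk(c(0.040, 0.035, 0.00)),
               "0.2" = mk(c(0.055, 0.050, 0.00)),
               "2" = mk(c(0.058, 0.053, 0.00)))
  cr <- concentrationResponse(sets, responseFloor = 0.02)
  expect_equal(cr$counts$n_responding, c(2, 2, 2))
  expect_equal(concentrationResponse(sets, responseFloor = 1)$counts$n_responding,
               c(0, 0, 0))
  expect_equal(concentrationResponse(sets, responseFloor = 0)$counts$n_responding,
               c(3, 3, 3))  # floor 0 counts every ROI
  bad <- sets
  bad[[2]]@frameDim <- c(32L, 32L)
  expect_error(concentrationResponse(bad, 0.02), "same field")
})
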