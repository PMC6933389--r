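#' Partition a frame into square blocks
#'
#' The bleaching correction operates block-wise: a 128 x 128 frame divided
#' into 4 x 4 pixel blocks yields 1,024 blocks.  The frame must tile
#' exactly.
#'
#' @param frameDim integer `(H, W)`.
#' @param blockSize block edge length, pixels.
#' @return data.frame in row-major order (block rows vary slowest) with
#'   1-based inclusive pixel extents `row0`, `row1`, `col0`, `col1` and the
#'   block-grid indices `row`, `col`.
#' @examples
#' nrow(partitionBlocks(c(128, 128), 4))  # 1024
#' @export
partitionBlocks <- function(frameDim, blockSize = 4L) {
  H <- as.integer(frameDim[1L]); W <- as.integer(frameDim[2L])
  blockSize <- as.integer(blockSize)
  stopifnot(blockSize >= 1L)
  if (H %% blockSize != 0L || W %% blockSize != 0L)
    stop("frame ", H, " x ", W, " is not divisible by block size ",
         blockSize, " (remainders ", H %% blockSize, ", ", W %% blockSize,
         ")")
  nr <- H %/% blockSize; nc <- W %/% blockSize
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
  data.frame(
    row = grid$row, col = grid$col,
    row0 = (grid$row - 1L) * blockSize + 1L,
    row1 = grid$row * blockSize,
    col0 = (grid$col - 1L) * blockSize + 1L,
    col1 = grid$col * blockSize
  )
}

#' Fit a single-exponential bleaching curve to a block-mean trace
#'
#' Fits `y(t) = amplitude * exp(-t / tau_s) + offset` by least squares to
#' the first `headFrames` frames plus the last `tailFrames` frames only.
#' The head captures the prestimulus decay; the few tail frames pin the
#' curve's plateau and prevent overcorrection from overfitting the early
#' frames, while being too few to distort the fit elsewhere.  The stimulus
#' response (which starts after the head window) never enters the fit.
#'
#' The offset term is essential: the plateau is the resting fluorescence
#' that the later dF/F0 division needs, so the correction removes only the
#' decaying component (see [correctPixel()]).
#'
#' Internally amplitude and offset are solved linearly at fixed tau and
#' tau is optimized over `[0.1, 10 * trial length]` seconds.  The fit is
#' reported `converged = FALSE` (with `amplitude = 0` and `offset =
#' mean(trace)`) when the amplitude is not significantly nonzero
#' (|amplitude| <= 3 standard errors), as for a bleach-free trace.
#'
#' @param trace numeric block-mean time series.
#' @param frameRateHz frame rate, Hz.
#' @param headFrames,tailFrames number of leading/trailing frames entering
#'   the fit (defaults 480 and 5: 3.8 s and 0.04 s at 125 Hz).
#' @return list of class `"BlockFit"` with `amplitude`, `tau_s`, `offset`,
#'   `rss`, `converged` and `n_fit` (always `headFrames + tailFrames`).
#' @export
fitBlockExponential <- function(trace, frameRateHz, headFrames = 480L,
                                tailFrames = 5L) {
  n <- length(trace)
  headFrames <- as.integer(headFrames); tailFrames <- as.integer(tailFrames)
  stopifnot(headFrames >= 2L, tailFrames >= 1L, frameRateHz > 0)
  if (n <= headFrames + tailFrames)
    stop("trace has ", n, " frames; need more than headFrames + tailFrames = ",
         headFrames + tailFrames)
  idx <- c(seq_len(headFrames), (n - tailFrames + 1L):n)
  tAll <- frameTimes(n, frameRateHz)
  tf <- tAll[idx]; yf <- trace[idx]
  m <- length(idx)

  # amplitude/offset are linear given tau; profile the residual sum of
  # squares over tau only
  linfit <- function(tau) {
    e <- exp(-tf / tau)
    X <- cbind(e, 1)
    fit <- stats::lm.fit(X, yf)
    list(A = fit$coefficients[1L], C = fit$coefficients[2L],
         rss = sum(fit$residuals^2), e = e)
  }
  tauMax <- 10 * n / frameRateHz
  opt <- tryCatch(
    stats::optimize(function(tau) linfit(tau)$rss, c(0.1, tauMax),
                    tol = 1e-6),
    error = function(e) NULL)

  fallback <- function() {
    structure(list(amplitude = 0, tau_s = NA_real_,
                   offset = mean(trace),
                   rss = sum((yf - mean(yf))^2),
                   converged = FALSE, n_fit = m),
              class = "BlockFit")
  }
  if (is.null(opt)) return(fallback())
  tau <- opt$minimum
  lf <- linfit(tau)
  if (!is.finite(lf$A) || !is.finite(lf$C)) return(fallback())
  # amplitude significance from the linear subproblem at the optimal tau
  sigma2 <- lf$rss / (m - 2L)
  e <- lf$e
  sAA <- sum((e - mean(e))^2)
  seA <- sqrt(sigma2 / sAA)
  if (!is.finite(seA) || sAA < 1e-12 || abs(lf$A) <= 3 * seA)
    return(fallback())
  structure(list(amplitude = unname(lf$A), tau_s = tau,
                 offset = unname(lf$C), rss = lf$rss,
                 converged = TRUE, n_fit = m),
            class = "BlockFit")
}

#' Correct one pixel's time course for photobleaching
#'
#' Scales the block's fitted curve so its initial value matches the
#' pixel's first frame (`k = trace[1] / (amplitude + offset)`) and
#' subtracts only the scaled decaying component `k * amplitude *
#' exp(-t / tau)`.  The scaled plateau `k * offset` is preserved, so a
#' pixel that follows the fitted shape exactly becomes constant at
#' `k * offset` and the corrected trace keeps a positive baseline for the
#' dF/F0 division.  Non-converged fits, zero amplitudes and non-positive
#' first frames pass the trace through unchanged (the latter flagged via
#' attribute `"skipped"`).
#'
#' @param trace numeric pixel time series.
#' @param fit a `"BlockFit"` from [fitBlockExponential()].
#' @param frameRateHz frame rate, Hz.
#' @return the corrected time series.
#' @export
correctPixel <- function(trace, fit, frameRateHz) {
  stopifnot(inherits(fit, "BlockFit"), frameRateHz > 0)
  if (!fit$converged || fit$amplitude == 0) return(trace)
  if (trace[1L] <= 0) {
    attr(trace, "skipped") <- TRUE
    return(trace)
  }
  k <- trace[1L] / (fit$amplitude + fit$offset)
  t <- frameTimes(length(trace), frameRateHz)
  trace - k * fit$amplitude * exp(-t / fit$tau_s)
}

#' Block-boundary artifact score
#'
#' Quantifies the "block noise" a failed block-wise correction produces:
#' per frame, the mean absolute intensity difference across block
#' boundaries divided by the mean absolute difference between neighboring
#' pixels inside blocks, averaged over frames.  Seamless images score
#' about 1; independent per-block offsets push the score well above 1.
#' Frames where both terms vanish (uniform images) score 1 by convention.
#'
#' @param movie a [Movie] or H x W x T array.
#' @param blockSize block edge length, pixels.
#' @return non-negative scalar score.
#' @export
blockNoiseScore <- function(movie, blockSize = 4L) {
  a <- if (is(movie, "Movie")) movieData(movie) else movie
  d <- dim(a)
  H <- d[1L]; W <- d[2L]; Tn <- d[3L]
  blockSize <- as.integer(blockSize)
  if (H %% blockSize != 0L || W %% blockSize != 0L)
    stop("frame is not divisible by the block size")
  # boundary pairs are (r, r + 1) with r a multiple of the block size
  bRow <- if (H > blockSize) seq(blockSize, H - blockSize, by = blockSize)
          else integer(0)
  bCol <- if (W > blockSize) seq(blockSize, W - blockSize, by = blockSize)
          else integer(0)
  eps <- .Machine$double.eps
  scores <- vapply(seq_len(Tn), function(f) {
    fr <- a[, , f]
    dr <- abs(fr[-1L, , drop = FALSE] - fr[-H, , drop = FALSE])
    dc <- abs(fr[, -1L, drop = FALSE] - fr[, -W, drop = FALSE])
    boundary <- c(dr[bRow, ], dc[, bCol])
    within <- c(if (length(bRow)) dr[-bRow, ] else dr,
                if (length(bCol)) dc[, -bCol] else dc)
    if (!length(boundary)) return(1)  # single block: no boundaries
    num <- mean(boundary); den <- mean(within)
    if (num < eps && den < eps) 1 else num / max(den, eps)
  }, numeric(1))
  mean(scores)
}

#' Block-wise photobleaching correction of a movie
#'
#' Partitions the frame into blocks ([partitionBlocks()]), fits a
#' single-exponential bleaching curve to each block-mean trace
#' ([fitBlockExponential()]), and applies the per-pixel scaled subtraction
#' ([correctPixel()]) to every pixel of each block.  The corrected movie
#' is then scored for block-boundary artifacts ([blockNoiseScore()]); a
#' score above `excludeThreshold` marks the trial for exclusion from
#' further analysis, emulating the rare (<1%) trials dropped for block
#' noise.
#'
#' @param movie a [Movie].
#' @param blockSize block edge length, pixels (default 4).
#' @param headFrames,tailFrames fitting-window sizes, frames.
#' @param excludeThreshold block-noise score above which the trial is
#'   marked excluded (default 2).
#' @param computeScore set `FALSE` to skip the score (e.g. in bulk
#'   parameter-recovery runs); the report then carries `NA` and
#'   `excluded = FALSE`.
#' @return list with `movie` (corrected [Movie]) and `report`
#'   (a [CorrectionReport]).
#' @export
bleachCorrect <- function(movie, blockSize = 4L, headFrames = 480L,
                          tailFrames = 5L, excludeThreshold = 2,
                          computeScore = TRUE) {
  stopifnot(is(movie, "Movie"))
  a <- movieData(movie)
  fs <- frameRate(movie)
  Tn <- dim(a)[3L]
  blocks <- partitionBlocks(dim(a)[1:2], blockSize)
  t <- frameTimes(Tn, fs)
  nSkipped <- 0L
  fitRows <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    rr <- blocks$row0[b]:blocks$row1[b]
    cc <- blocks$col0[b]:blocks$col1[b]
    px <- matrix(a[rr, cc, ], nrow = length(rr) * length(cc))  # pixels x T
    fit <- fitBlockExponential(colMeans(px), fs, headFrames, tailFrames)
    if (fit$converged && fit$amplitude != 0) {
      k <- px[, 1L] / (fit$amplitude + fit$offset)
      skip <- px[, 1L] <= 0
      nSkipped <- nSkipped + sum(skip)
      k[skip] <- 0
      px <- px - (k * fit$amplitude) %o% exp(-t / fit$tau_s)
      a[rr, cc, ] <- array(px, c(length(rr), length(cc), Tn))
    }
    fitRows[[b]] <- data.frame(
      row = blocks$row[b], col = blocks$col[b],
      amplitude = fit$amplitude, tau_s = fit$tau_s, offset = fit$offset,
      rss = fit$rss, converged = fit$converged)
  }
  fits <- do.call(rbind, fitRows)
  corrected <- Movie(a, frameRateHz = fs, pixelSizeUm = movie@pixelSizeUm)
  score <- if (computeScore) blockNoiseScore(a, blockSize) else NA_real_
  report <- new("CorrectionReport", fits = fits, blockNoiseScore = score,
                excluded = isTRUE(score > excludeThreshold),
                threshold = excludeThreshold, nSkippedPixels = nSkipped)
  list(movie = corrected, report = report)
}
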