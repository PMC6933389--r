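#' Generate a mirror-related pair of glomerular map layouts
#'
#' Most odorant-receptor types project to one lateral and one medial
#' glomerulus per bulb, forming two mirror-symmetric maps.  This generator
#' lays out `nGlomeruli` Gaussian-blob glomeruli on the dorsal view and
#' derives the medial view as seen through the mirror prism: the layout is
#' reflected about the horizontal image axis (dorso-ventral inversion) and
#' translated by `apOffsetPx` along the anterior-posterior (column) axis to
#' emulate prism placement.  Homologous glomeruli carry identical tuning by
#' construction.
#'
#' For an ordered homologous-series panel (e.g. aldehydes 3CHO..7CHO) the
#' tuning is chemotopic: each odorant's preferred position advances along
#' `chemotopyAxis`, so the most-sensitive glomerulus drifts monotonically
#' with panel order in both views.
#'
#' @param nGlomeruli number of glomeruli (>= 1).
#' @param odorantPanel character vector of odorant labels, in series order.
#' @param chemotopyAxis unit vector `(dx, dy)` of the chemotopic gradient
#'   in image coordinates (default anterior-posterior, along columns).
#' @param apOffsetPx integer prism-placement offset, pixels.
#' @param frameDim integer `(H, W)`.
#' @param radiusPx blob radius (Gaussian sigma is `radiusPx / 2`).
#' @param peakAmplitude peak windowed dF/F0 of a best-tuned glomerulus.
#' @param marginPx placement margin from the frame edge; must be at least
#'   `|apOffsetPx|` so medial centres stay in frame.
#' @param minSepPx minimum centre-to-centre separation, pixels.
#' @param seed optional integer seed.
#' @return list with elements `dorsal` and `medial`, both [MapSpec].
#' @export
generateMapPair <- function(nGlomeruli, odorantPanel,
                            chemotopyAxis = c(1, 0), apOffsetPx = 12L,
                            frameDim = c(128L, 128L), radiusPx = 4,
                            peakAmplitude = 0.08, marginPx = 16,
                            minSepPx = 12, seed = NULL) {
  stopifnot(nGlomeruli >= 1, length(odorantPanel) >= 1,
            length(chemotopyAxis) == 2L, any(chemotopyAxis != 0),
            radiusPx > 0, peakAmplitude >= 0)
  if (!is.null(seed)) set.seed(seed)
  H <- as.integer(frameDim[1L]); W <- as.integer(frameDim[2L])
  apOffsetPx <- as.integer(apOffsetPx)
  if (marginPx < abs(apOffsetPx))
    stop("marginPx must be >= |apOffsetPx| so that offset medial centres ",
         "remain within the frame")
  if (W - 1 - 2 * marginPx <= 0 || H - 1 - 2 * marginPx <= 0)
    stop("frame too small for the requested placement margin")

  # rejection-sampled placement with a bounded retry budget
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; budget <- 400L * nGlomeruli
  while (length(xs) < nGlomeruli) {
    if (tries >= budget)
      stop("could not place ", nGlomeruli, " glomeruli with separation ",
           minSepPx, " px in a ", H, " x ", W, " frame (overcrowded); ",
           "reduce nGlomeruli or minSepPx")
    tries <- tries + 1L
    x <- stats::runif(1, marginPx, W - 1 - marginPx)
    y <- stats::runif(1, marginPx, H - 1 - marginPx)
    if (!length(xs) || all(sqrt((xs - x)^2 + (ys - y)^2) >= minSepPx)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }

  ax <- chemotopyAxis / sqrt(sum(chemotopyAxis^2))
  proj <- xs * ax[1L] + ys * ax[2L]
  m <- length(odorantPanel)
  # preferred positions are the projections of actual glomeruli, spread
  # over the series, so each odorant has a best-tuned glomerulus at full
  # peak amplitude and the argmax advances along the axis with panel order
  ord <- order(proj)
  prefIdx <- ord[as.integer(round(seq(1, nGlomeruli, length.out = m)))]
  prefs <- proj[prefIdx]
  spacing <- if (m > 1) max(mean(diff(sort(prefs))), 1e-6) else
    max(diff(range(proj)), radiusPx)
  w <- spacing / 1.2
  tuning <- outer(proj, prefs, function(q, p)
    peakAmplitude * exp(-(q - p)^2 / (2 * w^2)))
  colnames(tuning) <- odorantPanel

  glom <- data.frame(x = xs, y = ys, radius = radiusPx)
  dorsal <- new("MapSpec", glomeruli = glom, tuning = tuning,
                view = "dorsal", apOffsetPx = 0L, flipApplied = FALSE,
                frameDim = c(H, W))
  glomM <- data.frame(x = xs + apOffsetPx, y = (H - 1) - ys,
                      radius = radiusPx)
  medial <- new("MapSpec", glomeruli = glomM, tuning = tuning,
                view = "medial", apOffsetPx = apOffsetPx,
                flipApplied = TRUE, frameDim = c(H, W))
  list(dorsal = dorsal, medial = medial)
}
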