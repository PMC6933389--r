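#' @rdname flipMedial
setMethod("flipMedial", "ActivityMap", function(map) {
  if (map@flipped)
    warning("map is already flipped; flipping again (involution guard)")
  map@values <- map@values[rev(seq_len(nrow(map@values))), , drop = FALSE]
  map@flagged <- map@flagged[rev(seq_len(nrow(map@flagged))), , drop = FALSE]
  map@flipped <- !map@flipped
  map
})

mapMatrix <- function(x) {
  if (is(x, "ActivityMap")) mapValues(x) else as.matrix(x)
}

#' Register the anterior-posterior prism offset between views
#'
#' The prism sits at a slightly different anterior-posterior position in
#' each preparation, so after the dorso-ventral un-flip the medial map is
#' shifted along the anterior-posterior (column) axis relative to the
#' dorsal map.  This performs an exhaustive 1-D search over integer column
#' shifts in `[-maxShiftPx, maxShiftPx]`, maximizing the Pearson
#' (normalized cross-) correlation over the overlapping region; ties break
#' toward the smallest absolute shift.  The score is invariant to additive
#' offsets and positive rescaling of either map.
#'
#' @param dorsal,medialFlipped [ActivityMap]s (or plain matrices) of equal
#'   shape; the medial one already un-flipped via [flipMedial()].
#' @param maxShiftPx maximum |shift| searched, pixels.
#' @return a [Registration]; `apShiftPx = s` means dorsal column `c`
#'   corresponds to medial column `c + s`.
#' @export
registerApOffset <- function(dorsal, medialFlipped, maxShiftPx = 20L) {
  if (is(medialFlipped, "ActivityMap") && !medialFlipped@flipped)
    warning("medial map does not appear to be flipped; ",
            "apply flipMedial() before registration")
  d <- mapMatrix(dorsal); m <- mapMatrix(medialFlipped)
  if (!identical(dim(d), dim(m)))
    stop("maps must have the same shape")
  W <- ncol(d)
  maxShiftPx <- as.integer(maxShiftPx)
  stopifnot(maxShiftPx >= 0L, maxShiftPx < W)
  shifts <- seq(-maxShiftPx, maxShiftPx)
  shifts <- shifts[order(abs(shifts), shifts)]  # prefer small |shift|
  best <- NULL; bestScore <- -Inf
  for (s in shifts) {
    cd <- max(1L, 1L - s):min(W, W - s)  # dorsal cols; medial cols cd + s
    dd <- d[, cd]; mm <- m[, cd + s]
    if (stats::sd(dd) == 0 || stats::sd(mm) == 0) next
    sc <- stats::cor(as.vector(dd), as.vector(mm))
    if (sc > bestScore + 1e-12) {
      bestScore <- sc; best <- s
    }
  }
  if (is.null(best))
    stop("registration failed: zero-variance overlap at every shift")
  new("Registration", flipAxis = "horizontal", apShiftPx = as.integer(best),
      score = bestScore)
}

#' Detect glomerular ROIs on a stack of activity maps
#'
#' Works on the pixelwise-maximum composite across the odorant maps:
#' Gaussian-smooth (sigma `sigmaPx`), find local maxima exceeding
#' `median + thresholdK * robust noise SD (MAD)` of the smoothed
#' composite, and grow a fixed-radius disk ROI around each accepted peak.
#' Peaks are processed in descending height; a peak within `radiusPx` of
#' an accepted one is suppressed, and contested pixels go to the
#' higher-peak ROI, so masks are disjoint.  Per-ROI mean dF/F0 amplitudes
#' are attached for every input map.
#'
#' @param maps list of [ActivityMap]s (same shape and view; for the
#'   medial view, already flipped).
#' @param sigmaPx Gaussian smoothing sigma, pixels.
#' @param thresholdK peak threshold in robust noise SDs above the median.
#' @param radiusPx disk ROI radius, pixels.
#' @param view view label; defaults to the maps' view.
#' @return a [GlomerulusSet] (possibly empty).
#' @export
detectGlomeruli <- function(maps, sigmaPx = 1, thresholdK = 3,
                            radiusPx = 3, view = NULL) {
  if (is(maps, "ActivityMap")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  mats <- lapply(maps, mapMatrix)
  dims <- unique(vapply(mats, function(m) paste(dim(m), collapse = "x"),
                        character(1)))
  if (length(dims) != 1L) stop("maps must share a frame shape")
  if (is.null(view)) {
    view <- if (is(maps[[1L]], "ActivityMap")) {
      if (maps[[1L]]@view == "medial" && maps[[1L]]@flipped)
        "medial_flipped" else maps[[1L]]@view
    } else "dorsal"
  }
  comp <- Reduce(pmax, mats)
  H <- nrow(comp); W <- ncol(comp)
  sm <- as.matrix(EBImage::gblur(comp, sigma = sigmaPx))
  # robust noise SD is measured on the raw composite; smoothing shrinks
  # noise but not blob peaks, so this keeps smoothed noise maxima well
  # below threshold.  The relative floor guards noise-free images against
  # FFT-smoothing ripple plateaus.
  md <- stats::median(sm)
  thr <- md + max(thresholdK * stats::mad(comp),
                  1e-3 * (max(sm) - md))

  # 8-neighborhood local maxima above threshold
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- sm
  isMax <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & sm >= pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  cand <- which(isMax & sm > thr, arr.ind = TRUE)
  empty <- function() new("GlomerulusSet",
    rois = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      peak = numeric(0)),
    masks = list(),
    amplitudes = matrix(numeric(0), 0L, length(mats),
                        dimnames = list(NULL, names(maps))),
    view = view, frameDim = c(H, W))
  if (!nrow(cand)) return(empty())
  peaks <- sm[cand]
  ord <- order(peaks, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; peaks <- peaks[ord]

  accR <- numeric(0); accC <- numeric(0); accP <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; c <- cand[i, 2L]
    if (length(accR) &&
        any(sqrt((accR - r)^2 + (accC - c)^2) < radiusPx)) next
    accR <- c(accR, r); accC <- c(accC, c); accP <- c(accP, peaks[i])
  }

  # disk masks, contested pixels to the higher (earlier) peak
  owner <- matrix(0L, H, W)
  for (i in seq_along(accR)) {
    rr <- max(1L, floor(accR[i] - radiusPx)):min(H, ceiling(accR[i] + radiusPx))
    cc <- max(1L, floor(accC[i] - radiusPx)):min(W, ceiling(accC[i] + radiusPx))
    for (r in rr) for (c in cc) {
      if ((r - accR[i])^2 + (c - accC[i])^2 <= radiusPx^2 &&
          owner[r, c] == 0L)
        owner[r, c] <- i
    }
  }
  masks <- lapply(seq_along(accR), function(i) which(owner == i))

  # smoothed-intensity-weighted centroid within each mask (0-based coords)
  cent <- t(vapply(masks, function(px) {
    rc <- arrayInd(px, c(H, W))
    wgt <- pmax(sm[px], 0) + 1e-12
    c(x = sum((rc[, 2L] - 1) * wgt) / sum(wgt),
      y = sum((rc[, 1L] - 1) * wgt) / sum(wgt))
  }, numeric(2)))

  amplitudes <- vapply(mats, function(m)
    vapply(masks, function(px) mean(m[px]), numeric(1)),
    numeric(length(masks)))
  if (length(masks) == 1L) amplitudes <- matrix(amplitudes, nrow = 1L)
  odorants <- vapply(seq_along(maps), function(i) {
    if (is(maps[[i]], "ActivityMap") && !is.na(maps[[i]]@odorant))
      maps[[i]]@odorant else paste0("map", i)
  }, character(1))
  colnames(amplitudes) <- odorants

  new("GlomerulusSet",
      rois = data.frame(id = seq_along(masks), x = cent[, "x"],
                        y = cent[, "y"], peak = accP),
      masks = masks, amplitudes = amplitudes, view = view,
      frameDim = c(H, W))
}

#' Match homologous glomeruli across views
#'
#' Applies the registration to the flipped-medial centroids (column
#' `x - apShiftPx` aligns with the dorsal frame) and matches dorsal to
#' medial ROIs greedily by ascending centroid distance, one-to-one,
#' rejecting pairs farther apart than `gatePx`.  Each pair carries the
#' Pearson correlation of its per-odorant amplitude vectors; homologous
#' glomeruli share a receptor type and so should have highly correlated
#' tuning.
#'
#' @param dorsal,medial [GlomerulusSet]s; the medial one detected on
#'   flipped maps.
#' @param reg a [Registration] from [registerApOffset()].
#' @param gatePx maximum pairing distance, pixels.
#' @return data.frame with columns `dorsal_id`, `medial_id`,
#'   `distance_px`, `tuning_cor`.
#' @export
matchEnsembles <- function(dorsal, medial, reg, gatePx = 5) {
  stopifnot(is(dorsal, "GlomerulusSet"), is(medial, "GlomerulusSet"),
            is(reg, "Registration"), gatePx >= 0)
  empty <- data.frame(dorsal_id = integer(0), medial_id = integer(0),
                      distance_px = numeric(0), tuning_cor = numeric(0))
  nd <- nrow(dorsal@rois); nm <- nrow(medial@rois)
  if (!nd || !nm) return(empty)
  mx <- medial@rois$x - reg@apShiftPx
  my <- medial@rois$y
  dist <- outer(dorsal@rois$x, mx, "-")^2 + outer(dorsal@rois$y, my, "-")^2
  dist <- sqrt(dist)
  pairs <- which(dist <= gatePx, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[order(dist[pairs]), , drop = FALSE]
  usedD <- logical(nd); usedM <- logical(nm)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    di <- pairs[i, 1L]; mi <- pairs[i, 2L]
    if (usedD[di] || usedM[mi]) next
    usedD[di] <- TRUE; usedM[mi] <- TRUE
    tc <- if (ncol(dorsal@amplitudes) >= 2L && ncol(medial@amplitudes) >= 2L &&
              stats::sd(dorsal@amplitudes[di, ]) > 0 &&
              stats::sd(medial@amplitudes[mi, ]) > 0)
      stats::cor(dorsal@amplitudes[di, ], medial@amplitudes[mi, ])
    else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      dorsal_id = dorsal@rois$id[di], medial_id = medial@rois$id[mi],
      distance_px = dist[di, mi], tuning_cor = tc)
  }
  do.call(rbind, out)
}

#' Chemotopic shift along an ordered odorant series
#'
#' For each odorant of an ordered homologous series (e.g. aldehydes
#' 3CHO..7CHO), finds the centroid of the most-responsive glomerulus and
#' tests whether the centroid projections onto the anterior-posterior
#' axis are weakly monotone in panel order (in either direction) -- the
#' signature of a local chemotopic representation.
#'
#' @param gset a [GlomerulusSet] whose amplitude columns cover the panel.
#' @param orderedPanel character vector of >= 3 odorant labels in series
#'   order.
#' @param responseFloor amplitude below which an odorant is marked absent
#'   and excluded from the monotonicity test.
#' @param axis unit vector `(dx, dy)` to project centroids onto (default
#'   anterior-posterior, i.e. columns).
#' @return list with `table` (odorant, roi id, centroid, projection,
#'   `present`) and `monotone` (logical flag).
#' @export
chemotopyShift <- function(gset, orderedPanel, responseFloor = 0,
                           axis = c(1, 0)) {
  stopifnot(is(gset, "GlomerulusSet"))
  if (length(orderedPanel) < 3L)
    stop("chemotopy requires an ordered panel of at least 3 odorants")
  missing <- setdiff(orderedPanel, colnames(gset@amplitudes))
  if (length(missing))
    stop("panel odorants not in the amplitude table: ",
         paste(missing, collapse = ", "))
  ax <- axis / sqrt(sum(axis^2))
  rows <- lapply(orderedPanel, function(od) {
    amps <- gset@amplitudes[, od]
    if (!length(amps) || max(amps) < responseFloor || max(amps) <= 0)
      return(data.frame(odorant = od, roi_id = NA_integer_,
                        x = NA_real_, y = NA_real_, projection = NA_real_,
                        present = FALSE))
    i <- which.max(amps)
    data.frame(odorant = od, roi_id = gset@rois$id[i],
               x = gset@rois$x[i], y = gset@rois$y[i],
               projection = gset@rois$x[i] * ax[1L] + gset@rois$y[i] * ax[2L],
               present = TRUE)
  })
  tab <- do.call(rbind, rows)
  p <- tab$projection[tab$present]
  monotone <- length(p) >= 2L &&
    (all(diff(p) >= 0) || all(diff(p) <= 0))
  list(table = tab, monotone = monotone)
}

#' Concentration-response table over a field of view
#'
#' Counts, at each concentration, the ROIs whose amplitude reaches
#' `responseFloor`, and tabulates per-ROI amplitudes.  In the recordings
#' this emulates, the number of responding glomeruli in matched subregions
#' was consistent across concentrations; consistency is reported, not
#' enforced.
#'
#' @param setsByConc named list mapping concentration (names coercible to
#'   numeric) to [GlomerulusSet]s detected on the same field of view.
#' @param responseFloor amplitude threshold for "responding".
#' @param odorant optional odorant column to use; defaults to each set's
#'   maximum across columns.
#' @return list with `counts` (data.frame: `concentration_pct`,
#'   `n_responding`, `n_rois`) and `amplitudes` (long data.frame:
#'   `concentration_pct`, `roi_id`, `amplitude`).
#' @export
concentrationResponse <- function(setsByConc, responseFloor,
                                  odorant = NULL) {
  stopifnot(length(setsByConc) >= 1L, !is.null(names(setsByConc)))
  dims <- unique(vapply(setsByConc, function(g)
    paste(g@frameDim, collapse = "x"), character(1)))
  views <- unique(vapply(setsByConc, function(g) g@view, character(1)))
  if (length(dims) != 1L || length(views) != 1L)
    stop("glomerulus sets must come from the same field of view")
  concs <- as.numeric(names(setsByConc))
  roiAmp <- function(g) {
    if (!nrow(g@rois)) return(numeric(0))
    if (is.null(odorant)) apply(g@amplitudes, 1L, max)
    else g@amplitudes[, odorant]
  }
  counts <- do.call(rbind, lapply(seq_along(setsByConc), function(i) {
    a <- roiAmp(setsByConc[[i]])
    data.frame(concentration_pct = concs[i],
               n_responding = sum(a >= responseFloor),
               n_rois = length(a))
  }))
  amplitudes <- do.call(rbind, lapply(seq_along(setsByConc), function(i) {
    g <- setsByConc[[i]]; a <- roiAmp(g)
    if (!length(a)) return(NULL)
    data.frame(concentration_pct = concs[i], roi_id = g@rois$id,
               amplitude = a)
  }))
  list(counts = counts, amplitudes = amplitudes)
}
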