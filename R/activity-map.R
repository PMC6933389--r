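#' Average time-aligned trials
#'
#' Shifts each trial's frame axis so that all alignment anchors coincide
#' and averages the overlapping frame range pixel-wise.  Averaging is done
#' on raw (bleach-corrected) intensities, *before* any dF/F0 computation.
#' The output movie's anchor frame is the smallest input anchor; its
#' length is the largest range covered by every shifted trial.
#'
#' @param trials list of [Trial] objects sharing frame rate and frame
#'   shape, with `anchorFrame` set (see [findAlignmentAnchor()]).
#' @return list with `movie` (the averaged [Movie]), `anchorFrame`
#'   (0-based) and `nTrials`.
#' @export
averageAlignedTrials <- function(trials) {
  if (!length(trials)) stop("empty trial set")
  stopifnot(all(vapply(trials, is, logical(1), "Trial")))
  anchors <- vapply(trials, function(tr) tr@anchorFrame, integer(1))
  if (anyNA(anchors))
    stop("all trials need a computed anchorFrame before averaging")
  fs <- unique(vapply(trials, function(tr) frameRate(tr@movie), numeric(1)))
  dims <- unique(t(vapply(trials, function(tr) frameDim(tr@movie),
                          integer(2))))
  if (length(fs) != 1L || nrow(dims) != 1L)
    stop("trials must share frame rate and frame shape")
  shifts <- anchors - min(anchors)
  lens <- vapply(trials, function(tr) nFrames(tr@movie), integer(1)) - shifts
  L <- min(lens)
  if (L < 1L)
    stop("aligned trials have no overlapping frame range")
  acc <- NULL
  for (i in seq_along(trials)) {
    part <- movieData(trials[[i]]@movie)[, , (shifts[i] + 1L):(shifts[i] + L),
                                         drop = FALSE]
    acc <- if (is.null(acc)) part else acc + part
  }
  list(movie = Movie(acc / length(trials), frameRateHz = fs,
                     pixelSizeUm = trials[[1L]]@movie@pixelSizeUm),
       anchorFrame = min(anchors), nTrials = length(trials))
}

#' Compute a dF/F0 activity map
#'
#' The response image R is the mean of `round(responseS * rate)` frames
#' starting at the anchor (200 frames, 1.6 s, at 125 Hz); the baseline
#' image B is the mean of the frames from `baselineFromS` to `baselineToS`
#' before the anchor (half-open window: 125 frames, 1.0 s, for 1.4-0.4 s
#' at 125 Hz).  The map is `(R - B) / B` elementwise.  Pixels whose
#' baseline falls below a positivity floor (1% of the movie's global
#' median) are set to 0 and flagged.
#'
#' @param movie the trial-averaged [Movie].
#' @param anchorFrame 0-based anchor frame.
#' @param responseS response-window length, seconds.
#' @param baselineFromS,baselineToS baseline window bounds, seconds before
#'   the anchor.
#' @param odorant,concentrationPct,nTrials,view provenance metadata.
#' @return an [ActivityMap].
#' @export
computeActivityMap <- function(movie, anchorFrame, responseS = 1.6,
                               baselineFromS = 1.4, baselineToS = 0.4,
                               odorant = NA_character_,
                               concentrationPct = NA_real_,
                               nTrials = 1L, view = "dorsal") {
  stopifnot(is(movie, "Movie"), baselineFromS > baselineToS,
            responseS > 0)
  a <- movieData(movie)
  fs <- frameRate(movie)
  Tn <- dim(a)[3L]
  anchorFrame <- as.integer(anchorFrame)
  nResp <- framesIn(responseS, fs)
  bFrom <- framesIn(baselineFromS, fs)
  bTo <- framesIn(baselineToS, fs)
  b0 <- anchorFrame - bFrom            # 0-based, inclusive
  b1 <- anchorFrame - bTo - 1L         # 0-based, inclusive (half-open at -bTo)
  r0 <- anchorFrame                    # anchor frame included
  r1 <- anchorFrame + nResp - 1L
  if (b0 < 0L)
    stop("baseline window starts before the movie (frame ", b0, " < 0)")
  if (r1 >= Tn)
    stop("response window ends past the movie (frame ", r1, " >= ", Tn, ")")

  R <- rowMeans(a[, , (r0 + 1L):(r1 + 1L), drop = FALSE], dims = 2L)
  B <- rowMeans(a[, , (b0 + 1L):(b1 + 1L), drop = FALSE], dims = 2L)
  floorB <- 0.01 * stats::median(a)
  flagged <- B < floorB
  vals <- (R - B) / B
  vals[flagged] <- 0
  new("ActivityMap", values = vals, odorant = odorant,
      concentrationPct = concentrationPct, nTrials = as.integer(nTrials),
      anchorFrame = anchorFrame, responseFrames = nResp,
      baselineFrames = bFrom - bTo, view = view, flipped = FALSE,
      flagged = flagged)
}

#' Run the full per-stimulus mapping pipeline on a trial set
#'
#' Bleach-corrects each trial (optionally), drops trials excluded for
#' block noise, detects breath events, anchors each trial to the first
#' inhalation onset after its stimulus, averages the aligned raw movies
#' and computes the dF/F0 map.
#'
#' @param trials list of [Trial] objects sharing odorant and concentration.
#' @param correctBleach apply [bleachCorrect()] first (default `TRUE`).
#' @param view view label for the resulting map.
#' @param blockSize,headFrames,tailFrames,excludeThreshold passed to
#'   [bleachCorrect()].
#' @param ... passed to [computeActivityMap()] (window parameters).
#' @return list with `map` (an [ActivityMap]), `reports` (per-trial
#'   [CorrectionReport]s or `NULL`), `excluded` (logical per trial) and
#'   `anchorFrames`.
#' @export
computeTrialSetMap <- function(trials, correctBleach = TRUE,
                               view = "dorsal", blockSize = 4L,
                               headFrames = 480L, tailFrames = 5L,
                               excludeThreshold = 2, ...) {
  if (!length(trials)) stop("empty trial set")
  odorant <- unique(vapply(trials, function(tr) tr@odorant, character(1)))
  conc <- unique(vapply(trials, function(tr) tr@concentrationPct, numeric(1)))
  if (length(odorant) != 1L || length(conc) != 1L)
    stop("trials must share odorant and concentration")
  reports <- vector("list", length(trials))
  excluded <- logical(length(trials))
  for (i in seq_along(trials)) {
    if (correctBleach) {
      bc <- bleachCorrect(trials[[i]]@movie, blockSize = blockSize,
                          headFrames = headFrames, tailFrames = tailFrames,
                          excludeThreshold = excludeThreshold)
      trials[[i]]@movie <- bc$movie
      reports[[i]] <- bc$report
      excluded[i] <- bc$report@excluded
    }
    ev <- detectBreathEvents(trials[[i]]@breath)
    anchor <- findAlignmentAnchor(ev, trials[[i]]@onsetS,
                                  frameRate(trials[[i]]@movie))
    trials[[i]]@anchorFrame <- as.integer(anchor$anchor_frame)
  }
  kept <- trials[!excluded]
  if (!length(kept)) stop("all trials excluded for block noise")
  avg <- averageAlignedTrials(kept)
  map <- computeActivityMap(avg$movie, avg$anchorFrame, odorant = odorant,
                            concentrationPct = conc,
                            nTrials = length(kept), view = view, ...)
  list(map = map, reports = reports, excluded = excluded,
       anchorFrames = vapply(trials, function(tr) tr@anchorFrame,
                             integer(1)))
}

#' Summarize a map over a set of ROIs
#'
#' @param map an [ActivityMap].
#' @param gset a [GlomerulusSet] on the same frame.
#' @return data.frame with one row per ROI: `id`, `n_pixels`, `mean_dff`
#'   (mean dF/F0 over the ROI mask; `NA` and `empty = TRUE` for empty
#'   masks).
#' @export
mapSummary <- function(map, gset) {
  stopifnot(is(map, "ActivityMap"), is(gset, "GlomerulusSet"))
  if (!identical(dim(mapValues(map)), as.integer(gset@frameDim)))
    stop("ROI set frame does not match the map")
  vals <- mapValues(map)
  out <- lapply(seq_along(gset@masks), function(i) {
    px <- gset@masks[[i]]
    data.frame(id = gset@rois$id[i], n_pixels = length(px),
               mean_dff = if (length(px)) mean(vals[px]) else NA_real_,
               empty = !length(px))
  })
  do.call(rbind, out)
}
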