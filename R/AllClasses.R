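#' @import methods
NULL

#' Movie: a fluorescence image time series
#'
#' A `Movie` holds a single-trial widefield recording as an H x W x T array
#' of intensities together with its acquisition metadata.  Frame `n`
#' (0-based in the time mapping) is sampled at `t = n / frameRate(x)`
#' seconds; R array indexing is 1-based, so frame `n` lives at
#' `movieData(x)[, , n + 1]`.
#'
#' @slot data numeric array, `H x W x T`.
#' @slot frameRateHz frame rate in Hz.
#' @slot pixelSizeUm pixel pitch in micrometres.
#' @export
setClass("Movie",
  representation(
    data = "array",
    frameRateHz = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("Movie", function(object) {
  if (length(dim(object@data)) != 3L)
    return("movie data must be an H x W x T array")
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    return("frameRateHz must be a single positive number")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' BreathTrace: a sampled respiration signal
#'
#' Piezo-like chest-movement signal sampled on the same clock as the movie.
#' Inhalation onsets and ends (seconds) are empty until filled by the
#' generator (ground truth) or by [detectBreathEvents()].
#'
#' @slot samples numeric vector of sensor values.
#' @slot sampleRateHz sampling rate in Hz.
#' @slot inhalationOnsetsS sorted inhalation-onset times, seconds.
#' @slot inhalationEndsS sorted inhalation-end times, seconds; end `k` falls
#'   between onsets `k` and `k + 1`.
#' @export
setClass("BreathTrace",
  representation(
    samples = "numeric",
    sampleRateHz = "numeric",
    inhalationOnsetsS = "numeric",
    inhalationEndsS = "numeric"
  ),
  prototype(inhalationOnsetsS = numeric(0), inhalationEndsS = numeric(0))
)

setValidity("BreathTrace", function(object) {
  if (length(object@sampleRateHz) != 1L || object@sampleRateHz <= 0)
    return("sampleRateHz must be a single positive number")
  on <- object@inhalationOnsetsS
  if (is.unsorted(on, strictly = TRUE) && length(on) > 1L)
    return("inhalation onsets must be strictly increasing")
  en <- object@inhalationEndsS
  if (length(en) > length(on))
    return("more inhalation ends than onsets")
  if (length(en) && any(en <= on[seq_along(en)]))
    return("every inhalation end must follow its onset")
  TRUE
})

#' MapSpec: ground-truth layout of a glomerular map
#'
#' Describes the glomeruli of one view (dorsal surface, or medial wall seen
#' through the prism) for the synthetic generator: positions, sizes and a
#' per-odorant peak dF/F0 tuning matrix.  For the medial view,
#' `flipApplied = TRUE` means the layout is stored as the camera sees it
#' through the mirror prism, i.e. dorso-ventrally inverted, and
#' `apOffsetPx` is the anterior-posterior shift introduced by prism
#' placement.
#'
#' @slot glomeruli data.frame with columns `x`, `y` (pixel centres, 0-based),
#'   `radius` (Gaussian sigma is `radius / 2`).
#' @slot tuning numeric matrix, glomeruli x odorants, peak windowed dF/F0
#'   per odorant (column names are the odorant panel).
#' @slot view `"dorsal"` or `"medial"`.
#' @slot apOffsetPx integer anterior-posterior offset in pixels.
#' @slot flipApplied logical; see above.
#' @slot frameDim integer `(H, W)` the layout is defined on.
#' @export
setClass("MapSpec",
  representation(
    glomeruli = "data.frame",
    tuning = "matrix",
    view = "character",
    apOffsetPx = "integer",
    flipApplied = "logical",
    frameDim = "integer"
  )
)

setValidity("MapSpec", function(object) {
  g <- object@glomeruli
  if (!all(c("x", "y", "radius") %in% names(g)))
    return("glomeruli must have columns x, y, radius")
  if (nrow(g) != nrow(object@tuning))
    return("tuning must have one row per glomerulus")
  if (any(g$radius <= 0)) return("radii must be positive")
  if (any(object@tuning < 0)) return("tuning amplitudes must be >= 0")
  H <- object@frameDim[1L]; W <- object@frameDim[2L]
  if (any(g$x < 0 | g$x > W - 1 | g$y < 0 | g$y > H - 1))
    return("all glomerulus centres must lie within the frame")
  if (!object@view %in% c("dorsal", "medial"))
    return("view must be 'dorsal' or 'medial'")
  TRUE
})

#' Trial: one stimulus presentation
#'
#' Bundles the movie, the breath trace, the stimulus descriptor, the actual
#' stimulus onset and (once computed) the alignment anchor.  Synthetic
#' trials also carry their ground truth.
#'
#' @slot movie a [Movie].
#' @slot breath a [BreathTrace].
#' @slot odorant odorant label.
#' @slot concentrationPct nominal concentration (percent of saturated vapour).
#' @slot onsetS actual stimulus onset, seconds.
#' @slot anchorFrame integer frame index (0-based) of the first inhalation
#'   onset after the stimulus; `NA` until computed.
#' @slot truth list of ground-truth values for synthetic trials (empty for
#'   real data).
#' @export
setClass("Trial",
  representation(
    movie = "Movie",
    breath = "BreathTrace",
    odorant = "character",
    concentrationPct = "numeric",
    onsetS = "numeric",
    anchorFrame = "integer",
    truth = "list"
  ),
  prototype(anchorFrame = NA_integer_, truth = list())
)

#' ActivityMap: a trial-averaged dF/F0 image
#'
#' @slot values H x W matrix of dF/F0 (dimensionless).
#' @slot odorant odorant label.
#' @slot concentrationPct nominal concentration.
#' @slot nTrials number of trials averaged.
#' @slot anchorFrame 0-based anchor frame of the averaged movie.
#' @slot responseFrames number of frames in the response window.
#' @slot baselineFrames number of frames in the baseline window.
#' @slot view `"dorsal"` or `"medial"`.
#' @slot flipped logical, whether the vertical (dorso-ventral) un-flip has
#'   been applied to a medial map.
#' @slot flagged logical H x W matrix marking pixels whose baseline fell
#'   below the positivity floor (rendered 0).
#' @export
setClass("ActivityMap",
  representation(
    values = "matrix",
    odorant = "character",
    concentrationPct = "numeric",
    nTrials = "integer",
    anchorFrame = "integer",
    responseFrames = "integer",
    baselineFrames = "integer",
    view = "character",
    flipped = "logical",
    flagged = "matrix"
  ),
  prototype(flipped = FALSE, concentrationPct = NA_real_)
)

setValidity("ActivityMap", function(object) {
  if (!identical(dim(object@values), dim(object@flagged)))
    return("flagged mask must match the map dimensions")
  if (!object@view %in% c("dorsal", "medial"))
    return("view must be 'dorsal' or 'medial'")
  TRUE
})

#' GlomerulusSet: detected ROIs with per-odorant amplitudes
#'
#' @slot rois data.frame with columns `id`, `x`, `y` (weighted centroid,
#'   0-based pixels), `peak` (composite peak height).
#' @slot masks list of integer vectors; pixel indices (into the H x W frame)
#'   of each disk ROI.  Masks are disjoint.
#' @slot amplitudes numeric matrix ROIs x odorants of mean dF/F0 per map.
#' @slot view `"dorsal"` or `"medial_flipped"`.
#' @slot frameDim integer `(H, W)`.
#' @export
setClass("GlomerulusSet",
  representation(
    rois = "data.frame",
    masks = "list",
    amplitudes = "matrix",
    view = "character",
    frameDim = "integer"
  )
)

setValidity("GlomerulusSet", function(object) {
  if (nrow(object@rois) != length(object@masks))
    return("one mask per ROI required")
  if (nrow(object@rois) != nrow(object@amplitudes))
    return("one amplitude row per ROI required")
  if (length(object@masks) > 1L) {
    all_px <- unlist(object@masks)
    if (anyDuplicated(all_px)) return("ROI masks must be disjoint")
  }
  TRUE
})

#' Registration: flip + anterior-posterior shift between views
#'
#' @slot flipAxis always `"horizontal"` (rows reversed, dorso-ventral).
#' @slot apShiftPx integer shift along the anterior-posterior (column) axis
#'   maximizing normalized cross-correlation: dorsal column `c` matches
#'   flipped-medial column `c + apShiftPx`.
#' @slot score normalized cross-correlation at the optimum, in `[-1, 1]`.
#' @export
setClass("Registration",
  representation(
    flipAxis = "character",
    apShiftPx = "integer",
    score = "numeric"
  ),
  prototype(flipAxis = "horizontal")
)

setValidity("Registration", function(object) {
  if (!is.na(object@score) && (object@score < -1 - 1e-9 || object@score > 1 + 1e-9))
    return("score must lie in [-1, 1]")
  TRUE
})

#' CorrectionReport: diagnostics of a bleach correction
#'
#' @slot fits data.frame of per-block exponential fits (`row`, `col` block
#'   indices, `amplitude`, `tau_s`, `offset`, `rss`, `converged`).
#' @slot blockNoiseScore block-boundary artifact score of the corrected
#'   movie (about 1 for seamless images).
#' @slot excluded logical; `TRUE` when the score exceeds the threshold and
#'   the trial should be dropped from averaging.
#' @slot threshold the exclusion threshold applied.
#' @slot nSkippedPixels pixels left uncorrected (non-positive first frame).
#' @export
setClass("CorrectionReport",
  representation(
    fits = "data.frame",
    blockNoiseScore = "numeric",
    excluded = "logical",
    threshold = "numeric",
    nSkippedPixels = "integer"
  )
)
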