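#' @rdname Movie-class
setMethod("movieData", "Movie", function(x) x@data)

#' @rdname Movie-class
setMethod("frameRate", "Movie", function(x) x@frameRateHz)

#' @rdname Movie-class
setMethod("nFrames", "Movie", function(x) dim(x@data)[3L])

#' @rdname Movie-class
setMethod("frameDim", "Movie", function(x) dim(x@data)[1:2])

#' @rdname BreathTrace-class
setMethod("frameRate", "BreathTrace", function(x) x@sampleRateHz)

#' @rdname BreathTrace-class
setMethod("inhalationOnsets", "BreathTrace", function(x) x@inhalationOnsetsS)

#' @rdname BreathTrace-class
setMethod("inhalationEnds", "BreathTrace", function(x) x@inhalationEndsS)

#' @rdname ActivityMap-class
setMethod("mapValues", "ActivityMap", function(x) x@values)

#' @rdname GlomerulusSet-class
setMethod("rois", "GlomerulusSet", function(x) x@rois)

#' @rdname GlomerulusSet-class
setMethod("roiAmplitudes", "GlomerulusSet", function(x) x@amplitudes)

setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf("Movie: %d x %d px, %d frames @ %.5g Hz (%.3g s), %.3g um/px\n",
              d[1], d[2], d[3], object@frameRateHz,
              d[3] / object@frameRateHz, object@pixelSizeUm))
})

setMethod("show", "BreathTrace", function(object) {
  cat(sprintf("BreathTrace: %d samples @ %.5g Hz (%.3g s), %d inhalation onsets\n",
              length(object@samples), object@sampleRateHz,
              length(object@samples) / object@sampleRateHz,
              length(object@inhalationOnsetsS)))
})

setMethod("show", "MapSpec", function(object) {
  cat(sprintf("MapSpec (%s view%s): %d glomeruli, %d odorants, A-P offset %d px\n",
              object@view, if (object@flipApplied) ", flip applied" else "",
              nrow(object@glomeruli), ncol(object@tuning), object@apOffsetPx))
})

setMethod("show", "Trial", function(object) {
  cat(sprintf("Trial: odorant %s @ %.3g%%, stimulus onset %.3f s, anchor frame %s\n",
              object@odorant, object@concentrationPct, object@onsetS,
              ifelse(is.na(object@anchorFrame), "not set",
                     as.character(object@anchorFrame))))
  show(object@movie)
})

setMethod("show", "ActivityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ActivityMap (%s%s): %d x %d px, odorant %s, n = %d trials, peak dF/F0 = %.4f\n",
    object@view, if (object@flipped) ", flipped" else "",
    d[1], d[2], object@odorant, object@nTrials, max(object@values)))
})

setMethod("show", "GlomerulusSet", function(object) {
  cat(sprintf("GlomerulusSet (%s): %d ROIs, %d odorants\n",
              object@view, nrow(object@rois), ncol(object@amplitudes)))
})

setMethod("show", "Registration", function(object) {
  cat(sprintf("Registration: %s flip, A-P shift %d px, NCC score %.3f\n",
              object@flipAxis, object@apShiftPx, object@score))
})

setMethod("show", "CorrectionReport", function(object) {
  cat(sprintf(
    "CorrectionReport: %d blocks (%d converged), block-noise score %.3f (threshold %.2f) -> %s\n",
    nrow(object@fits), sum(object@fits$converged), object@blockNoiseScore,
    object@threshold, if (object@excluded) "EXCLUDED" else "kept"))
})

#' Construct a Movie
#'
#' @param data numeric H x W x T array of intensities.
#' @param frameRateHz frame rate in Hz (default 125, the acquisition rate
#'   of the recordings the pipeline targets).
#' @param pixelSizeUm pixel pitch in micrometres (default 1750/128, a
#'   1.75 x 1.75 mm field of view on 128 x 128 pixels).
#' @return a [Movie].
#' @export
Movie <- function(data, frameRateHz = 125, pixelSizeUm = 1750 / 128) {
  new("Movie", data = data, frameRateHz = frameRateHz,
      pixelSizeUm = pixelSizeUm)
}

#' Construct a BreathTrace
#'
#' @param samples numeric vector of piezo sensor values.
#' @param sampleRateHz sampling rate in Hz.
#' @param inhalationOnsetsS,inhalationEndsS optional event times (seconds),
#'   e.g. generator ground truth.
#' @return a [BreathTrace].
#' @export
BreathTrace <- function(samples, sampleRateHz,
                        inhalationOnsetsS = numeric(0),
                        inhalationEndsS = numeric(0)) {
  new("BreathTrace", samples = as.numeric(samples),
      sampleRateHz = sampleRateHz,
      inhalationOnsetsS = inhalationOnsetsS,
      inhalationEndsS = inhalationEndsS)
}
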