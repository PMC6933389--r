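#' Acquisition parameters for the synthetic generator
#'
#' Defaults reproduce the recording geometry the pipeline targets: 13 s
#' trials at 125 Hz (1,625 frames), 128 x 128 pixels covering a
#' 1.75 x 1.75 mm^2 field of view.  Photobleaching is modeled as a
#' multiplicative mono-exponential loss, `1 - bleachFraction * (1 -
#' exp(-t / bleachTauS))`, optionally with per-quadrant tau scaling to make
#' the bleaching spatially heterogeneous; sensor noise is additive Gaussian
#' per pixel and frame.
#'
#' @param frameRateHz frame rate, Hz.
#' @param nFrames frames per trial; must equal
#'   `framesIn(durationS, frameRateHz)` for the implied duration.
#' @param frameDim integer `(H, W)` in pixels.
#' @param pixelSizeUm pixel pitch, micrometres.
#' @param bleachTauS bleaching time constant, seconds.
#' @param bleachFraction fraction of initial intensity lost as t -> Inf,
#'   in `[0, 1)`.
#' @param noiseSd additive Gaussian noise SD, intensity counts.
#' @param baselineLevel resting fluorescence at the field centre, counts.
#' @param quadrantTauScale length-4 multiplicative tau scaling for the
#'   (top-left, top-right, bottom-left, bottom-right) quadrants; all 1 for
#'   spatially homogeneous bleaching.
#' @param seed optional integer seed for the noise draw.
#' @return a validated list of class `"AcquisitionSpec"`.
#' @export
AcquisitionSpec <- function(frameRateHz = 125, nFrames = 1625,
                            frameDim = c(128L, 128L),
                            pixelSizeUm = 1750 / 128,
                            bleachTauS = 5, bleachFraction = 0.2,
                            noiseSd = 5, baselineLevel = 1000,
                            quadrantTauScale = c(1, 1, 1, 1),
                            seed = NULL) {
  stopifnot(frameRateHz > 0, nFrames >= 1, length(frameDim) == 2L,
            all(frameDim >= 1), pixelSizeUm > 0, bleachTauS > 0,
            bleachFraction >= 0, bleachFraction < 1, noiseSd >= 0,
            baselineLevel > 0, length(quadrantTauScale) == 4L,
            all(quadrantTauScale > 0))
  structure(list(
    frameRateHz = frameRateHz, nFrames = as.integer(nFrames),
    frameDim = as.integer(frameDim), pixelSizeUm = pixelSizeUm,
    bleachTauS = bleachTauS, bleachFraction = bleachFraction,
    noiseSd = noiseSd, baselineLevel = baselineLevel,
    quadrantTauScale = quadrantTauScale, seed = seed
  ), class = "AcquisitionSpec")
}

#' Respiration parameters for the synthetic generator
#'
#' The piezo chest signal is modeled as a positive sine inhalation lobe
#' followed by a negative sine exhalation lobe scaled so each cycle has
#' zero mean.  Ground-truth inhalation onsets/ends are the upward/downward
#' zero crossings of the noiseless waveform.  The ~2 Hz default is in the
#' range typical of urethane-anesthetized mice.
#'
#' @param rateHz nominal breathing rate, Hz.
#' @param dutyInhale inhaled fraction of each cycle, in (0, 1).
#' @param jitterSdS SD of the cycle-to-cycle period jitter, seconds.
#' @param amplitude waveform amplitude, arbitrary sensor units.
#' @param noiseSd additive sensor noise SD, as a fraction of `amplitude`.
#' @param seed optional integer seed.
#' @return a validated list of class `"BreathSpec"`.
#' @export
BreathSpec <- function(rateHz = 2, dutyInhale = 0.35, jitterSdS = 0.02,
                       amplitude = 1, noiseSd = 0.05, seed = NULL) {
  stopifnot(rateHz > 0, dutyInhale > 0, dutyInhale < 1, jitterSdS >= 0,
            amplitude > 0, noiseSd >= 0)
  structure(list(rateHz = rateHz, dutyInhale = dutyInhale,
                 jitterSdS = jitterSdS, amplitude = amplitude,
                 noiseSd = noiseSd, seed = seed),
            class = "BreathSpec")
}

#' Stimulus protocol descriptor
#'
#' A 2 s odor pulse whose command onset is synchronized to the end of an
#' inhalation (so odorant is never delivered mid-inhalation), after a
#' prestimulus baseline of at least 4 s.
#'
#' @param odorant odorant label (e.g. `"5CHO"`).
#' @param nominalConcentrationPct nominal concentration, percent of
#'   saturated vapour (see [nominalConcentration()]).
#' @param requestedOnsetS requested command onset, seconds.
#' @param durationS odor-pulse duration, seconds.
#' @param minPrestimulusS minimum prestimulus baseline, seconds.
#' @return a validated list of class `"StimulusSpec"`.
#' @export
StimulusSpec <- function(odorant, nominalConcentrationPct = 0.2,
                         requestedOnsetS = 5, durationS = 2,
                         minPrestimulusS = 4) {
  stopifnot(is.character(odorant), length(odorant) == 1L,
            nominalConcentrationPct >= 0, durationS > 0,
            requestedOnsetS >= 0, minPrestimulusS >= 0)
  structure(list(odorant = odorant,
                 nominalConcentrationPct = nominalConcentrationPct,
                 requestedOnsetS = requestedOnsetS, durationS = durationS,
                 minPrestimulusS = minPrestimulusS),
            class = "StimulusSpec")
}
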