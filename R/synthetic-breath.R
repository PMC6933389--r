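#' Generate a synthetic respiration trace with ground-truth events
#'
#' Emits a piezo-like chest signal: each breathing cycle is a positive sine
#' inhalation lobe of duration `dutyInhale / rateHz` followed by a negative
#' sine exhalation lobe scaled so the cycle integrates to zero.  Cycle
#' periods jitter independently (SD `jitterSdS`, floored at half the
#' nominal period).  Ground-truth inhalation onsets and ends are the upward
#' and downward zero crossings of the noiseless waveform and are returned
#' on the trace.
#'
#' @param spec a [BreathSpec()].
#' @param durationS trace duration, seconds (> 0).
#' @param sampleRateHz sampling rate, Hz; defaults to 125, the movie clock.
#' @return a [BreathTrace] with ground-truth events filled in.
#' @export
generateBreathTrace <- function(spec, durationS, sampleRateHz = 125) {
  stopifnot(inherits(spec, "BreathSpec"), durationS > 0, sampleRateHz > 0)
  if (spec$rateHz * durationS < 2)
    stop("trace must cover at least 2 breathing cycles")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  P <- 1 / spec$rateHz
  d <- spec$dutyInhale * P
  # one virtual cycle before t = 0 so early samples fall in an exhalation
  onsets <- 0.25 * P - P
  while (onsets[length(onsets)] < durationS + P) {
    dt <- P + stats::rnorm(1, 0, spec$jitterSdS)
    onsets <- c(onsets, onsets[length(onsets)] + max(dt, 0.5 * P))
  }

  n <- as.integer(roundHalfAway(durationS * sampleRateHz))
  t <- frameTimes(n, sampleRateHz)
  k <- findInterval(t, onsets)
  t0 <- onsets[k]
  gap <- onsets[k + 1L] - t0 - d
  phase <- t - t0
  A <- spec$amplitude
  inhale <- phase < d
  v <- numeric(n)
  v[inhale] <- A * sin(pi * phase[inhale] / d)
  r <- d / gap[!inhale]  # zero-mean scaling of the exhalation lobe
  v[!inhale] <- -A * r * sin(pi * (phase[!inhale] - d) / gap[!inhale])
  if (spec$noiseSd > 0)
    v <- v + stats::rnorm(n, 0, spec$noiseSd * A)

  keep <- onsets >= 0 & onsets < durationS
  ends <- onsets + d
  BreathTrace(v, sampleRateHz,
              inhalationOnsetsS = onsets[keep],
              inhalationEndsS = ends[onsets >= 0 & ends <= durationS])
}

#' Schedule the stimulus command onset on an inhalation end
#'
#' The odor command is synchronized to the end of an inhalation so odorant
#' is never delivered in the middle of an inhalation: the actual onset is
#' the first inhalation end at or after
#' `max(requestedOnsetS, minPrestimulusS)`.
#'
#' @param spec a [StimulusSpec()].
#' @param breath a [BreathTrace] whose inhalation ends are filled in
#'   (generator ground truth or [detectBreathEvents()] output).
#' @return actual stimulus onset, seconds.
#' @export
scheduleStimulus <- function(spec, breath) {
  stopifnot(inherits(spec, "StimulusSpec"), is(breath, "BreathTrace"))
  ends <- inhalationEnds(breath)
  if (!length(ends)) stop("breath trace has no inhalation ends")
  target <- max(spec$requestedOnsetS, spec$minPrestimulusS)
  cand <- ends[ends >= target]
  if (!length(cand))
    stop("no inhalation end at or after ", signif(target, 4),
         " s before the end of the trace")
  cand[1L]
}
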