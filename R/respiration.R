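#' Detect inhalation onsets and ends on a breath trace
#'
#' The piezo signal is boxcar-smoothed, detrended by subtracting a rolling
#' baseline, and inhalation onsets are marked at upward zero crossings of
#' the detrended signal (ends at the subsequent downward crossings).  A
#' refractory period `minCycleS` suppresses onsets that follow another
#' onset too closely.  Detection is invariant to positive rescaling of the
#' trace; `polarity` handles piezo mounting sign (`"auto"` flips the trace
#' when its large excursions are predominantly negative).
#'
#' @param trace a [BreathTrace] (any pre-existing events are replaced).
#' @param smoothingS boxcar smoothing width, seconds (default 40 ms).
#' @param minCycleS refractory period between onsets, seconds (default
#'   150 ms).
#' @param baselineS rolling-baseline window, seconds (default 1 s).
#' @param polarity `"auto"`, `"pos"` (signal rises on inhalation) or
#'   `"neg"`.
#' @return the trace with `inhalationOnsetsS` / `inhalationEndsS` filled.
#' @export
detectBreathEvents <- function(trace, smoothingS = 0.04, minCycleS = 0.15,
                               baselineS = 1, polarity = c("auto", "pos", "neg")) {
  stopifnot(is(trace, "BreathTrace"))
  polarity <- match.arg(polarity)
  fs <- trace@sampleRateHz
  x <- trace@samples
  if (polarity == "neg") x <- -x
  if (polarity == "auto") {
    dev <- x - stats::median(x)
    if (abs(stats::quantile(dev, 0.01)) > abs(stats::quantile(dev, 0.99)))
      x <- -x
  }
  s <- boxcarSmooth(x, roundHalfAway(smoothingS * fs))
  s <- s - boxcarSmooth(s, roundHalfAway(baselineS * fs))

  up <- which(s[-length(s)] <= 0 & s[-1L] > 0) + 1L   # first positive sample
  down <- which(s[-length(s)] > 0 & s[-1L] <= 0) + 1L # first non-positive
  if (!length(up)) stop("no inhalation events found in the breath trace")

  # refractory enforcement on onsets
  refr <- minCycleS * fs
  keep <- up[1L]
  for (i in up[-1L]) if (i - keep[length(keep)] >= refr) keep <- c(keep, i)
  onsets <- keep

  # end = first downward crossing after each onset and before the next one
  nxt <- c(onsets[-1L], length(s) + 1L)
  ends <- vapply(seq_along(onsets), function(i) {
    d <- down[down > onsets[i] & down < nxt[i]]
    if (length(d)) d[1L] else NA_integer_
  }, integer(1))
  ok <- !is.na(ends)
  # drop trailing onsets without an end only from the end list (validity
  # allows fewer ends than onsets); interior onsets without a downward
  # crossing cannot occur since the next onset requires s <= 0 before it
  trace@inhalationOnsetsS <- (onsets - 1L) / fs
  trace@inhalationEndsS <- (ends[ok] - 1L) / fs
  validObject(trace)
  trace
}

#' Find the trial-alignment anchor
#'
#' All imaging data are aligned to the onset of the first inhalation cycle
#' after the stimulus presentation: the anchor is the earliest detected
#' inhalation onset at or after `stimulusOnsetS`, and the anchor frame is
#' `round(anchor_time * frame rate)` (half away from zero).
#'
#' @param trace a [BreathTrace] with events detected.
#' @param stimulusOnsetS actual stimulus onset, seconds.
#' @param frameRateHz movie frame rate, Hz.
#' @return list with `anchor_time_s` and `anchor_frame` (0-based).
#' @examples
#' tr <- BreathTrace(numeric(0), 125, inhalationOnsetsS = c(4.5, 5.1, 5.6))
#' findAlignmentAnchor(tr, 5.0, 125)$anchor_frame  # 638
#' @export
findAlignmentAnchor <- function(trace, stimulusOnsetS, frameRateHz) {
  stopifnot(is(trace, "BreathTrace"), frameRateHz > 0)
  onsets <- inhalationOnsets(trace)
  if (!length(onsets))
    stop("no inhalation onsets on the trace; run detectBreathEvents() first")
  cand <- onsets[onsets >= stimulusOnsetS]
  if (!length(cand))
    stop("no inhalation onset at or after the stimulus onset (",
         signif(stimulusOnsetS, 4), " s)")
  anchor <- cand[1L]
  list(anchor_time_s = anchor,
       anchor_frame = timeToFrame(anchor, frameRateHz))
}
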