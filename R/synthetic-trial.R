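#' Calcium-indicator impulse kernel
#'
#' Double-exponential GCaMP6f-like transient, `exp(-t/decay) -
#' exp(-t/rise)` for `t >= 0`, with a 0.05 s rise and 0.6 s decay by
#' default.  The generator normalizes the sampled kernel so that its mean
#' over the analysis response window is exactly 1; a glomerulus' tuning
#' amplitude is therefore *defined* as the windowed dF/F0 it produces,
#' independent of the kernel shape.
#'
#' @param t_s times since transient onset, seconds (values < 0 give 0).
#' @param riseS,decayS rise and decay time constants, seconds.
#' @return kernel values (unnormalized).
#' @export
calciumKernel <- function(t_s, riseS = 0.05, decayS = 0.6) {
  stopifnot(riseS > 0, decayS > riseS)
  k <- exp(-t_s / decayS) - exp(-t_s / riseS)
  k[t_s < 0] <- 0
  k
}

# radially vignetted resting-fluorescence field (15% falloff at the corner)
baselineField <- function(frameDim, level) {
  H <- frameDim[1L]; W <- frameDim[2L]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  r2 <- outer(((seq_len(H) - 1) - cy)^2, ((seq_len(W) - 1) - cx)^2, "+")
  level * (1 - 0.15 * r2 / max(r2))
}

# sum of Gaussian blobs scaled by per-glomerulus amplitudes
responseField <- function(map, amplitudes) {
  H <- map@frameDim[1L]; W <- map@frameDim[2L]
  R <- matrix(0, H, W)
  g <- map@glomeruli
  ygrid <- seq_len(H) - 1; xgrid <- seq_len(W) - 1
  for (i in seq_len(nrow(g))) {
    if (amplitudes[i] <= 0) next
    s2 <- (g$radius[i] / 2)^2
    R <- R + amplitudes[i] *
      outer(exp(-(ygrid - g$y[i])^2 / (2 * s2)),
            exp(-(xgrid - g$x[i])^2 / (2 * s2)))
  }
  R
}

# per-quadrant bleaching factors; returns function(rows, cols) -> T-vector
quadrantTau <- function(frameDim, tauS, scale) {
  H <- frameDim[1L]; W <- frameDim[2L]
  halfR <- ceiling(H / 2); halfC <- ceiling(W / 2)
  list(
    rows = list(1:halfR, 1:halfR, (halfR + 1):H, (halfR + 1):H),
    cols = list(1:halfC, (halfC + 1):W, 1:halfC, (halfC + 1):W),
    tau = tauS * scale
  )
}

#' Hill-type concentration scaling
#'
#' Saturating scaling of glomerular response amplitude with nominal
#' concentration, normalized to 1 at the reference concentration so tuning
#' amplitudes are calibrated at `refPct`.
#'
#' @param concPct nominal concentration, percent.
#' @param refPct reference concentration at which scaling is 1.
#' @param kPct half-saturation concentration, percent.
#' @return scaling factor.
#' @export
hillScale <- function(concPct, refPct = 0.2, kPct = 0.01) {
  stopifnot(concPct >= 0, refPct > 0, kPct > 0)
  (concPct / (concPct + kPct)) / (refPct / (refPct + kPct))
}

#' Render one synthetic trial
#'
#' Forward model: `F(x, t) = F0(x) * (1 + R(x) * k(t)) * B(x, t) + noise`,
#' where `F0` is a smooth resting-fluorescence field, `R` the sum of
#' glomerular Gaussian blobs scaled by their tuning amplitude for the
#' stimulated odorant (Hill-scaled by concentration), `k` the calcium
#' kernel triggered at the first ground-truth inhalation onset after the
#' stimulus onset (normalized so its mean over the response window is 1),
#' and `B(x, t) = 1 - bleachFraction * (1 - exp(-t / tau))` the
#' photobleaching factor (tau optionally per quadrant).  In the noiseless,
#' bleach-free case the windowed dF/F0 at a blob centre equals the spec
#' tuning amplitude.
#'
#' @param map a [MapSpec].
#' @param acq an [AcquisitionSpec()].
#' @param breath a [BreathTrace] with ground-truth events.
#' @param stim a [StimulusSpec()].
#' @param onsetS actual stimulus onset from [scheduleStimulus()].
#' @param responseWindowS response-window length used to calibrate the
#'   kernel, seconds.
#' @return a [Trial] whose `truth` records the effective per-glomerulus
#'   amplitudes, bleach parameters, inhalation events, anchor and layout.
#' @export
renderTrial <- function(map, acq, breath, stim, onsetS,
                        responseWindowS = 1.6) {
  stopifnot(is(map, "MapSpec"), inherits(acq, "AcquisitionSpec"),
            is(breath, "BreathTrace"), inherits(stim, "StimulusSpec"))
  fs <- acq$frameRateHz
  Tn <- acq$nFrames
  if (length(breath@samples) / breath@sampleRateHz < (Tn - 1) / fs)
    stop("breath trace shorter than the movie")
  if (!is.null(acq$seed)) set.seed(acq$seed)

  onsets <- inhalationOnsets(breath)
  after <- onsets[onsets >= onsetS]
  if (!length(after)) stop("no inhalation onset after the stimulus onset")
  anchorS <- after[1L]
  anchorFrame <- timeToFrame(anchorS, fs)

  t <- frameTimes(Tn, fs)
  k0 <- calciumKernel(t - anchorS)
  nResp <- framesIn(responseWindowS, fs)
  respIdx <- (anchorFrame + 1L):(anchorFrame + nResp)
  if (anchorFrame + nResp > Tn) {
    warning("calcium kernel window extends past the end of the trial; ",
            "truncating")
    respIdx <- respIdx[respIdx <= Tn]
  }
  k <- k0 / mean(k0[respIdx])

  if (!stim$odorant %in% colnames(map@tuning))
    stop("odorant '", stim$odorant, "' not in the map's tuning panel")
  amps <- map@tuning[, stim$odorant] *
    hillScale(stim$nominalConcentrationPct)
  F0 <- baselineField(acq$frameDim, acq$baselineLevel)
  R <- responseField(map, amps)

  H <- acq$frameDim[1L]; W <- acq$frameDim[2L]
  mov <- array(0, c(H, W, Tn))
  q <- quadrantTau(acq$frameDim, acq$bleachTauS, acq$quadrantTauScale)
  for (i in 1:4) {
    rr <- q$rows[[i]]; cc <- q$cols[[i]]
    B <- 1 - acq$bleachFraction * (1 - exp(-t / q$tau[i]))
    mov[rr, cc, ] <- outer(F0[rr, cc], B) + outer(F0[rr, cc] * R[rr, cc], k * B)
  }
  if (acq$noiseSd > 0)
    mov <- mov + array(stats::rnorm(length(mov), 0, acq$noiseSd), dim(mov))

  truth <- list(
    amplitudes = unname(amps),
    centers = map@glomeruli[, c("x", "y")],
    radiusPx = map@glomeruli$radius,
    view = map@view, apOffsetPx = map@apOffsetPx,
    flipApplied = map@flipApplied,
    bleach = list(fraction = acq$bleachFraction, tauS = acq$bleachTauS,
                  quadrantTauScale = acq$quadrantTauScale),
    inhalationOnsetsS = onsets,
    inhalationEndsS = inhalationEnds(breath),
    stimulusOnsetS = onsetS,
    anchorTimeS = anchorS, anchorFrame = anchorFrame
  )
  new("Trial",
      movie = Movie(mov, frameRateHz = fs, pixelSizeUm = acq$pixelSizeUm),
      breath = breath, odorant = stim$odorant,
      concentrationPct = stim$nominalConcentrationPct,
      onsetS = onsetS, anchorFrame = NA_integer_, truth = truth)
}

#' Simulate a set of trials for one stimulus
#'
#' Generates `nTrials` trials of the same odorant and concentration with
#' independent breathing jitter and sensor noise, mirroring the repeated
#' presentations (3-4 trials) that are averaged into one activity map.
#'
#' @param map a [MapSpec].
#' @param acq an [AcquisitionSpec()]; its `seed` field is ignored here.
#' @param breathSpec a [BreathSpec()]; its `seed` field is ignored here.
#' @param stim a [StimulusSpec()].
#' @param nTrials number of trials (default 4).
#' @param seed integer seed governing the whole set.
#' @return list of [Trial] objects.
#' @export
simulateTrialSet <- function(map, acq, breathSpec, stim, nTrials = 4,
                             seed = NULL) {
  stopifnot(nTrials >= 1)
  if (!is.null(seed)) set.seed(seed)
  acq$seed <- NULL
  breathSpec$seed <- NULL
  durationS <- acq$nFrames / acq$frameRateHz
  lapply(seq_len(nTrials), function(i) {
    breath <- generateBreathTrace(breathSpec, durationS,
                                  sampleRateHz = acq$frameRateHz)
    onset <- scheduleStimulus(stim, breath)
    renderTrial(map, acq, breath, stim, onset)
  })
}
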