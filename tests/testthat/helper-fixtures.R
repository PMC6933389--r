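# Shared fixture builders. Small frames / short movies keep unit tests
# fast; the acceptance tests run the full-size study conditions.

tinyAcq <- function(...) {
  AcquisitionSpec(frameDim = c(32L, 32L), ...)
}

# a movie whose every frame is the given matrix (or constant)
constantMovie <- function(value, dim = c(8L, 8L), nFrames = 30L,
                          frameRateHz = 125) {
  fr <- if (is.matrix(value)) value else matrix(value, dim[1L], dim[2L])
  Movie(array(fr, c(nrow(fr), ncol(fr), nFrames)), frameRateHz = frameRateHz)
}

# breath trace with prescribed events and no samples (for anchor logic)
eventTrace <- function(onsets, ends = numeric(0), fs = 125) {
  BreathTrace(numeric(0), fs, inhalationOnsetsS = onsets,
              inhalationEndsS = ends)
}

# one-blob map spec on a small frame
oneBlobMap <- function(x = 16, y = 12, radius = 4, amplitude = 0.05,
                       odorant = "5CHO", dim = c(32L, 32L)) {
  tun <- matrix(amplitude, 1L, 1L, dimnames = list(NULL, odorant))
  new("MapSpec", glomeruli = data.frame(x = x, y = y, radius = radius),
      tuning = tun, view = "dorsal", apOffsetPx = 0L, flipApplied = FALSE,
      frameDim = as.integer(dim))
}

# minimal Trial wrapper around a movie for alignment tests
bareTrial <- function(movie, anchorFrame, odorant = "test", conc = 0.2) {
  new("Trial", movie = movie,
      breath = BreathTrace(numeric(0), frameRate(movie)),
      odorant = odorant, concentrationPct = conc, onsetS = 0,
      anchorFrame = as.integer(anchorFrame), truth = list())
}

# an ActivityMap directly from a matrix
bareMap <- function(values, view = "dorsal", flipped = FALSE,
                    odorant = NA_character_) {
  new("ActivityMap", values = values, odorant = odorant,
      concentrationPct = NA_real_, nTrials = 1L, anchorFrame = 0L,
      responseFrames = 0L, baselineFrames = 0L, view = view,
      flipped = flipped,
      flagged = matrix(FALSE, nrow(values), ncol(values)))
}

# a GlomerulusSet built directly from centroid/amplitude tables
bareGlomSet <- function(x, y, amplitudes, view = "dorsal",
                        frameDim = c(64L, 64L)) {
  n <- length(x)
  amplitudes <- as.matrix(amplitudes)
  peak <- if (n) apply(amplitudes, 1L, max) else numeric(0)
  new("GlomerulusSet",
      rois = data.frame(id = seq_len(n), x = x, y = y, peak = peak),
      masks = as.list(seq_len(n)),  # disjoint single-pixel placeholders
      amplitudes = amplitudes, view = view,
      frameDim = as.integer(frameDim))
}
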