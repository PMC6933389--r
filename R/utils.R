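# Round half away from zero (base round() rounds half to even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Frame (0-based) <-> time mapping: frame n is sampled at t = n / rate.
timeToFrame <- function(t_s, rateHz) as.integer(roundHalfAway(t_s * rateHz))

frameTimes <- function(n, rateHz) (seq_len(n) - 1) / rateHz

# Centered boxcar smoothing with edge shrinkage (partial windows at the
# ends instead of NA padding).
boxcarSmooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  n <- length(x)
  num <- stats::filter(c(rep(0, width), x, rep(0, width)), k, sides = 2)
  den <- stats::filter(c(rep(0, width), rep(1, n), rep(0, width)), k, sides = 2)
  as.numeric(num / den)[(width + 1):(width + n)]
}
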