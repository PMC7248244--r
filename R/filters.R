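# Zero-phase band shaping.
#
# One primitive serves both the LFP synthesizer (imposing per-band PD vs
# non-PD amplitude differences) and the modulating network (imposing
# stimulation-frequency-dependent gains). It is realized in the frequency
# domain with an exponential gain law: the amplitude response is
#   R(f) = prod_k g_k ^ w_k(f)
# with w_k a trapezoidal band weight (1 inside band k, linear transitions of
# `trans_hz` outside). Exponential weighting makes shaping multiplicative in
# the gains — shape(g1) followed by shape(g2) is exactly shape(g1 * g2) at
# every frequency, including where overlapping bands stack — which is what
# makes the modulation calibration exact: driving the gains of a PD signal
# to the non-PD gain values reproduces the non-PD spectrum bin by bin.
# The response is real and even, hence zero-phase.

# The default transition width (0.5 Hz) is narrow enough that each band's
# weight is exactly 1 at its own center and exactly 0 at the other band's
# center for the 5 Hz / 3 Hz-step band layout, so band-center oscillations
# are scaled by exactly their own band's gain.

# trapezoidal band weight at frequencies f (Hz)
band_weight <- function(f, band, trans_hz = 0.5) {
  up <- (f - (band[1] - trans_hz)) / trans_hz
  dn <- ((band[2] + trans_hz) - f) / trans_hz
  pmin(1, pmax(0, pmin(up, dn)))
}

# mirror-extend x by np samples on each side (period-2(n-1) reflection)
reflect_pad <- function(x, np) {
  n <- length(x)
  idx <- function(i) {
    j <- ((i - 1) %% (2L * (n - 1L)))
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  c(x[idx(seq(np + 1L, 2L, by = -1L))], x, x[idx(seq(n - 1L, n - np, by = -1L))])
}

# apply per-band amplitude gains to a signal (zero-phase, exponential law)
shape_bands <- function(x, bands, gains, sample_rate, trans_hz = 0.5,
                        pad_s = 1) {
  stopifnot(length(bands) == length(gains))
  if (all(gains == 1)) return(x)
  n <- length(x)
  np <- min(as.integer(round(pad_s * sample_rate)), n - 1L)
  xp <- reflect_pad(x, np)
  m <- length(xp)
  # frequency of each DFT bin, folded to [0, fs/2]
  k <- 0:(m - 1L)
  f <- pmin(k, m - k) * sample_rate / m
  logR <- 0
  for (b in seq_along(bands))
    logR <- logR + band_weight(f, bands[[b]], trans_hz) * log(gains[b])
  y <- Re(stats::fft(stats::fft(xp) * exp(logR), inverse = TRUE)) / m
  y[(np + 1L):(np + n)]
}

# amplitude response of the band shaping at frequencies f (Hz)
shape_response <- function(f, bands, gains, trans_hz = 0.5) {
  logR <- 0
  for (b in seq_along(bands))
    logR <- logR + band_weight(f, bands[[b]], trans_hz) * log(gains[b])
  exp(logR)
}
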