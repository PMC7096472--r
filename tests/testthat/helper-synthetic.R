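# Shared fixtures: tiny protocols and model-generated series built in code.

flat_protocol <- function(duration = 60, mean_rr = 1000, lf = 0, hf = 0,
                          scr_rate = 0, scr_amp = 0, tonic = 1, seed = 1L,
                          transition_s = 0) {
  protocol_spec(data.frame(label = "rest", duration = duration,
                           mean_rr = mean_rr, lf_amp = lf, hf_amp = hf,
                           scr_rate = scr_rate, scr_amp = scr_amp,
                           tonic_level = tonic),
                seed = seed, transition_s = transition_s)
}

# Stationary inverse-Gaussian renewal heartbeat series.
renewal_series <- function(n = 600, mu = 0.8, lambda = 50, seed = 1L,
                           t0 = 10) {
  with_seed(seed, {
    rr <- rinvgauss(n, mu, lambda)
    heartbeat_series(cumsum(c(t0, rr)))
  })
}

# Resample an RR sequence onto a regular grid (for Welch checks).
rr_resampled <- function(beats, fs = 4) {
  rr <- diff(beats)
  tt <- beats[-1]
  grid <- seq(min(tt), max(tt), by = 1 / fs)
  approx(tt, rr, xout = grid)$y
}

# Simple Welch PSD used as an independent spectral oracle in tests.
welch_psd <- function(x, fs, nseg = 8L) {
  n <- length(x)
  lseg <- 2^floor(log2(2 * n / (nseg + 1)))
  step <- lseg %/% 2L
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(lseg) - 1) / (lseg - 1))  # Hann
  u <- sum(w^2)
  starts <- seq(1L, n - lseg + 1L, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + lseg - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + abs(fft(seg * w))^2 / (fs * u)
  }
  p <- acc / length(starts)
  f <- (seq_len(lseg) - 1) * fs / lseg
  keep <- f <= fs / 2
  list(f = f[keep], p = p[keep])
}
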