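#' @useDynLib svbalance, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median optimize quantile rbinom rexp rgamma
#'   rlnorm rnorm rpois runif sd spline splinefun var complete.cases pnorm
#'   setNames acf mad
#' @importFrom utils head read.csv tail write.csv modifyList
NULL

abort <- function(...) stop(..., call. = FALSE)

check_that <- function(cond, msg) if (!isTRUE(cond)) abort(msg)

#' Seeded evaluation helper
#'
#' Runs `expr` under a local RNG state seeded with `seed`, restoring the
#' caller's RNG state afterwards. Used throughout so a single global seed
#' expands into reproducible substreams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit substream seed from (seed, counter).
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647
  as.integer(s)
}

# Blackman window (symmetric), n points.
blackman <- function(n) {
  check_that(n >= 1, "window length must be >= 1")
  k <- seq_len(n) - 1L
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

# Hamming-windowed sinc FIR low-pass, cutoff in cycles/sample, odd length.
fir_lowpass <- function(cutoff, n_taps = 65L) {
  check_that(cutoff > 0 && cutoff < 0.5, "cutoff must be in (0, 0.5) cycles/sample")
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  k <- seq(-m, m)
  h <- 2 * cutoff * sinc(2 * cutoff * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Band-pass by difference of two low-pass designs.
fir_bandpass <- function(low, high, n_taps = 65L) {
  check_that(low < high, "band edges out of order")
  fir_lowpass(high, n_taps) - fir_lowpass(low, n_taps)
}

# Zero-phase FIR filtering via central convolution with edge padding.
filter_zero_phase <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1L) %/% 2L
  xp <- c(rep(x[1], m), x, rep(x[n], m))
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  as.numeric(y[(m + 1L):(m + n)])
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Linear convolution via FFT (full length).
conv_fft <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  re <- fft(fft(c(x, rep(0, nf - length(x)))) *
            fft(c(y, rep(0, nf - length(y)))), inverse = TRUE) / nf
  Re(re)[seq_len(n)]
}
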