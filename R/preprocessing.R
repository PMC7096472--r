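#' R-peak detection (Pan-Tompkins-style)
#'
#' Classic cascade: band-pass (default 5-15 Hz) -> derivative -> squaring ->
#' moving-window integration (150 ms) -> adaptive dual-threshold peak
#' picking with a 200 ms refractory period. Detected fiducials are refined
#' to the local maximum of the raw ECG within +/- 40 ms.
#'
#' @param ecg numeric ECG samples.
#' @param rate sampling rate, Hz (>= 100).
#' @param band band-pass edges (Hz).
#' @param refractory refractory period (s).
#' @return object of class `heartbeat_series`: list with `event_times` (s),
#'   `rr` (s, one fewer than beats), `flags` (logical, per beat).
#' @export
detect_r_peaks <- function(ecg, rate, band = c(5, 15), refractory = 0.2) {
  check_that(rate >= 100, "sampling rate must be >= 100 Hz")
  check_that(length(ecg) >= 10 * rate, "recording must be at least 10 s")
  check_that(!anyNA(ecg), "ECG contains NA samples")
  check_that(sd(ecg) > 0, "ECG is flat (zero variance)")
  n <- length(ecg)
  h <- fir_bandpass(band[1] / rate, band[2] / rate,
                    n_taps = max(65L, as.integer(rate %/% 4) * 2L + 1L))
  xf <- filter_zero_phase(ecg, h)
  dx <- c(0, diff(xf)) * rate
  sq <- dx^2
  wlen <- max(3L, round(0.15 * rate))
  mwi <- filter_zero_phase(sq, rep(1 / wlen, wlen))

  refr <- round(refractory * rate)
  # initial thresholds from the first 2 s
  init <- mwi[seq_len(min(n, 2L * round(rate)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  last <- -refr
  i <- 2L
  while (i < n) {
    if (mwi[i] > mwi[i - 1L] && mwi[i] >= mwi[i + 1L]) {  # local max of MWI
      if (mwi[i] > thr1 && (i - last) > refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * mwi[i] + 0.875 * spki
      } else {
        npki <- 0.125 * mwi[i] + 0.875 * npki
      }
      thr1 <- npki + 0.25 * (spki - npki)
    }
    i <- i + 1L
  }
  check_that(length(peaks) >= 2L, "no QRS complexes detected")
  # two-stage refinement: coarse apex on the band-passed signal (in-band
  # noise only), then fine apex on a 40 Hz low-passed copy that keeps the
  # R wave sharp while suppressing broadband noise
  lp <- filter_zero_phase(ecg, fir_lowpass(min(40 / rate, 0.45), 33L))
  half1 <- round(0.06 * rate)
  half2 <- round(0.02 * rate)
  ref <- vapply(peaks, function(p) {
    j0 <- max(1L, p - half1); j1 <- min(n, p + half1)
    c0 <- j0 + which.max(xf[j0:j1]) - 1L
    k0 <- max(1L, c0 - half2); k1 <- min(n, c0 + half2)
    as.integer(k0 + which.max(lp[k0:k1]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # drop refinement collisions closer than the refractory period
  keep <- c(TRUE, diff(ref) > refr)
  ref <- ref[keep]
  times <- (ref - 1L) / rate
  heartbeat_series(times)
}

#' Construct a heartbeat series from beat event times
#' @param event_times strictly increasing R-wave times (s).
#' @param flags optional logical vector marking suspect beats.
#' @return object of class `heartbeat_series`.
#' @export
heartbeat_series <- function(event_times, flags = NULL) {
  check_that(length(event_times) >= 2L, "need at least 2 beats")
  check_that(all(diff(event_times) > 0), "event times must be strictly increasing")
  if (is.null(flags)) flags <- rep(FALSE, length(event_times))
  check_that(length(flags) == length(event_times), "flags length must equal beats")
  structure(list(event_times = as.numeric(event_times),
                 rr = diff(event_times), flags = flags),
            class = "heartbeat_series")
}

#' @export
print.heartbeat_series <- function(x, ...) {
  cat(sprintf("<heartbeat_series> %d beats over %.1f s, mean RR %.0f ms, %d flagged\n",
              length(x$event_times), diff(range(x$event_times)),
              mean(x$rr) * 1000, sum(x$flags)))
  invisible(x)
}

#' RR artifact correction by local-median flagging and spline interpolation
#'
#' Beats whose RR interval deviates more than `threshold` (fraction) from
#' the running median (window `window` beats) are flagged; flagged RR values
#' are replaced by cubic-spline interpolation through the accepted RR
#' values, and event times are rebuilt by cumulative summation from the
#' first beat.
#'
#' @param series a `heartbeat_series`.
#' @param threshold relative deviation triggering correction (default 0.25;
#'   1 disables correction entirely).
#' @param window local-median window in beats (odd, default 11).
#' @return corrected `heartbeat_series` with `flags` marking replaced beats
#'   and attribute `fraction_corrected`.
#' @export
correct_rr_artifacts <- function(series, threshold = 0.25, window = 11L) {
  check_that(inherits(series, "heartbeat_series"), "series must be a heartbeat_series")
  rr <- series$rr
  check_that(length(rr) >= 9L, "need at least 10 beats")
  if (threshold >= 1) {                 # a 100% threshold disables flagging
    out <- heartbeat_series(series$event_times, flags = rep(FALSE, length(rr) + 1L))
    attr(out, "fraction_corrected") <- 0
    return(out)
  }
  med <- stats::runmed(rr, k = min(window, 2L * (length(rr) %/% 2L) - 1L),
                       endrule = "median")
  bad <- abs(rr - med) > threshold * med
  if (all(bad)) abort("all beats flagged as artifacts")
  frac <- mean(bad)
  if (frac > 0.2)
    warning(sprintf("%.1f%% of beats flagged as artifacts", 100 * frac))
  rr2 <- rr
  if (any(bad)) {
    idx <- seq_along(rr)
    sf <- splinefun(idx[!bad], rr[!bad], method = "natural")
    rr2[bad] <- sf(idx[bad])
  }
  times <- series$event_times[1] + c(0, cumsum(rr2))
  out <- heartbeat_series(times, flags = c(FALSE, bad))
  attr(out, "fraction_corrected") <- frac
  out
}

#' Normalize and downsample an EDA series
#'
#' Anti-alias low-pass filtering, decimation to `target_rate` (default
#' 50 Hz), then a Z-score over the whole recording, yielding a
#' dimensionless series with zero mean and unit variance.
#'
#' @param eda numeric samples, or a list with `samples` and `rate`.
#' @param rate input sampling rate (Hz, >= 50); ignored when `eda` carries
#'   its own.
#' @param target_rate output rate (Hz).
#' @return object of class `eda_series`: list with `samples`, `rate`,
#'   `t`, and the `center`/`scale` used by the Z-score.
#' @export
preprocess_eda <- function(eda, rate = NULL, target_rate = 50) {
  if (is.list(eda)) { rate <- eda$rate; eda <- eda$samples }
  check_that(!is.null(rate) && rate >= target_rate,
             "input rate must be >= the 50 Hz target")
  check_that(!anyNA(eda), "EDA contains NA samples")
  s <- sd(eda)
  check_that(s > 0, "zero-variance EDA: Z-score undefined")
  factor <- rate / target_rate
  if (abs(factor - round(factor)) < 1e-9 && round(factor) > 1L) {
    k <- as.integer(round(factor))
    h <- fir_lowpass(0.4 / k, n_taps = 16L * k + 1L)
    xf <- filter_zero_phase(eda, h)
    x <- xf[seq(1L, length(xf), by = k)]
  } else if (abs(factor - 1) < 1e-9) {
    x <- eda
  } else {
    # non-integer factor: filter then linear resample
    h <- fir_lowpass(0.4 * target_rate / rate, n_taps = 129L)
    xf <- filter_zero_phase(eda, h)
    t_in <- (seq_along(eda) - 1L) / rate
    t_out <- seq(0, t_in[length(t_in)], by = 1 / target_rate)
    x <- approx(t_in, xf, xout = t_out)$y
  }
  ctr <- mean(x); scl <- sd(x)
  check_that(scl > 0, "zero-variance EDA after decimation")
  z <- (x - ctr) / scl
  structure(list(samples = z, rate = target_rate,
                 t = (seq_along(z) - 1L) / target_rate,
                 center = ctr, scale = scl),
            class = "eda_series")
}
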