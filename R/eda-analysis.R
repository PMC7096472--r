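#' Time-frequency plane of an EDA series
#'
#' Sliding 60 s Blackman-windowed segments with 59 s overlap (1 s hop);
#' within each segment a Welch periodogram (default four 50%-overlapped
#' Blackman sub-windows, zero-padded for <= 0.01 Hz frequency resolution).
#' Power is scaled as a one-sided PSD so that integrating over frequency
#' recovers the segment variance (window-gain corrected).
#'
#' @param eda an `eda_series` (50 Hz, Z-scored) or list with `samples`,
#'   `rate`.
#' @param window_s segment length (s), default 60.
#' @param hop_s hop between segments (s), default 1 (= 59 s overlap).
#' @param n_sub number of Welch sub-windows per segment (default 4,
#'   50% overlap).
#' @param fmax highest frequency retained (Hz), default 0.6.
#' @param df_max maximum frequency spacing (Hz), default 0.01.
#' @return object of class `tf_plane`: `t` (segment centers, s), `f` (Hz),
#'   `power` (time x frequency, PSD units 1/Hz).
#' @export
eda_time_frequency <- function(eda, window_s = 60, hop_s = 1, n_sub = 4L,
                               fmax = 0.6, df_max = 0.01) {
  rate <- eda$rate; x <- eda$samples
  check_that(!is.null(rate), "eda must carry its sampling rate")
  nwin <- round(window_s * rate)
  check_that(length(x) >= nwin, "recording shorter than the 60 s analysis window")
  hop <- round(hop_s * rate)
  nsub <- max(1L, as.integer(n_sub))
  lsub <- if (nsub == 1L) nwin else floor(2L * nwin / (nsub + 1L))
  step <- if (nsub == 1L) nwin else floor(lsub / 2L)
  w <- blackman(lsub)
  u <- sum(w^2)                               # window energy
  nfft <- 2^ceiling(log2(rate / df_max))
  nfft <- max(nfft, 2L * lsub)
  f <- (0:(nfft %/% 2L)) * rate / nfft
  keep <- f <= fmax
  f <- f[keep]

  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  P <- matrix(0, length(starts), length(f))
  for (si in seq_along(starts)) {
    seg <- x[starts[si]:(starts[si] + nwin - 1L)]
    acc <- numeric(length(f))
    for (k in seq_len(nsub)) {
      i0 <- (k - 1L) * step + 1L
      sub <- seg[i0:(i0 + lsub - 1L)] * w
      sp <- abs(fft(c(sub, rep(0, nfft - lsub))))^2 / (rate * u)
      sp <- sp[seq_along(keep)][keep]
      acc <- acc + sp
    }
    acc <- acc / nsub
    # one-sided scaling (DC and Nyquist not doubled)
    dbl <- f > 0 & f < rate / 2
    acc[dbl] <- 2 * acc[dbl]
    P[si, ] <- acc
  }
  structure(list(t = (starts - 1L) / rate + window_s / 2, f = f, power = P,
                 window_s = window_s, hop_s = hop_s, n_sub = nsub),
            class = "tf_plane")
}

#' Spectral sympathetic index EDAsymp
#'
#' Per-step trapezoidal integral of the EDA time-frequency plane over the
#' sympathetic band (default 0.045-0.25 Hz). Units are normalized power of
#' the Z-scored EDA (dimensionless), one value per 1 s step.
#'
#' @param plane a `tf_plane`.
#' @param band two-element band (Hz).
#' @return data.frame with `t` (s) and `edasymp`.
#' @export
compute_edasymp <- function(plane, band = c(0.045, 0.25)) {
  check_that(inherits(plane, "tf_plane"), "plane must be a tf_plane")
  check_that(band[1] >= min(plane$f) - 1e-12 && band[2] <= max(plane$f) + 1e-12,
             "band outside the time-frequency grid")
  keep <- plane$f >= band[1] - 1e-12 & plane$f <= band[2] + 1e-12
  vals <- apply(plane$power[, keep, drop = FALSE], 1L,
                function(p) trapz(plane$f[keep], p))
  data.frame(t = plane$t, edasymp = pmax(vals, 0))
}

#' Tonic/phasic decomposition of skin conductance
#'
#' Sparse non-negative deconvolution: solves
#' \deqn{\min_{d \ge 0,\; b} \; \tfrac12\|y - K d - S b\|^2 + \lambda_1 \|d\|_1}
#' where K is the Bateman-kernel convolution operator and S a coarse-knot
#' cubic B-spline basis for the tonic level. Alternates closed-form tonic
#' updates with FISTA (non-negative soft-thresholding) for the driver.
#'
#' @param eda an `eda_series` or list with `samples`, `rate`.
#' @param tau0,tau1 Bateman time constants (s).
#' @param lambda1 sparsity weight; default 0.1 (L-curve choice on generator
#'   data, fixed).
#' @param knot_s tonic spline knot spacing (s), default 20.
#' @param n_outer,n_fista iteration controls.
#' @param peak_threshold minimum driver amplitude for a significant SCR
#'   peak (default 0.05, normalized units).
#' @return object of class `scr_decomposition`: `t`, `tonic`, `phasic`,
#'   `driver` (>= 0), `peaks` (data.frame time/amplitude of significant
#'   driver peaks with phasic amplitudes), `residual` (relative L2),
#'   `lambda1`.
#' @export
decompose_scr <- function(eda, tau0 = 0.7, tau1 = 3.0, lambda1 = 0.1,
                          knot_s = 20, n_outer = 8L, n_fista = 150L,
                          peak_threshold = 0.05) {
  rate <- eda$rate; y <- eda$samples
  n <- length(y)
  check_that(n >= 30 * rate, "need at least 30 s of EDA")
  kern <- bateman_kernel(seq(0, min(40, n / rate), by = 1 / rate), tau0, tau1)
  kern <- kern / max(kern)           # unit-peak kernel: driver in amplitude units
  nf <- stats::nextn(n + length(kern), 2)
  Kf <- fft(c(kern, rep(0, nf - length(kern))))
  convK <- function(v, flt) {
    Re(fft(fft(c(v, rep(0, nf - length(v)))) * flt, inverse = TRUE))[seq_len(n)] / nf
  }
  Kd <- function(d) convK(d, Kf)                    # K d
  Ktd <- function(r) rev(convK(rev(r), Kf))         # K' r (correlation)
  L <- max(abs(Kf))^2                               # Lipschitz bound for K'K

  tt <- (seq_len(n) - 1L) / rate
  nk <- max(4L, ceiling(n / rate / knot_s))
  S <- splines::bs(tt, df = nk + 3L, intercept = TRUE)
  Sqr <- qr(S)

  d <- numeric(n)
  tonic <- numeric(n)
  for (outer in seq_len(n_outer)) {
    tonic <- as.numeric(S %*% qr.coef(Sqr, y - Kd(d)))
    r0 <- y - tonic
    z <- d; tk <- 1
    for (it in seq_len(n_fista)) {
      g <- Ktd(Kd(z) - r0)
      dn <- pmax(z - (g + lambda1) / L, 0)
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- dn + ((tk - 1) / tk1) * (dn - d)
      tk <- tk1
      d <- dn
    }
  }
  # debias: non-negative least-squares refit restricted to the recovered
  # support (projected gradient, lambda1 = 0), removing lasso shrinkage
  supp <- d > 0
  if (any(supp)) {
    r0 <- y - tonic
    for (it in seq_len(n_fista)) {
      g <- Ktd(Kd(d) - r0)
      d <- pmax(d - g / L, 0)
      d[!supp] <- 0
    }
  }
  phasic <- Kd(d)
  resid <- sqrt(sum((y - tonic - phasic)^2) / max(sum(y^2), 1e-12))

  # significant driver peaks: local maxima of d above threshold, merged
  # within a 1 s refractory window
  pk <- which(d > peak_threshold &
                d >= c(-Inf, d[-n]) & d > c(d[-1], -Inf))
  if (length(pk) > 1L) {
    keep <- logical(length(pk)); keep[1] <- TRUE
    last <- pk[1]
    for (i in 2:length(pk)) {
      if ((pk[i] - last) > rate) { keep[i] <- TRUE; last <- pk[i] }
      else if (d[pk[i]] > d[last]) { keep[which(pk == last)] <- FALSE
                                     keep[i] <- TRUE; last <- pk[i] }
    }
    pk <- pk[keep]
  }
  # SCR amplitude: phasic maximum within 5 s after the driver impulse
  amp5 <- vapply(pk, function(i) {
    max(phasic[i:min(n, i + 5L * round(rate))])
  }, numeric(1))
  peaks <- data.frame(time = tt[pk], driver_amp = d[pk], phasic_amp = amp5)
  structure(list(t = tt, rate = rate, tonic = tonic, phasic = phasic,
                 driver = d, peaks = peaks, residual = resid,
                 lambda1 = lambda1, peak_threshold = peak_threshold),
            class = "scr_decomposition")
}

#' @export
print.scr_decomposition <- function(x, ...) {
  cat(sprintf("<scr_decomposition> %.0f s @ %g Hz | %d significant peaks | rel. residual %.3f\n",
              max(x$t), x$rate, nrow(x$peaks), x$residual))
  invisible(x)
}

#' Standard EDA features from a tonic/phasic decomposition
#'
#' Over a time segment: `nscr` = significant driver peaks per minute,
#' `sum_amp_scr` = sum of phasic amplitudes at significant peaks,
#' `phasic_max` = maximum of the phasic component, `tonic` = mean tonic
#' level.
#'
#' @param decomp an `scr_decomposition`.
#' @param segment two-element `c(start, end)` in seconds; default the full
#'   decomposition support.
#' @return named list with `nscr`, `sum_amp_scr`, `phasic_max`, `tonic`.
#' @export
scr_features <- function(decomp, segment = NULL) {
  check_that(inherits(decomp, "scr_decomposition"), "decomp must be an scr_decomposition")
  if (is.null(segment)) segment <- range(decomp$t)
  keep <- decomp$t >= segment[1] & decomp$t <= segment[2]
  check_that(any(keep), "empty segment")
  mins <- (segment[2] - segment[1]) / 60
  inpk <- decomp$peaks$time >= segment[1] & decomp$peaks$time <= segment[2]
  list(nscr = sum(inpk) / mins,
       sum_amp_scr = sum(decomp$peaks$phasic_amp[inpk]),
       phasic_max = max(decomp$phasic[keep]),
       tonic = mean(decomp$tonic[keep]))
}
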