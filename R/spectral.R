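#' Laguerre-to-lag-domain kernel expansion
#'
#' Maps Laguerre coefficients to the lag-domain Volterra kernel acting on
#' past beat-series increments: linear
#' \eqn{a_n = \sum_i g_1(i)\phi_i(n - 1)} and quadratic
#' \eqn{k_2(n, m) = \sum_{ij} g_2(i,j)\phi_i(n - 1)\phi_j(m - 1)} for beat
#' lags \eqn{n \ge 1} (the filter weights the most recent complete
#' increment by \eqn{\phi_i(0)}, so lag-domain index n corresponds to
#' basis index n - 1).
#'
#' @param g coefficient vector (linear) or symmetric matrix (quadratic).
#' @param basis a [laguerre_basis()].
#' @return numeric vector `a[n]`, n = 1..n_mem+1, or matrix `k2[n, m]`.
#' @export
laguerre_to_lag <- function(g, basis) {
  check_that(inherits(basis, "laguerre_basis"), "basis must be a laguerre_basis")
  phi <- basis$phi                       # rows: basis lags 0..n_mem
  if (is.matrix(g)) {
    k <- ncol(g)
    check_that(k <= ncol(phi), "quadratic order exceeds basis order")
    phi[, seq_len(k), drop = FALSE] %*% g %*% t(phi[, seq_len(k), drop = FALSE])
  } else {
    check_that(length(g) <= ncol(phi), "linear order exceeds basis order")
    drop(phi[, seq_along(g), drop = FALSE] %*% g)
  }
}

# Frequency response of a lag-domain kernel a[n], n >= 1, at frequencies f
# (Hz) given sampling interval dt (s): A(f) = sum_n a_n exp(-i 2 pi f n dt).
lag_transfer <- function(a, f, dt) {
  n <- seq_along(a)
  ex <- exp(-2i * pi * outer(f, n) * dt)
  drop(ex %*% a)
}

#' Instantaneous linear power spectrum of the heartbeat model
#'
#' The linear part of the model is an autoregression of the RR series on
#' its own past increments; its theoretical one-sided power spectral
#' density is
#' \deqn{Q(f) = \frac{2\sigma^2\Delta t}{|1 - A(f)|^2},}
#' where \eqn{A(f)} is the transfer function of the lag-domain linear
#' kernel, \eqn{\sigma^2} the inverse-Gaussian interval variance
#' \eqn{\mu^3/\lambda}, and \eqn{\Delta t} the local mean heart period used
#' as the sampling interval of the beat series. Integrating Q over
#' (0, Nyquist) recovers the series variance (Parseval). Powers are
#' reported in ms^2/Hz.
#'
#' @param params list with `g1`, `mu`, `sigma2` (as from [params_at()]), or
#'   a `pp_fit` together with `t`.
#' @param basis a [laguerre_basis()]; defaults to the fit's basis.
#' @param t time at which to evaluate when `params` is a `pp_fit`.
#' @param fgrid frequency grid (Hz); default `seq(0, 0.5, by = 0.002)`.
#' @return list of class `pp_spectrum` with `f`, `Q` (ms^2/Hz), `dt`,
#'   `stable` flag.
#' @export
instantaneous_spectrum <- function(params, basis = NULL, t = NULL,
                                   fgrid = seq(0, 0.5, by = 0.002)) {
  if (inherits(params, "pp_fit")) {
    check_that(!is.null(t), "supply t when passing a pp_fit")
    basis <- if (is.null(basis)) params$basis else basis
    params <- params_at(params, t)
  }
  check_that(!is.null(basis), "a laguerre_basis is required")
  a <- laguerre_to_lag(params$g1, basis)
  dt <- params$mu
  A <- lag_transfer(a, fgrid, dt)
  stable <- ar_stable(a)
  if (!stable)
    warning("AR polynomial root on/inside the unit circle: spectrum flagged unstable")
  sigma2_ms <- params$sigma2 * 1e6  # s^2 -> ms^2
  Q <- 2 * sigma2_ms * dt / abs(1 - A)^2
  structure(list(f = fgrid, Q = Q, dt = dt, stable = stable),
            class = "pp_spectrum")
}

# Stability of 1 - sum_n a_n z^-n: all roots strictly inside unit circle.
ar_stable <- function(a, tol = 1e-6) {
  nz <- which(a != 0)
  if (!length(nz)) return(TRUE)
  a <- a[seq_len(max(nz))]
  rts <- polyroot(c(1, -a))  # roots of 1 - a1 w - a2 w^2 ... (w = z^-1)
  all(Mod(rts) > 1 + tol)
}

#' Integrate a power spectrum over LF/HF bands
#'
#' Trapezoidal band integrals of the instantaneous spectrum; defaults
#' LF = 0.04-0.15 Hz, HF = 0.15-0.4 Hz (band edges are configurable; the
#' HF upper edge is quoted variously as 0.4-0.5 Hz in the HRV literature).
#'
#' @param spec a `pp_spectrum` (or list with `f`, `Q`).
#' @param bands list with `lf` and `hf` two-element vectors (Hz).
#' @return list with `lf`, `hf` (ms^2), `lf_hf` ratio, `bands`.
#' @export
integrate_spectrum <- function(spec, bands = list(lf = c(0.04, 0.15),
                                                  hf = c(0.15, 0.4))) {
  f <- spec$f; Q <- spec$Q
  for (b in bands)
    check_that(b[1] >= min(f) - 1e-12 && b[2] <= max(f) + 1e-12,
               "band outside the spectrum grid")
  band_int <- function(b) {
    keep <- f >= b[1] - 1e-12 & f <= b[2] + 1e-12
    trapz(f[keep], Re(Q[keep]))
  }
  lf <- band_int(bands$lf); hf <- band_int(bands$hf)
  list(lf = lf, hf = hf, lf_hf = if (hf > 0) lf / hf else NA_real_,
       bands = bands)
}

#' Instantaneous magnitude bispectrum of the quadratic heartbeat model
#'
#' For the quadratic Volterra system with linear transfer
#' \eqn{G(f) = 1/(1 - A(f))} and Laguerre-expanded quadratic kernel
#' \eqn{H_2(f_1, f_2)}, the magnitude bispectrum is evaluated as
#' \deqn{|Bis(f_1, f_2)| = 2\sigma^4\,
#'   |G(f_1)\,G(f_2)\,G^*(f_1 + f_2)\, H_2(f_1, f_2)|}
#' on a 2-D frequency grid. A linear (Gaussian) system has zero
#' bispectrum; quadratic phase coupling injected at \eqn{(f_a, f_b)}
#' produces a peak there. The overall normalization constant is this
#' implementation's own fixed convention; magnitudes are comparable within
#' the package (reported in ms^2-scaled units).
#'
#' @param params list with `g1`, `g2`, `mu`, `sigma2`, or a `pp_fit` plus `t`.
#' @param basis a [laguerre_basis()].
#' @param t evaluation time when `params` is a `pp_fit`.
#' @param fgrid frequency grid (Hz) for both axes; default
#'   `seq(0, 0.4, by = 0.005)`.
#' @return list of class `pp_bispectrum` with `f1`, `f2`, `B` (matrix,
#'   |Bis|).
#' @export
instantaneous_bispectrum <- function(params, basis = NULL, t = NULL,
                                     fgrid = seq(0, 0.4, by = 0.005)) {
  if (inherits(params, "pp_fit")) {
    check_that(!is.null(t), "supply t when passing a pp_fit")
    basis <- if (is.null(basis)) params$basis else basis
    params <- params_at(params, t)
  }
  check_that(!is.null(basis), "a laguerre_basis is required")
  check_that(max(fgrid) <= 1 / (2 * params$mu) + 1e-9,
             "frequency grid exceeds the Nyquist of the local beat rate")
  dt <- params$mu
  if (is.null(params$g2) || all(params$g2 == 0)) {
    B <- matrix(0, length(fgrid), length(fgrid))
    return(structure(list(f1 = fgrid, f2 = fgrid, B = B),
                     class = "pp_bispectrum"))
  }
  a <- laguerre_to_lag(params$g1, basis)
  G <- function(f) 1 / (1 - lag_transfer(a, f, dt))
  g1f <- G(fgrid)
  qq <- ncol(params$g2)
  phi <- basis$phi[, seq_len(qq), drop = FALSE]  # basis lags 0.. = AR lags 1..
  n <- seq_len(nrow(phi))
  E <- exp(-2i * pi * outer(fgrid, n) * dt)            # |f| x |n|
  PhiF <- E %*% phi                                    # |f| x qq
  H2 <- PhiF %*% params$g2 %*% t(PhiF)                 # H2(f1, f2)
  fsum <- outer(fgrid, fgrid, "+")
  Gsum <- matrix(G(as.numeric(fsum)), length(fgrid))
  sigma4_ms <- (params$sigma2 * 1e6)^2
  B <- 2 * sigma4_ms * abs(outer(g1f, g1f) * Conj(Gsum) * H2)
  structure(list(f1 = fgrid, f2 = fgrid, B = B), class = "pp_bispectrum")
}

#' Integrate a magnitude bispectrum over the LF/HF quadrants
#'
#' Two-dimensional trapezoidal integrals over
#' LL: (0, 0.15]^2, LH: (0, 0.15] x (0.15, 0.4], HH: (0.15, 0.4]^2.
#'
#' @param bis a `pp_bispectrum`.
#' @param split LF/HF split frequency (default 0.15 Hz).
#' @param top upper band edge (default 0.4 Hz).
#' @return list with `ll`, `lh`, `hh`.
#' @export
integrate_bispectrum <- function(bis, split = 0.15, top = 0.4) {
  f1 <- bis$f1; f2 <- bis$f2
  check_that(max(f1) >= top - 1e-9 && max(f2) >= top - 1e-9,
             "bispectrum grid does not cover the requested bands")
  quad <- function(r1, r2) {
    i1 <- f1 >= r1[1] - 1e-12 & f1 <= r1[2] + 1e-12
    i2 <- f2 >= r2[1] - 1e-12 & f2 <= r2[2] + 1e-12
    g1 <- f1[i1]; g2 <- f2[i2]
    M <- bis$B[i1, i2, drop = FALSE]
    # trapezoid along f2 then f1
    inner <- apply(M, 1L, function(row) trapz(g2, row))
    trapz(g1, inner)
  }
  list(ll = quad(c(0, split), c(0, split)),
       lh = quad(c(0, split), c(split, top)),
       hh = quad(c(split, top), c(split, top)))
}

#' Instantaneous spectral and bispectral index series from a fit
#'
#' Evaluates the model spectrum and bispectrum along a regular clock
#' (default 1 Hz) and integrates them into LF/HF and LL/LH/HH series.
#'
#' @param fit a `pp_fit`.
#' @param clock evaluation times (s); default every 1 s over the fitted
#'   range.
#' @param bands spectral bands as in [integrate_spectrum()].
#' @param fstep frequency resolution (Hz) for both grids.
#' @return data.frame with columns `t`, `mu`, `sigma2`, `lf`, `hf`,
#'   `lf_hf`, `ll`, `lh`, `hh`.
#' @export
pp_index_series <- function(fit, clock = NULL,
                            bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.4)),
                            fstep = 0.005) {
  check_that(inherits(fit, "pp_fit"), "fit must be a pp_fit")
  ok <- which(!is.na(fit$mu))
  check_that(length(ok) > 0L, "fit has no evaluated steps")
  rng <- range(fit$time[ok])
  if (is.null(clock)) clock <- seq(ceiling(rng[1]), floor(rng[2]), by = 1)
  clock <- clock[clock >= rng[1] & clock <= rng[2]]
  fgrid1 <- seq(0, 0.5, by = fstep)
  fgrid2 <- seq(0, 0.4, by = fstep)
  n_unstable <- 0L
  out <- lapply(clock, function(tt) {
    pr <- params_at(fit, tt)
    sp <- withCallingHandlers(
      instantaneous_spectrum(pr, basis = fit$basis, fgrid = fgrid1),
      warning = function(w) {
        n_unstable <<- n_unstable + 1L
        invokeRestart("muffleWarning")
      })
    si <- integrate_spectrum(sp, bands)
    bi <- integrate_bispectrum(
      instantaneous_bispectrum(pr, basis = fit$basis, fgrid = fgrid2))
    data.frame(t = tt, mu = pr$mu, sigma2 = pr$sigma2,
               lf = si$lf, hf = si$hf, lf_hf = si$lf_hf,
               ll = bi$ll, lh = bi$lh, hh = bi$hh)
  })
  if (n_unstable > 0L)
    warning(sprintf("unstable AR polynomial at %d of %d steps", n_unstable,
                    length(clock)))
  do.call(rbind, out)
}
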