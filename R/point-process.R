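#' Fit the inverse-Gaussian point-process heartbeat model
#'
#' Models each RR interval as a draw from an inverse-Gaussian distribution
#' whose mean follows a nonlinear Volterra-Wiener autoregression on past RR
#' increments, expanded on an orthonormal Laguerre basis:
#' \deqn{\mu_{RR}(t) = RR_{\tilde N(t)} + g_0 + \sum_{i=0}^{p} g_1(i)\,l_i
#'   + \sum_{i=0}^{q}\sum_{j=0}^{q} g_2(i,j)\, l_i l_j.}
#' Parameters are tracked along a regular time grid by local weighted
#' maximum likelihood over a trailing window with exponential forgetting,
#' warm-starting each step from the previous one (Newton-Raphson with
#' profiled shape and step-halving).
#'
#' @param series a `heartbeat_series`.
#' @param alpha Laguerre parameter (default 0.2).
#' @param p linear kernel order (default 8).
#' @param q quadratic kernel order; `q = NULL` or negative disables the
#'   quadratic term (default 2).
#' @param window trailing window W in seconds (default 90).
#' @param step time resolution in seconds (default 0.005; analyses at desk
#'   scale typically use a coarser grid, which only subsamples the
#'   trajectory).
#' @param rho per-second forgetting factor (default 0.98).
#' @param max_iter,tol Newton-Raphson controls.
#' @param n_mem Laguerre memory in beats.
#' @return object of class `pp_fit`: the parameter trajectory (`time`,
#'   `mu`, `sigma`, `lambda`, `g0`, `g1`, `g2`), the basis, per-beat model
#'   means (`beat_mu`, `beat_lambda`), and a convergence log.
#' @export
fit_point_process <- function(series, alpha = 0.2, p = 8L, q = 2L,
                              window = 90, step = 0.005, rho = 0.98,
                              max_iter = 20L, tol = 1e-6, n_mem = 60L) {
  check_that(inherits(series, "heartbeat_series"), "series must be a heartbeat_series")
  u <- series$event_times
  total <- u[length(u)] - u[1]
  check_that(total >= window, "recording shorter than the fitting window")
  has_quad <- !is.null(q) && q >= 0L
  qq <- if (has_quad) as.integer(q) else -1L
  ord <- max(p, max(qq, 0L))
  basis <- laguerre_basis(alpha, ord, n_mem = n_mem)
  rr <- series$rr
  n <- length(u)
  check_that(n >= p + max(qq, 0L) + 5L, "too few beats for the requested orders")

  L <- laguerre_filter_series(rr, basis)  # row j: l's for target interval j
  # targets: intervals ending at beats 3..n (need previous RR)
  jidx <- 3:n
  y <- rr[jidx - 1L]          # RR_j = u_j - u_{j-1}
  base <- rr[jidx - 2L]       # RR_{j-1}
  ty <- u[jidx]
  Xlin <- L[jidx - 1L, 1:(p + 1L), drop = FALSE]
  cols <- c("g0", paste0("g1.", 0:p))
  X <- cbind(1, Xlin)
  if (has_quad) {
    Lq <- L[jidx - 1L, 1:(qq + 1L), drop = FALSE]
    for (a in 0:qq) for (b in a:qq) {
      mult <- if (a == b) 1 else 2
      X <- cbind(X, mult * Lq[, a + 1L] * Lq[, b + 1L])
      cols <- c(cols, sprintf("g2.%d.%d", a, b))
    }
  }
  colnames(X) <- cols

  t0 <- u[1]
  tgrid <- seq(t0 + window, u[n], by = step)
  check_that(length(tgrid) >= 1L, "window leaves no evaluation steps")

  theta0 <- numeric(ncol(X))
  theta0[1] <- mean(y) - mean(base)
  lam0 <- mean(y)^3 / max(var(y), 1e-8)
  res <- ppfit_core(ty, y, base, X, tgrid, window, rho,
                    as.integer(max_iter), tol, theta0, lam0)
  frac_nc <- res$n_nonconverged / length(tgrid)
  if (frac_nc > 0.05)
    abort(sprintf("point-process fit failed to converge at %.1f%% of steps",
                  100 * frac_nc))
  mu <- as.numeric(res$mu)
  lam <- as.numeric(res$lambda)
  sigma <- sqrt(pmax(mu, 0)^3 / lam)

  # per-beat parameters: trajectory value at the step just before each beat
  ok <- !is.na(mu)
  beat_mu <- rep(NA_real_, length(jidx))
  beat_lambda <- rep(NA_real_, length(jidx))
  if (any(ok)) {
    idx <- findInterval(ty, tgrid[ok])
    usable <- idx >= 1L
    okpos <- which(ok)
    for (k in which(usable)) {
      th <- res$theta[okpos[idx[k]], ]
      beat_mu[k] <- base[k] + sum(X[k, ] * th)
      beat_lambda[k] <- lam[okpos[idx[k]]]
    }
  }

  structure(list(
    time = tgrid, mu = mu, sigma = sigma, lambda = lam,
    theta = res$theta, theta_names = cols,
    converged = as.logical(res$converged), frac_nonconverged = frac_nc,
    alpha = alpha, p = as.integer(p), q = qq, window = window, step = step,
    rho = rho, basis = basis,
    beat_times = ty, beat_rr = y, beat_mu = beat_mu, beat_lambda = beat_lambda
  ), class = "pp_fit")
}

#' @export
print.pp_fit <- function(x, ...) {
  ok <- !is.na(x$mu)
  cat(sprintf(paste0("<pp_fit> p=%d q=%d alpha=%.2f | %d steps of %g s | ",
                     "mean mu_RR %.0f ms | %.2f%% non-converged\n"),
              x$p, x$q, x$alpha, length(x$time), x$step,
              mean(x$mu[ok]) * 1000, 100 * x$frac_nonconverged))
  invisible(x)
}

# Extract model parameters at (or just before) time t.
params_at <- function(fit, t) {
  check_that(inherits(fit, "pp_fit"), "fit must be a pp_fit")
  ok <- which(!is.na(fit$mu))
  check_that(length(ok) > 0L, "fit has no evaluated steps")
  i <- ok[findInterval(t, fit$time[ok])]
  check_that(length(i) == 1L && !is.na(i) && i >= 1L, "time before first evaluated step")
  th <- fit$theta[i, ]
  names(th) <- fit$theta_names
  g1 <- th[grep("^g1\\.", fit$theta_names)]
  g2 <- matrix(0, max(fit$q, 0L) + 1L, max(fit$q, 0L) + 1L)
  if (fit$q >= 0L) {
    for (a in 0:fit$q) for (b in a:fit$q) {
      v <- th[sprintf("g2.%d.%d", a, b)]
      g2[a + 1L, b + 1L] <- v
      g2[b + 1L, a + 1L] <- v
    }
  }
  list(t = fit$time[i], g0 = th[["g0"]], g1 = unname(g1), g2 = g2,
       lambda = fit$lambda[i], mu = fit$mu[i],
       sigma2 = fit$mu[i]^3 / fit$lambda[i])
}

#' Goodness-of-fit by the time-rescaling theorem
#'
#' Each observed interval is mapped through the fitted conditional
#' distribution, \eqn{z_j = -\log(1 - F(RR_j \mid \mu_j, \lambda_j))};
#' under a correct model the \eqn{z_j} are unit exponential and
#' \eqn{\tau_j = 1 - e^{-z_j}} uniform on (0,1). Reports the KS distance of
#' the \eqn{\tau_j} from uniformity, KS-plot coordinates, the 95% band
#' \eqn{1.36/\sqrt{n}}, and the lag-1..`n_lags` autocorrelation of the
#' transformed intervals.
#'
#' @param fit a `pp_fit`.
#' @param n_lags autocorrelation lags to report.
#' @return list with `ks`, `pass` (logical, 95% band), `band`, `quantiles`
#'   (empirical), `uniform` (model), `tau`, `acf`.
#' @export
ks_goodness_of_fit <- function(fit, n_lags = 20L) {
  check_that(inherits(fit, "pp_fit"), "fit must be a pp_fit")
  ok <- !is.na(fit$beat_mu) & fit$beat_mu > 0
  rr <- fit$beat_rr[ok]
  mu <- fit$beat_mu[ok]
  lam <- fit$beat_lambda[ok]
  n <- length(rr)
  check_that(n >= 20L, "fewer than 20 rescaled intervals: refusing to test")
  tau <- pinvgauss(rr, mu, lam)
  tau <- pmin(pmax(tau, 1e-12), 1 - 1e-12)
  srt <- sort(tau)
  emp <- (seq_len(n) - 0.5) / n
  ks <- max(abs(srt - emp))
  band <- 1.36 / sqrt(n)
  rho <- acf(stats::qnorm(tau), lag.max = n_lags, plot = FALSE)$acf[-1]
  list(ks = ks, pass = ks < band, band = band, n = n,
       quantiles = srt, uniform = emp, tau = tau, acf = as.numeric(rho))
}
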