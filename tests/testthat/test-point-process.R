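test_that("Laguerre basis special values and orthonormality", {
  b0 <- laguerre_basis(0, 0, 10)
  expect_equal(b0$phi[, 1], c(1, rep(0, 10)))
  b <- laguerre_basis(0.2, 9, 500)
  expect_equal(b$phi[1, 1], sqrt(0.8), tolerance = 1e-12)
  G <- crossprod(b$phi)
  expect_lt(max(abs(G - diag(10))), 1e-6)
  expect_error(laguerre_basis(1, 2), "alpha")
  expect_error(laguerre_basis(-0.1, 2), "alpha")
})

test_that("Laguerre filter matches the brute-force summation oracle", {
  b <- laguerre_basis(0.3, 4, 50)
  # constant RR history -> zero increments -> all outputs zero
  expect_equal(laguerre_filter(rep(0, 20), b), rep(0, 5))
  # single increment at history position n0 (basis lag n0 - 1)
  d <- rep(0, 20); d[7] <- 0.05
  expect_equal(laguerre_filter(d, b), 0.05 * b$phi[7, ], tolerance = 1e-12)
  # random history vs direct sum
  set.seed(3)
  d <- rnorm(40, 0, 0.02)
  oracle <- vapply(0:4, function(i)
    sum(b$phi[1:40, i + 1] * d), numeric(1))
  expect_equal(laguerre_filter(d, b), oracle, tolerance = 1e-12)
})

test_that("inverse-Gaussian density, CDF and likelihood behave", {
  q <- integrate(function(x) dinvgauss(x, 0.8, 10), 0, Inf)
  expect_lt(abs(q$value - 1), 1e-6)
  # CDF against numeric quadrature
  for (x0 in c(0.3, 0.8, 2)) {
    num <- integrate(function(x) dinvgauss(x, 0.8, 10), 0, x0)$value
    expect_equal(pinvgauss(x0, 0.8, 10), num, tolerance = 1e-7)
  }
  set.seed(5)
  xs <- rinvgauss(1e5, 0.8, 10)
  se <- sqrt(0.8^3 / 10 / 1e5)
  expect_lt(abs(mean(xs) - 0.8), 3 * se)
  # weights all zero -> zero log-likelihood; bad mean -> -Inf
  expect_equal(ig_loglik(c(0.8, 0.9), 0.8, 10, weights = c(0, 0)), 0)
  expect_equal(as.numeric(ig_loglik(c(0.8), c(-1), 10)), -Inf)
  # consistency with the density
  expect_equal(ig_loglik(c(0.7, 0.9), c(0.8, 0.85), 12),
               dinvgauss(0.7, 0.8, 12, log = TRUE) +
                 dinvgauss(0.9, 0.85, 12, log = TRUE), tolerance = 1e-12)
})

test_that("stationary renewal fit recovers the mean and passes KS", {
  hs <- renewal_series(640, mu = 0.8, lambda = 50, seed = 21)
  fit <- fit_point_process(hs, p = 4L, q = NULL, step = 0.1)
  ok <- !is.na(fit$mu)
  expect_lt(abs(mean(fit$mu[ok]) - 0.8) / 0.8, 0.02)
  gof <- ks_goodness_of_fit(fit)
  expect_true(gof$pass)
  expect_lt(max(abs(gof$acf)), 0.2)
})

test_that("evaluation grid arithmetic: (T - W)/step steps", {
  hs <- renewal_series(130, mu = 0.5, lambda = 2000, seed = 2)
  u <- hs$event_times
  fit <- fit_point_process(heartbeat_series(u[u <= u[1] + 60 + 1e-9]),
                           p = 3L, q = NULL, window = 30, step = 0.05)
  total <- max(fit$time) - u[1]
  expect_equal(length(fit$time), floor((total - 30) / 0.05) + 1L)
})

test_that("fit tracks a step change in mean RR within 15 s", {
  set.seed(31)
  rr <- c(rinvgauss(150, 1.0, 200), rinvgauss(220, 0.8, 200))
  u <- cumsum(c(5, rr))
  tstep <- u[151]
  fit <- fit_point_process(heartbeat_series(u), p = 4L, q = NULL, step = 0.1)
  ok <- !is.na(fit$mu)
  tcross <- fit$time[ok][which(fit$mu[ok] < 0.9 & fit$time[ok] > tstep)[1]]
  expect_lt(tcross - tstep, 15)
})

test_that("warm-started trajectories agree across step sizes (stationary)", {
  hs <- renewal_series(500, mu = 0.8, lambda = 60, seed = 77)
  f1 <- fit_point_process(hs, p = 3L, q = NULL, step = 1)
  f2 <- fit_point_process(hs, p = 3L, q = NULL, step = 0.25)
  common <- intersect(round(f1$time, 6), round(f2$time, 6))
  common <- common[common > min(f1$time) + 30]
  i1 <- match(common, round(f1$time, 6)); i2 <- match(common, round(f2$time, 6))
  keep <- !is.na(f1$mu[i1]) & !is.na(f2$mu[i2])
  expect_gt(sum(keep), 100)
  rel <- abs(f1$mu[i1][keep] - f2$mu[i2][keep]) / f2$mu[i2][keep]
  expect_lt(max(rel), 1e-4)
})

test_that("linear kernel coefficients are recovered on model-generated data", {
  # simulate from the model itself (alpha and orders matched); a strongly
  # anti-persistent kernel keeps the integrated heart-period series from
  # drifting and is well excited by its own interval noise. 20 seeds
  # (scaled from 100); estimation uses the whole stationary series (large
  # window, near-unity forgetting).
  b <- laguerre_basis(0.2, 2, 60)
  g1_true <- c(-0.7, 0.35, -0.15)
  lambda_true <- 3000
  errs <- vapply(1:20, function(sd0) {
    with_seed(100 + sd0, {
      n <- 620
      rr <- numeric(n); rr[1:2] <- 0.8
      for (j in 3:n) {
        l <- laguerre_filter(rev(diff(rr[1:(j - 1)])), b)
        mu_j <- rr[j - 1] + sum(g1_true * l)
        mu_j <- min(max(mu_j, 0.4), 1.6)
        rr[j] <- rinvgauss(1, mu_j, lambda_true)
      }
      fit <- fit_point_process(heartbeat_series(cumsum(c(1, rr))),
                               alpha = 0.2, p = 2L, q = NULL,
                               window = 300, step = 2, rho = 0.999)
      ok <- which(!is.na(fit$mu))
      g1_hat <- colMeans(fit$theta[ok, 2:4, drop = FALSE])
      sqrt(sum((g1_hat - g1_true)^2) / sum(g1_true^2))
    })
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("KS goodness-of-fit flags a misspecified model", {
  hs <- renewal_series(400, mu = 0.8, lambda = 50, seed = 5)
  fit <- fit_point_process(hs, p = 3L, q = NULL, step = 0.25)
  # corrupt the per-beat means: half the true rate
  bad <- fit
  bad$beat_mu <- fit$beat_mu * 2
  gof_bad <- ks_goodness_of_fit(bad)
  expect_false(gof_bad$pass)
  # too few intervals refused
  tiny <- fit; keep <- seq_len(10)
  tiny$beat_mu <- fit$beat_mu[keep]; tiny$beat_rr <- fit$beat_rr[keep]
  tiny$beat_lambda <- fit$beat_lambda[keep]
  expect_error(ks_goodness_of_fit(tiny), "20")
})

test_that("fit input validation", {
  hs <- renewal_series(30, mu = 0.8, lambda = 50, seed = 1)
  expect_error(fit_point_process(hs, window = 500), "shorter")
})
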