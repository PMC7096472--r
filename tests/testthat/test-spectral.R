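test_that("Laguerre-to-lag expansion inverts the basis projection", {
  b <- laguerre_basis(0.2, 5, 200)
  set.seed(4)
  g1 <- rnorm(6, 0, 0.1)
  a <- laguerre_to_lag(g1, b)
  # project back: phi' a = g1 exactly by orthonormality
  back <- drop(crossprod(b$phi, a))
  expect_equal(unname(back), g1, tolerance = 1e-8)
})

test_that("white case: flat spectrum at 2 sigma^2 dt and Parseval", {
  b <- laguerre_basis(0.2, 3, 100)
  pars <- list(g1 = rep(0, 4), mu = 0.8, sigma2 = 1e-6)  # 1 ms^2
  sp <- instantaneous_spectrum(pars, basis = b)
  expect_equal(range(sp$Q), rep(2 * 1 * 0.8, 2), tolerance = 1e-12)
  fny <- 1 / (2 * 0.8)
  spN <- instantaneous_spectrum(pars, basis = b, fgrid = seq(0, fny, 5e-4))
  expect_lt(abs(svbalance:::trapz(spN$f, spN$Q) - 1) / 1, 0.02)
})

test_that("AR(1)-equivalent kernel matches the closed-form spectrum", {
  b <- laguerre_basis(0, 3, 60)   # alpha = 0: phi_i(n) = (-1)^i at n = i; AR lag i + 1
  pars <- list(g1 = c(0.5, 0, 0, 0), mu = 0.8, sigma2 = 1e-6)
  sp <- instantaneous_spectrum(pars, basis = b, fgrid = seq(0, 0.5, 0.002))
  closed <- 2 * 1 * 0.8 / abs(1 - 0.5 * exp(-2i * pi * sp$f * 0.8))^2
  rel <- sqrt(sum((sp$Q - closed)^2) / sum(closed^2))
  expect_lt(rel, 0.01)
  # Parseval against the AR(1) variance sigma^2 / (1 - a^2)
  fny <- 1 / (2 * 0.8)
  spN <- instantaneous_spectrum(pars, basis = b, fgrid = seq(0, fny, 5e-4))
  expect_lt(abs(svbalance:::trapz(spN$f, spN$Q) - 1 / 0.75) / (1 / 0.75), 0.02)
  expect_true(all(spN$Q >= 0))
})

test_that("unstable AR kernels are flagged", {
  b <- laguerre_basis(0, 2, 30)
  expect_warning(
    instantaneous_spectrum(list(g1 = c(1.05, 0, 0), mu = 0.8, sigma2 = 1e-6),
                           basis = b),
    "unstable")
})

test_that("band integration: constants, delta peaks, refinement oracle", {
  f <- seq(0, 0.5, by = 0.002)
  spec <- list(f = f, Q = rep(3, length(f)))
  si <- integrate_spectrum(spec)
  expect_equal(si$lf, 3 * 0.11, tolerance = 1e-12)
  expect_equal(si$hf, 3 * 0.25, tolerance = 1e-12)
  expect_equal(si$lf_hf, 0.11 / 0.25, tolerance = 1e-12)
  # delta-like peak at 0.25 Hz -> all power in HF
  Q <- numeric(length(f)); Q[f > 0.24 & f < 0.26] <- 100
  si2 <- integrate_spectrum(list(f = f, Q = Q))
  expect_gt(si2$hf, 100 * 0.01)
  expect_equal(si2$lf, 0)
  # random spectrum: halved-step trapezoid oracle within 0.5%
  set.seed(9)
  Qs <- splinefun(seq(0, 0.5, by = 0.05), runif(11, 0.5, 2))
  coarse <- integrate_spectrum(list(f = f, Q = Qs(f)))
  f2 <- seq(0, 0.5, by = 0.001)
  fine <- integrate_spectrum(list(f = f2, Q = Qs(f2)))
  expect_lt(abs(coarse$lf - fine$lf) / fine$lf, 0.005)
  expect_lt(abs(coarse$hf - fine$hf) / fine$hf, 0.005)
  expect_error(integrate_spectrum(list(f = f, Q = Q),
                                  bands = list(lf = c(0.04, 0.15),
                                               hf = c(0.15, 0.7))),
               "band")
})

test_that("bispectrum: linear system is identically zero, symmetric otherwise", {
  b <- laguerre_basis(0.2, 2, 60)
  bz <- instantaneous_bispectrum(list(g1 = c(0.1, -0.2, 0), g2 = matrix(0, 3, 3),
                                      mu = 0.8, sigma2 = 1e-6), basis = b)
  expect_lt(max(bz$B), 1e-10)
  set.seed(2)
  g2 <- matrix(rnorm(9, 0, 0.1), 3); g2 <- (g2 + t(g2)) / 2
  bs <- instantaneous_bispectrum(list(g1 = c(0.1, -0.2, 0), g2 = g2,
                                      mu = 0.8, sigma2 = 1e-6), basis = b)
  expect_equal(bs$B, t(bs$B), tolerance = 1e-10)
  expect_true(all(bs$B >= 0))
  expect_error(
    instantaneous_bispectrum(list(g1 = rep(0, 3), g2 = g2, mu = 1.4,
                                  sigma2 = 1e-6), basis = b),
    "Nyquist")
})

test_that("constructed quadratic coupling peaks at its injection point", {
  dt <- 0.8; N <- 40
  k2 <- outer(1:N, 1:N, function(n, m)
    cos(2 * pi * 0.1 * n * dt) * cos(2 * pi * 0.25 * m * dt))
  k2 <- (k2 + t(k2)) / 2
  b0 <- laguerre_basis(0, N - 1, N + 5)
  g2 <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) g2[i, j] <- (-1)^(i + j) * k2[i, j]
  bis <- instantaneous_bispectrum(list(g1 = rep(0, 2), g2 = g2, mu = dt,
                                       sigma2 = 1e-6), basis = b0,
                                  fgrid = seq(0, 0.4, by = 0.005))
  am <- which(bis$B == max(bis$B), arr.ind = TRUE)[1, ]
  fhit <- sort(c(bis$f1[am[1]], bis$f2[am[2]]))
  expect_lte(abs(fhit[1] - 0.1), 0.005 + 1e-12)
  expect_lte(abs(fhit[2] - 0.25), 0.005 + 1e-12)
})

test_that("bispectral band integrals: unit field and refinement oracle", {
  f <- seq(0, 0.4, by = 0.005)
  ib <- integrate_bispectrum(list(f1 = f, f2 = f,
                                  B = matrix(1, length(f), length(f))))
  expect_equal(ib$ll, 0.15^2, tolerance = 1e-12)
  expect_equal(ib$lh, 0.15 * 0.25, tolerance = 1e-12)
  expect_equal(ib$hh, 0.25^2, tolerance = 1e-12)
  zero <- integrate_bispectrum(list(f1 = f, f2 = f,
                                    B = matrix(0, length(f), length(f))))
  expect_equal(unlist(zero), c(ll = 0, lh = 0, hh = 0))
  # random smooth field vs refined grid
  set.seed(12)
  gs <- splinefun(seq(0, 0.4, by = 0.05), runif(9, 0.5, 2))
  mk <- function(fg) {
    v <- gs(fg)
    list(f1 = fg, f2 = fg, B = outer(v, v))
  }
  coarse <- integrate_bispectrum(mk(f))
  fine <- integrate_bispectrum(mk(seq(0, 0.4, by = 0.00125)))
  for (nm in c("ll", "lh", "hh"))
    expect_lt(abs(coarse[[nm]] - fine[[nm]]) / fine[[nm]], 0.01)
  expect_error(integrate_bispectrum(list(f1 = seq(0, 0.3, 0.005),
                                         f2 = f, B = matrix(1, 61, 81))),
               "cover")
})
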