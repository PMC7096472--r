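test_that("rmssd and pnn50 match their definitions", {
  expect_equal(rmssd(c(0.8, 0.8, 0.8)), 0)
  expect_equal(rmssd(c(0.8, 0.9)), 0.1, tolerance = 1e-12)
  expect_equal(pnn50(c(1, 1, 1)), 0)
  expect_equal(pnn50(cumsum(c(1, 0.06, 0.04, 0.07))), 100 * 2 / 3,
               tolerance = 1e-12)
  set.seed(31)
  rr <- 0.8 + cumsum(rnorm(50, 0, 0.03))
  expect_equal(rmssd(rr), sqrt(mean(diff(rr)^2)), tolerance = 1e-12)
  expect_equal(pnn50(rr), 100 * sum(abs(diff(rr)) > 0.05) / 49,
               tolerance = 1e-12)
  expect_error(rmssd(0.8), "2 intervals")
})

test_that("window_average: constants, steps, random oracle, empty windows", {
  t <- seq(0, 100, by = 0.5)
  w <- data.frame(start = c(0, 50, 200), end = c(50, 100, 210))
  wa <- window_average(t, rep(4, length(t)), w)
  expect_equal(wa$value[1:2], c(4, 4))
  expect_true(wa$empty[3] && is.na(wa$value[3]))
  x <- ifelse(t < 50, 1, 7)
  expect_equal(window_average(t, x, w)$value[1:2], c(1, 7))
  set.seed(32)
  z <- rnorm(length(t))
  expect_equal(window_average(t, z, w)$value[1], mean(z[t < 50]))
})

test_that("neutral normalization divides by the subject's neutral row", {
  tb <- data.frame(subject = rep(1:2, each = 3),
                   session = rep(c("neutral", "pleasant", "unpleasant"), 2),
                   a = c(2, 3, 4, 1, 5, 0.5), b = c(4, 4, 2, 0, 3, 6))
  out <- normalize_by_neutral(tb)
  expect_equal(out$a[out$subject == 1], c(1.5, 2))
  expect_equal(out$b[out$subject == 1], c(1, 0.5))
  # zero neutral entry masks the column for that subject
  expect_true(all(is.na(out$b[out$subject == 2])))
  expect_equal(attr(out, "masked"), 2L)
  # identical sessions -> all ones
  tb2 <- tb[tb$subject == 1, ]; tb2$a <- 2; tb2$b <- 5
  expect_true(all(unlist(normalize_by_neutral(tb2)[, c("a", "b")]) == 1))
})

test_that("paired Wilcoxon: exact enumeration against independent oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- paired_wilcoxon(x, x - 1)       # all differences positive
  expect_equal(res$p_value, 2 / 2^8, tolerance = 1e-12)
  expect_equal(paired_wilcoxon(x, x)$p_value, 1)
  # random data without ties: agree with stats::wilcox.test exact p
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(6:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- paired_wilcoxon(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               exact = TRUE))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # brute-force oracle that also covers ties (midranks)
  brute <- function(d) {
    d <- d[d != 0]; n <- length(d); r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats_all <- as.numeric(signs %*% r)
    mean(abs(stats_all - mean(stats_all)) >= abs(v - mean(stats_all)) - 1e-9)
  }
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    a <- sample(1:4, n, replace = TRUE); b <- sample(1:4, n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] + 1
    expect_equal(paired_wilcoxon(a, b)$p_value, brute(a - b),
                 tolerance = 1e-12)
  }
  expect_error(paired_wilcoxon(1:3, 3:1), "5 pairs")
})

test_that("large-sample Wilcoxon approximation is close to the exact tail", {
  set.seed(35)
  x <- rnorm(30); y <- rnorm(30) + 0.5
  approx_p <- paired_wilcoxon(x, y)$p_value
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE,
                                             correct = TRUE))$p.value
  expect_equal(approx_p, unname(ref), tolerance = 1e-8)
})

test_that("normality check calibrates near 5% and detects exponentials", {
  set.seed(36)
  rej_norm <- mean(vapply(1:300, function(i)
    !normality_check(rnorm(200))$normal, logical(1)))
  expect_gt(rej_norm, 0.02); expect_lt(rej_norm, 0.09)
  rej_exp <- mean(vapply(1:100, function(i)
    !normality_check(rexp(200))$normal, logical(1)))
  expect_gte(rej_exp, 0.95)
  expect_false(normality_check(rep(1, 10))$normal)
  expect_error(normality_check(c(1, 2, 3)), "5 observations")
})

test_that("robust summary matches its definition and is scale-equivariant", {
  rs <- robust_summary(c(1, 1, 1))
  expect_equal(rs$median, 1); expect_equal(rs$dispersion, 0)
  rs2 <- robust_summary(c(1, 2, 3, 4, 5))
  expect_equal(rs2$median, 3)
  expect_equal(rs2$dispersion, 1.4826 / sqrt(5), tolerance = 1e-12)
  set.seed(37)
  x <- rexp(40)
  a <- robust_summary(x); b <- robust_summary(3 * x)
  expect_equal(b$median, 3 * a$median)
  expect_equal(b$dispersion, 3 * a$dispersion, tolerance = 1e-12)
})

test_that("compare_conditions assembles summaries and p-values per feature", {
  set.seed(38)
  rest <- data.frame(subject = 1:10, a = rnorm(10), b = rnorm(10, 5))
  elic <- data.frame(subject = 1:10, a = rnorm(10, 2), b = rnorm(10, 5))
  out <- compare_conditions(rest, elic)
  expect_equal(out$feature, c("a", "b"))
  expect_lt(out$p_value[out$feature == "a"], 0.05)
  expect_gt(out$p_value[out$feature == "b"], 0.05)
  out2 <- compare_conditions(rest, elic, adjust = "BH")
  expect_true("p_adjusted" %in% names(out2))
})
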