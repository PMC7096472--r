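#' Inverse-Gaussian density, distribution, and random generation
#'
#' Mean/shape parametrization used by the heartbeat interval model:
#' \deqn{f(x;\mu,\lambda) = \sqrt{\lambda/(2\pi x^3)}
#'   \exp\{-\lambda (x-\mu)^2 / (2\mu^2 x)\}, \quad x > 0.}
#'
#' @param x,n quantiles / number of draws.
#' @param mu mean (> 0).
#' @param lambda shape (> 0).
#' @param log,lower.tail usual conventions.
#' @return density, probability, or draws.
#' @export
dinvgauss <- function(x, mu, lambda, log = FALSE) {
  check_that(all(mu > 0) && all(lambda > 0), "mu and lambda must be > 0")
  ld <- ifelse(x > 0,
               0.5 * (log(lambda) - log(2 * pi) - 3 * log(x)) -
                 lambda * (x - mu)^2 / (2 * mu^2 * x),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dinvgauss
#' @export
pinvgauss <- function(x, mu, lambda, lower.tail = TRUE) {
  check_that(all(mu > 0) && all(lambda > 0), "mu and lambda must be > 0")
  p <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    xx <- x[pos]; m <- rep_len(mu, length(x))[pos]; l <- rep_len(lambda, length(x))[pos]
    a <- sqrt(l / xx) * (xx / m - 1)
    b <- -sqrt(l / xx) * (xx / m + 1)
    # log-scale second term to avoid overflow of exp(2*lambda/mu)
    p[pos] <- pnorm(a) + exp(2 * l / m + pnorm(b, log.p = TRUE))
  }
  p <- pmin(pmax(p, 0), 1)
  if (lower.tail) p else 1 - p
}

#' @rdname dinvgauss
#' @export
rinvgauss <- function(n, mu, lambda) {
  check_that(all(mu > 0) && all(lambda > 0), "mu and lambda must be > 0")
  # Michael-Schucany-Haas transformation method
  mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  nu <- rnorm(n)^2
  x <- mu + mu^2 * nu / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Weighted inverse-Gaussian log-likelihood
#'
#' \eqn{\sum_j w_j \log f(RR_j \mid \mu_j, \lambda)} for observed intervals
#' with per-interval means. Used as the local criterion of the point-process
#' fit.
#'
#' @param rr observed intervals (s).
#' @param mu per-interval means (s).
#' @param lambda IG shape (> 0).
#' @param weights non-negative weights (default all 1).
#' @return scalar log-likelihood; `-Inf` (with a message attribute) if any
#'   mean is non-positive.
#' @export
ig_loglik <- function(rr, mu, lambda, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(rr))
  check_that(length(mu) %in% c(1L, length(rr)), "mu must be scalar or match rr")
  check_that(lambda > 0, "lambda must be > 0")
  if (all(weights == 0)) return(0)
  if (any(mu <= 0)) {
    out <- -Inf
    attr(out, "diagnostic") <- "non-positive mean in likelihood window"
    return(out)
  }
  sum(weights * dinvgauss(rr, rep_len(mu, length(rr)), lambda, log = TRUE))
}
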