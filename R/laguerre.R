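#' Discrete-time orthonormal Laguerre basis
#'
#' The i-th order discrete Laguerre function
#' \deqn{\phi_i(n) = \alpha^{(n-i)/2}(1-\alpha)^{1/2}
#'   \sum_{j=0}^{i} (-1)^j \binom{n}{j}\binom{i}{j}
#'   \alpha^{i-j}(1-\alpha)^{j}, \quad n \ge 0,}
#' with \eqn{\alpha \in [0, 1)} controlling memory decay. The functions are
#' orthonormal over \eqn{n = 0, 1, \dots} and are used to expand the
#' Volterra kernels of the heartbeat model with a handful of coefficients.
#'
#' @param alpha Laguerre parameter in \[0, 1).
#' @param order maximum order (>= 0); orders 0..order are returned.
#' @param n_mem memory length: lags 0..n_mem.
#' @return object of class `laguerre_basis`: list with `alpha`, `order`,
#'   `phi` (matrix, (n_mem+1) x (order+1), rows = lags).
#' @export
laguerre_basis <- function(alpha, order, n_mem = 500L) {
  check_that(alpha >= 0 && alpha < 1, "alpha must lie in [0, 1)")
  check_that(order >= 0, "order must be >= 0")
  n <- 0:n_mem
  phi <- matrix(0, n_mem + 1L, order + 1L)
  for (i in 0:order) {
    s <- numeric(n_mem + 1L)
    for (j in 0:i)
      s <- s + (-1)^j * choose(n, j) * choose(i, j) *
        alpha^(i - j) * (1 - alpha)^j
    if (alpha == 0) {
      pref <- ifelse(n == i, 1, 0)  # 0^0 = 1 convention
    } else {
      pref <- alpha^((n - i) / 2)
      pref[n < i] <- alpha^((n[n < i] - i) / 2)  # still finite for alpha > 0
    }
    phi[, i + 1L] <- pref * sqrt(1 - alpha) * s
  }
  structure(list(alpha = alpha, order = order, n_mem = n_mem, phi = phi),
            class = "laguerre_basis")
}

#' Laguerre filter outputs from RR increment history
#'
#' Computes \eqn{l_i = \sum_{n \ge 0} \phi_i(n)\, d_n} where \eqn{d_n} is
#' the n-th most recent complete RR increment
#' (\eqn{d_0 = RR_{j-1} - RR_{j-2}} when filtering for target beat j, so
#' the filter is strictly causal). Filtering from lag 0 preserves the
#' orthonormality of the effective regressors, which keeps the kernel
#' coefficients identifiable. Sums run over the available history;
#' shorter-than-memory histories are summed as far as they go.
#'
#' @param increments numeric vector of RR increments, most recent first
#'   (`increments[1]` is weighted by \eqn{\phi_i(0)}).
#' @param basis a [laguerre_basis()].
#' @return numeric vector of filter outputs, one per basis order.
#' @export
laguerre_filter <- function(increments, basis) {
  check_that(inherits(basis, "laguerre_basis"), "basis must be a laguerre_basis")
  nmax <- min(length(increments), basis$n_mem + 1L)
  if (nmax < 1L) return(numeric(basis$order + 1L))
  # phi rows are lags 0..n_mem; increments[k] gets weight phi(k - 1)
  drop(crossprod(basis$phi[seq_len(nmax), , drop = FALSE],
                 increments[seq_len(nmax)]))
}

# Laguerre filter outputs for every beat of an RR series.
# Returns an (n_beats x (order+1)) matrix; row j holds l_i computed from
# history strictly before beat j (i.e. increments up to RR_{j-1}).
laguerre_filter_series <- function(rr, basis) {
  n <- length(rr)
  p1 <- basis$order + 1L
  out <- matrix(0, n, p1)
  d <- diff(rr)  # d[k] = RR_{k+1} - RR_k
  for (j in seq_len(n)) {
    # increments most recent first, strictly before beat j:
    # d_1 = RR_{j-1} - RR_{j-2}, ...
    if (j >= 3L) {
      hist <- d[(j - 2L):1L]
      out[j, ] <- laguerre_filter(hist, basis)
    }
  }
  out
}
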