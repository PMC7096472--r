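// Local maximum-likelihood tracking of the inverse-Gaussian heartbeat model.
//
// At every step of a regular time grid the model mean
//   mu_j = base_j + x_j' theta
// (base_j = previous RR, x_j = [1, Laguerre filter outputs, quadratic
// products]) is fitted to the intervals whose end beat lies in a trailing
// window of length W, with exponential forgetting rho^(t - u_j).  The IG
// shape lambda is profiled out in closed form; theta is updated by
// Newton-Raphson with step halving, warm-started from the previous step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double ig_wll(const arma::vec& y, const arma::vec& mu,
                     const arma::vec& w, double lambda) {
  arma::vec t = arma::log(lambda / (2.0 * M_PI * arma::pow(y, 3))) * 0.5 -
                lambda * arma::square(y - mu) / (2.0 * arma::square(mu) % y);
  return arma::dot(w, t);
}

// [[Rcpp::export]]
List ppfit_core(const arma::vec& ty, const arma::vec& y,
                const arma::vec& base, const arma::mat& X,
                const arma::vec& tgrid, double W, double rho,
                int max_iter, double tol,
                arma::vec theta, double lambda) {
  const int m = y.n_elem, d = X.n_cols, S = tgrid.n_elem;
  arma::mat theta_out(S, d, arma::fill::value(NA_REAL));
  arma::vec lam_out(S, arma::fill::value(NA_REAL));
  arma::vec mu_out(S, arma::fill::value(NA_REAL));
  arma::vec conv(S, arma::fill::zeros);
  arma::vec lnrho = arma::vec(1);
  const double lrho = std::log(rho);

  int lo = 0, hi = -1;  // ty indices in window (t - W, t]
  int n_nonconv = 0;

  for (int s = 0; s < S; ++s) {
    const double t = tgrid[s];
    while (hi + 1 < m && ty[hi + 1] <= t) ++hi;
    while (lo <= hi && ty[lo] <= t - W) ++lo;
    const int nw = hi - lo + 1;
    if (nw < d + 2) continue;  // not enough intervals yet

    arma::vec yw = y.subvec(lo, hi);
    arma::vec bw = base.subvec(lo, hi);
    arma::mat Xw = X.rows(lo, hi);
    arma::vec w = arma::exp(lrho * (t - ty.subvec(lo, hi)));

    const double sw = arma::accu(w);
    bool ok = false;
    arma::vec mu = bw + Xw * theta;
    if (mu.min() <= 0) {
      // reset to a safe starting point: constant mean
      theta.zeros();
      theta[0] = arma::dot(w, yw) / sw - arma::dot(w, bw) / sw;
      mu = bw + Xw * theta;
    }
    double ll_prev = -arma::datum::inf;
    for (int it = 0; it < max_iter; ++it) {
      // profile lambda
      arma::vec r2 = arma::square(yw - mu) / (arma::square(mu) % yw);
      double lam = sw / std::max(arma::dot(w, r2), 1e-12);
      arma::vec g1 = w % (yw - mu) / arma::pow(mu, 3);
      arma::vec grad = lam * Xw.t() * g1;
      if (arma::abs(grad).max() < tol) { ok = true; lambda = lam; break; }
      arma::vec h1 = w % (3.0 * yw - 2.0 * mu) / arma::pow(mu, 4);
      arma::mat H = Xw.t() * (Xw.each_col() % h1) * lam;  // -Hessian
      H.diag() += 1e-10;
      arma::vec step;
      bool solved = arma::solve(step, H, grad, arma::solve_opts::no_approx);
      if (!solved) break;
      double ll0 = ig_wll(yw, mu, w, lam);
      double sc = 1.0;
      bool accepted = false;
      for (int h = 0; h < 25; ++h) {
        arma::vec th_try = theta + sc * step;
        arma::vec mu_try = bw + Xw * th_try;
        if (mu_try.min() > 0) {
          double ll_try = ig_wll(yw, mu_try, w, lam);
          if (ll_try >= ll0 - 1e-12) {
            theta = th_try; mu = mu_try; accepted = true; break;
          }
        }
        sc *= 0.5;
      }
      if (!accepted) break;
      double ll_now = ig_wll(yw, mu, w, lam);
      if (std::abs(ll_now - ll_prev) < 1e-12 * (1.0 + std::abs(ll_now))) {
        ok = true; lambda = lam; break;
      }
      ll_prev = ll_now;
      lambda = lam;
    }
    if (!ok) {
      // recompute gradient norm; accept if close enough, else carry over
      arma::vec g1 = w % (yw - mu) / arma::pow(mu, 3);
      if (arma::abs(lambda * Xw.t() * g1).max() < 100 * tol) ok = true;
    }
    if (!ok) ++n_nonconv;
    conv[s] = ok ? 1.0 : 0.0;
    theta_out.row(s) = theta.t();
    lam_out[s] = lambda;
    // instantaneous mean: prediction for the upcoming interval
    if (hi + 1 < m) mu_out[s] = base[hi + 1] + arma::dot(X.row(hi + 1), theta);
    else mu_out[s] = bw[nw - 1] + arma::dot(Xw.row(nw - 1), theta);
  }
  return List::create(_["theta"] = theta_out, _["lambda"] = lam_out,
                      _["mu"] = mu_out, _["converged"] = conv,
                      _["n_nonconverged"] = n_nonconv);
}
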