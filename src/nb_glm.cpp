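// Negative-binomial GLM (log link) fitted by IRLS, vectorised over features.
// Parameterisation: Var(Y) = mu + phi * mu^2 (edgeR-style dispersion phi).
// phi below 1e-10 is treated as the Poisson limit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_MAX = 30.0;
static const double ETA_MIN = -30.0;

static double nb_loglik(const arma::rowvec& y, const arma::vec& mu, double phi) {
  const int n = y.n_elem;
  double ll = 0.0;
  if (phi < 1e-10) {
    for (int i = 0; i < n; ++i)
      ll += y[i] * std::log(mu[i]) - mu[i] - std::lgamma(y[i] + 1.0);
  } else {
    const double a = 1.0 / phi;
    for (int i = 0; i < n; ++i) {
      const double m = mu[i];
      ll += std::lgamma(y[i] + a) - std::lgamma(a) - std::lgamma(y[i] + 1.0)
          + y[i] * std::log(phi * m / (1.0 + phi * m))
          - a * std::log1p(phi * m);
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".nbGlmFitCpp")]]
List nb_glm_fit_cpp(const arma::mat& Y,        // G x n counts
                    const arma::mat& X,        // n x p design
                    const arma::vec& offset,   // n, log effective library size
                    const arma::vec& phi,      // length 1 or G
                    const bool cr_adjust,
                    const double tol,
                    const int maxit) {
  const int G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  arma::mat beta(G, p, arma::fill::value(NA_REAL));
  arma::vec loglik(G, arma::fill::value(NA_REAL));
  arma::vec cr(G, arma::fill::zeros);
  LogicalVector converged(G);
  IntegerVector iters(G);

  for (int g = 0; g < G; ++g) {
    const arma::rowvec y = Y.row(g);
    const double ph = (phi.n_elem == 1) ? phi[0] : phi[g];

    if (arma::max(y) <= 0.0) {               // no information: flagged, not fitted
      converged[g] = false;
      iters[g] = 0;
      loglik[g] = 0.0;                       // limit as mu -> 0
      continue;
    }

    arma::vec eta(n), mu(n), b(p, arma::fill::zeros), b_old(p);
    for (int i = 0; i < n; ++i) eta[i] = std::log(y[i] + 0.5);
    mu = arma::exp(eta);

    bool ok = false;
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      arma::vec w(n), z(n);
      for (int i = 0; i < n; ++i) {
        const double m = mu[i];
        w[i] = m / (1.0 + ph * m);
        z[i] = (eta[i] - offset[i]) + (y[i] - m) / m;
      }
      arma::mat Xw = X.each_col() % w;
      arma::mat XtWX = X.t() * Xw;
      XtWX.diag() += 1e-10;                  // guard near-singular weights
      arma::vec XtWz = Xw.t() * z;
      b_old = b;
      const bool solved = arma::solve(b, XtWX, XtWz, arma::solve_opts::likely_sympd);
      if (!solved || !b.is_finite()) { ok = false; break; }
      eta = offset + X * b;
      eta.clamp(ETA_MIN, ETA_MAX);
      mu = arma::exp(eta);
      if (it > 0 && arma::abs(b - b_old).max() < tol) { ok = true; ++it; break; }
    }

    converged[g] = ok;
    iters[g] = it;
    if (b.is_finite()) {
      beta.row(g) = b.t();
      loglik[g] = nb_loglik(y, mu, ph);
      if (cr_adjust) {
        arma::vec w(n);
        for (int i = 0; i < n; ++i) w[i] = mu[i] / (1.0 + ph * mu[i]);
        arma::mat XtWX = X.t() * (X.each_col() % w);
        double val, sign;
        if (arma::log_det(val, sign, XtWX) && sign > 0) cr[g] = 0.5 * val;
        else cr[g] = NA_REAL;
      }
    }
  }

  return List::create(_["beta"] = beta,
                      _["loglik"] = loglik,
                      _["converged"] = converged,
                      _["iter"] = iters,
                      _["cr"] = cr);
}
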