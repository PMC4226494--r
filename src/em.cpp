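// EM core for the mixture-of-regressions likelihood with latent genotype
// G in {0,1,2} and per-sample prior weights given by posterior genotype
// probabilities. Kept in C++ so Monte-Carlo drivers can run 1e5+ fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SIGMA2_FLOOR = 1e-12;

// Observed-data log-likelihood sum_i log sum_g f_ig phi(y_i; b0+b1*g+Z*gam, s2),
// evaluated in log space with per-sample max subtraction (stable for
// standardized residuals up to ~300).
// [[Rcpp::export]]
double obs_loglik_cpp(const arma::vec& y, const arma::mat& F,
                      const arma::mat& Z, double beta0, double beta1,
                      const arma::vec& gamma, double sigma2) {
  const arma::uword n = y.n_elem;
  if (sigma2 < SIGMA2_FLOOR) sigma2 = SIGMA2_FLOOR;
  const double lognorm = -0.5 * std::log(2.0 * M_PI * sigma2);
  const double inv2s2 = 0.5 / sigma2;
  arma::vec base(n, arma::fill::zeros);
  if (Z.n_cols > 0) base = Z * gamma;
  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double lw[3];
    double m = -std::numeric_limits<double>::infinity();
    for (int g = 0; g < 3; ++g) {
      double f = F(i, g);
      if (f > 0.0) {
        double r = y[i] - beta0 - beta1 * g - base[i];
        lw[g] = std::log(f) + lognorm - r * r * inv2s2;
        if (lw[g] > m) m = lw[g];
      } else {
        lw[g] = -std::numeric_limits<double>::infinity();
      }
    }
    double s = 0.0;
    for (int g = 0; g < 3; ++g)
      if (std::isfinite(lw[g])) s += std::exp(lw[g] - m);
    ll += m + std::log(s);
  }
  return ll;
}

// One EM fit. start = (beta0, beta1, gamma...), sigma2_start > 0.
// Returns parameter estimates, observed-data log-likelihood, iteration
// count, convergence flag and (optionally) the per-iteration trace.
// [[Rcpp::export]]
List em_fit_cpp(const arma::vec& y, const arma::mat& F, const arma::mat& Z,
                const arma::vec& start, double sigma2_start, double tol,
                int max_iter, bool keep_trace) {
  const arma::uword n = y.n_elem;
  const arma::uword K = Z.n_cols;
  double beta0 = start[0], beta1 = start[1];
  arma::vec gamma(K, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k) gamma[k] = start[2 + k];
  double sigma2 = std::max(sigma2_start, SIGMA2_FLOOR);

  arma::vec eg(n), eg2(n), base(n, arma::fill::zeros);
  std::vector<double> trace;
  double prev = -std::numeric_limits<double>::infinity();
  double ll = prev;
  bool converged = false, degenerate = false;
  int it = 0;

  // Fixed pieces of the expected-complete-data normal equations.
  const double Sy = arma::accu(y);
  arma::vec Sz(K), Syz(K);
  arma::mat Szz(K, K);
  if (K > 0) {
    Sz = arma::sum(Z, 0).t();
    Syz = Z.t() * y;
    Szz = Z.t() * Z;
  }

  for (it = 1; it <= max_iter; ++it) {
    // E-step (also yields the observed-data log-likelihood at current theta)
    if (K > 0) base = Z * gamma;
    const double lognorm = -0.5 * std::log(2.0 * M_PI * sigma2);
    const double inv2s2 = 0.5 / sigma2;
    ll = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double lw[3], w[3];
      double m = -std::numeric_limits<double>::infinity();
      for (int g = 0; g < 3; ++g) {
        double f = F(i, g);
        if (f > 0.0) {
          double r = y[i] - beta0 - beta1 * g - base[i];
          lw[g] = std::log(f) + lognorm - r * r * inv2s2;
          if (lw[g] > m) m = lw[g];
        } else {
          lw[g] = -std::numeric_limits<double>::infinity();
        }
      }
      double s = 0.0;
      for (int g = 0; g < 3; ++g)
        w[g] = std::isfinite(lw[g]) ? std::exp(lw[g] - m) : 0.0, s += w[g];
      ll += m + std::log(s);
      eg[i] = (w[1] + 2.0 * w[2]) / s;
      eg2[i] = (w[1] + 4.0 * w[2]) / s;
    }
    if (keep_trace) trace.push_back(ll);
    if (it > 1 && std::fabs(ll - prev) < tol) { converged = true; break; }
    prev = ll;

    // M-step: solve the expected-complete-data normal equations, with
    // E[G^2] in the Gram matrix where G^2 would appear.
    const double Seg = arma::accu(eg);
    const double Seg2 = arma::accu(eg2);
    const double Syeg = arma::dot(y, eg);
    arma::mat A(2 + K, 2 + K);
    arma::vec b(2 + K);
    A(0, 0) = (double)n; A(0, 1) = A(1, 0) = Seg; A(1, 1) = Seg2;
    b[0] = Sy; b[1] = Syeg;
    if (K > 0) {
      arma::vec Segz = Z.t() * eg;
      for (arma::uword k = 0; k < K; ++k) {
        A(0, 2 + k) = A(2 + k, 0) = Sz[k];
        A(1, 2 + k) = A(2 + k, 1) = Segz[k];
        b[2 + k] = Syz[k];
        for (arma::uword l = 0; l < K; ++l) A(2 + k, 2 + l) = Szz(k, l);
      }
    }
    arma::vec coef;
    bool ok = arma::solve(coef, A, b, arma::solve_opts::no_approx);
    if (!ok) { degenerate = true; break; }
    beta0 = coef[0]; beta1 = coef[1];
    for (arma::uword k = 0; k < K; ++k) gamma[k] = coef[2 + k];
    if (K > 0) base = Z * gamma;
    double rss = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double r = y[i] - beta0 - beta1 * eg[i] - base[i];
      rss += r * r + beta1 * beta1 * (eg2[i] - eg[i] * eg[i]);
    }
    sigma2 = std::max(rss / n, SIGMA2_FLOOR);
  }
  if (it > max_iter) it = max_iter;

  return List::create(
      _["beta0"] = beta0, _["beta1"] = beta1, _["gamma"] = gamma,
      _["sigma2"] = sigma2, _["loglik"] = ll, _["n_iter"] = it,
      _["converged"] = converged, _["degenerate"] = degenerate,
      _["trace"] = trace);
}
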