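// Polya-Gamma data augmentation for Bayesian logistic regression.
//
// rpg1() draws PG(1, z) by Devroye's alternating-series rejection sampler
// (the b = 1 case is all a Bernoulli likelihood needs).  All randomness goes
// through R's RNG so set.seed() in R gives bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;  // left/right split point of the J*(1,z) proposal

// coefficients of the alternating series for the J*(1,z) density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC)
    return M_PI * k * std::exp(-k * k * M_PI * M_PI * x / 2.0);
  return M_PI * k * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * k * k / x);
}

// P(IG(1/z, 1) <= t); finite for z = 0 (Levy limit) and large z (log-scale term)
static double pigauss(double t, double z) {
  double s = std::sqrt(t);
  double term1 = R::pnorm((t * z - 1.0) / s, 0.0, 1.0, 1, 0);
  double term2 = std::exp(2.0 * z + R::pnorm(-(t * z + 1.0) / s, 0.0, 1.0, 1, 1));
  return term1 + term2;
}

// inverse-Gaussian(1/z, 1) truncated to (0, TRUNC)
static double tinvgauss(double z) {
  double t = TRUNC;
  if (z < 1.0 / t) {
    // big mean: sample from the one-sided stable tail and thin by exp(-z^2 X / 2)
    for (;;) {
      double E, E2;
      do {
        E = exp_rand();
        E2 = exp_rand();
      } while (E * E > 2.0 * E2 / t);
      double X = t / ((1.0 + t * E) * (1.0 + t * E));
      if (unif_rand() <= std::exp(-0.5 * z * z * X)) return X;
    }
  } else {
    double mu = 1.0 / z;
    for (;;) {
      double Y = norm_rand();
      Y = Y * Y;
      double X = mu + 0.5 * mu * mu * Y -
                 0.5 * mu * std::sqrt(4.0 * mu * Y + mu * mu * Y * Y);
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
      if (X <= t) return X;
    }
  }
}

// one draw from PG(1, z)
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double K = M_PI * M_PI / 8.0 + 0.5 * z * z;
  double logp = std::log(M_PI / (2.0 * K)) - K * TRUNC;
  double logq = M_LN2 - z + std::log(pigauss(TRUNC, z));
  double p_right = 1.0 / (1.0 + std::exp(logq - logp));
  for (;;) {
    double X;
    if (unif_rand() < p_right)
      X = TRUNC + exp_rand() / K;
    else
      X = tinvgauss(z);
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return X / 4.0;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;  // reject, redraw X
      }
    }
  }
}

//' @title Polya-Gamma PG(1, z) draws (internal)
//' @param z numeric vector of tilting parameters
//' @return one PG(1, z[i]) draw per element
//' @keywords internal
// [[Rcpp::export(rng = true)]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

//' @title Blocked Gibbs sampler for Bayesian logistic regression (internal)
//'
//' Likelihood y_i ~ Bernoulli(logit^-1(a_i' theta)) with independent
//' N(0, prior_var_j) priors.  Augmentation omega_i ~ PG(1, eta_i) makes the
//' coefficient update conjugate multivariate normal.
//'
//' @param A n x d design (prognostic columns then treatment-interacted columns)
//' @param y 0/1 response
//' @param prior_var d-vector of prior variances
//' @param n_iter retained draws
//' @param burn discarded initial iterations
//' @param init starting coefficient vector
//' @return n_iter x d matrix of retained draws
//' @keywords internal
// [[Rcpp::export(rng = true)]]
arma::mat gibbs_pg_logistic(const arma::mat& A, const arma::vec& y,
                            const arma::vec& prior_var, int n_iter, int burn,
                            const arma::vec& init) {
  const arma::uword n = A.n_rows, d = A.n_cols;
  arma::vec Atk = A.t() * (y - 0.5);
  arma::mat Binv = arma::diagmat(1.0 / prior_var);
  arma::vec theta = init;
  arma::mat out(n_iter, d);
  arma::vec omega(n), eta(n), zdraw(d);
  for (int it = 0; it < n_iter + burn; ++it) {
    if (n > 0) {
      eta = A * theta;
      for (arma::uword i = 0; i < n; ++i) omega(i) = rpg1(eta(i));
    }
    arma::mat P = Binv;
    if (n > 0) P += A.t() * (A.each_col() % omega);
    arma::mat L = arma::chol(P, "lower");
    arma::vec m = arma::solve(arma::trimatu(L.t()),
                              arma::solve(arma::trimatl(L), Atk));
    for (arma::uword j = 0; j < d; ++j) zdraw(j) = norm_rand();
    theta = m + arma::solve(arma::trimatu(L.t()), zdraw);
    if (it >= burn) out.row(it - burn) = theta.t();
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
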