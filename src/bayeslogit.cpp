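// Polya-Gamma Gibbs sampler for Bayesian logistic regression with
// ridge and horseshoe priors. PG(1, z) draws use the alternating-series
// rejection sampler of Polson, Scott & Windle; all randomness comes from
// R's RNG so fits are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;

static inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * 0.5 * x);
  else
    return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
           std::exp(-2.0 * np5 * np5 / x);
}

// CDF at x of inverse-Gaussian(mu = 1/z, lambda = 1); parameterized by z
// so z = 0 (mu = infinity) is well defined.
static inline double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  z = std::fabs(z);
  double t = TRUNC;
  double X = t + 1.0;
  if (z < 1.0 / t) { // mu > t: rejection from truncated inverse-chi-square
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    double mu = 1.0 / z;
    while (X > t) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// One draw from PG(1, z)
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = M_PI * M_PI * 0.125 + z * z * 0.5;
  for (int tries = 0; tries < 10000; ++tries) {
    double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
    double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
    double U = R::unif_rand();
    double X;
    if (U * (p + q) <= p)
      X = TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(z);
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break; // reject, restart
      }
      if (n > 500) return 0.25 * X; // numerical guard, series has converged
    }
  }
  return 0.25 * TRUNC; // unreachable
}

// [[Rcpp::export]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

static inline double rinvgamma(double shape, double scale) {
  // X ~ IG(shape, scale): 1/G with G ~ Gamma(shape, rate = scale)
  double g = R::rgamma(shape, 1.0 / scale);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Gibbs sampler. X must contain the intercept as its first column.
// prior: 0 = ridge, 1 = horseshoe; the intercept is unpenalized
// (fixed Normal(0, intercept_var) prior).
// [[Rcpp::export]]
List gibbs_logistic_cpp(const arma::mat& X, const arma::vec& y, int prior,
                        int burn, int samples, int thin,
                        double intercept_var) {
  int n = X.n_rows, p = X.n_cols, pb = p - 1;
  int nsave = samples / thin;
  arma::mat draws(nsave, p, arma::fill::zeros);
  arma::vec tau2_draws(nsave, arma::fill::zeros);

  arma::vec beta(p, arma::fill::zeros);
  double tau2 = 1.0, xi = 1.0;
  arma::vec lambda2(pb, arma::fill::ones), nu(pb, arma::fill::ones);
  arma::vec kappa = y - 0.5;

  int total = burn + samples, isave = 0;
  for (int it = 0; it < total; ++it) {
    // latent Polya-Gamma variables
    arma::vec eta = X * beta;
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // prior precision
    arma::vec pprec(p);
    pprec[0] = 1.0 / intercept_var;
    for (int j = 0; j < pb; ++j) {
      double v = (prior == 1) ? tau2 * lambda2[j] : tau2;
      pprec[j + 1] = 1.0 / clampd(v, 1e-12, 1e12);
    }

    // beta | omega ~ N(Prec^-1 X'kappa, Prec^-1)
    arma::mat Xo = X.each_col() % omega;
    arma::mat Prec = X.t() * Xo;
    Prec.diag() += pprec;
    arma::mat R_ = arma::chol(Prec); // upper: R'R = Prec
    arma::vec b = X.t() * kappa;
    arma::vec m = arma::solve(arma::trimatu(R_),
                              arma::solve(arma::trimatl(R_.t()), b));
    arma::vec zdraw(p);
    for (int j = 0; j < p; ++j) zdraw[j] = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(R_), zdraw);

    // shrinkage hyper-parameters (half-Cauchy via inverse-gamma auxiliaries)
    if (prior == 1) {
      double ssum = 0.0;
      for (int j = 0; j < pb; ++j) {
        double bj = beta[j + 1];
        lambda2[j] = clampd(
            rinvgamma(1.0, 1.0 / nu[j] + bj * bj / (2.0 * tau2)),
            1e-12, 1e12);
        nu[j] = rinvgamma(1.0, 1.0 + 1.0 / lambda2[j]);
        ssum += bj * bj / lambda2[j];
      }
      tau2 = clampd(rinvgamma(0.5 * (pb + 1.0), 1.0 / xi + 0.5 * ssum),
                    1e-12, 1e12);
      xi = rinvgamma(1.0, 1.0 + 1.0 / tau2);
    } else {
      double ssum = 0.0;
      for (int j = 0; j < pb; ++j) ssum += beta[j + 1] * beta[j + 1];
      tau2 = clampd(rinvgamma(0.5 * (pb + 1.0), 1.0 / xi + 0.5 * ssum),
                    1e-12, 1e12);
      xi = rinvgamma(1.0, 1.0 + 1.0 / tau2);
    }

    if (it >= burn && ((it - burn) % thin == thin - 1)) {
      draws.row(isave) = beta.t();
      tau2_draws[isave] = tau2;
      ++isave;
    }
  }
  return List::create(_["beta"] = draws, _["tau2"] = tau2_draws);
}
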