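// Hot loops for the Lorentzian-mixture sampler: mixture evaluation, Gaussian
// log likelihood, and an adaptive random-walk Metropolis chain targeting
// prior(theta) * likelihood(theta)^beta over the uniform prior box.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static void add_mixture(const arma::vec& x, const arma::vec& M,
                        const arma::vec& omega, const arma::vec& beta,
                        double sf, arma::vec& out) {
  const int K = M.n_elem;
  const int n = x.n_elem;
  for (int k = 0; k < K; ++k) {
    const double hg = 0.5 * std::pow(10.0, beta[k]) / sf; // half FWHM in ppm
    const double amp = (M[k] / M_PI) * hg;
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - omega[k];
      out[i] += amp / (d * d + hg * hg);
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_mixture(const arma::vec& x, const arma::vec& M,
                      const arma::vec& omega, const arma::vec& beta,
                      double sf) {
  arma::vec out(x.n_elem, arma::fill::zeros);
  add_mixture(x, M, omega, beta, sf, out);
  return out;
}

static double loglik_theta(const arma::vec& x, const arma::vec& y,
                           const arma::vec& theta, int K, double sf,
                           double sigma, double lconst) {
  // theta layout: M_1..M_K, omega_1..omega_K, beta_1..beta_K
  const int n = x.n_elem;
  double ss = 0.0;
  if (K == 0) {
    ss = arma::dot(y, y);
  } else if (K == 1) {
    const double hg = 0.5 * std::pow(10.0, theta[2]) / sf;
    const double amp = (theta[0] / M_PI) * hg;
    const double w = theta[1];
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - w;
      const double r = y[i] - amp / (d * d + hg * hg);
      ss += r * r;
    }
  } else {
    arma::vec f(n, arma::fill::zeros);
    add_mixture(x, theta.subvec(0, K - 1), theta.subvec(K, 2 * K - 1),
                theta.subvec(2 * K, 3 * K - 1), sf, f);
    for (int i = 0; i < n; ++i) {
      const double r = y[i] - f[i];
      ss += r * r;
    }
  }
  return lconst - ss / (2.0 * sigma * sigma);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::vec& x, const arma::vec& y, const arma::vec& M,
                  const arma::vec& omega, const arma::vec& beta, double sf,
                  double sigma) {
  const int K = M.n_elem;
  arma::vec theta(std::max(3 * K, 1));
  for (int k = 0; k < K; ++k) {
    theta[k] = M[k];
    theta[K + k] = omega[k];
    theta[2 * K + k] = beta[k];
  }
  const double n = static_cast<double>(x.n_elem);
  const double lconst = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma);
  return loglik_theta(x, y, theta, K, sf, sigma, lconst);
}

static arma::vec rnorm_vec(int d) {
  arma::vec z(d);
  for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
  return z;
}

// Adaptive random-walk Metropolis at inverse temperature beta_temp.
// Proposal N(theta, s^2 * Sigma_hat): the global scale s follows a
// Robbins-Monro recursion toward a 0.28 acceptance rate and Sigma_hat is the
// running sample covariance of the chain (Haario-style), both adapted during
// burn-in only and frozen afterwards. Box bounds act through the uniform
// prior: out-of-box proposals are rejected outright.
// [[Rcpp::export]]
List cpp_am_chain(const arma::vec& x, const arma::vec& y, int K, double sf,
                  double sigma, double beta_temp, const arma::vec& lower,
                  const arma::vec& upper, const arma::vec& init,
                  int n_steps, int burn_in, int thinning) {
  const int d = 3 * K;
  const double n = static_cast<double>(x.n_elem);
  const double lconst = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma);

  arma::vec theta = init;
  double ll_cur = loglik_theta(x, y, theta, K, sf, sigma, lconst);

  // running moments for covariance adaptation
  arma::vec mu = theta;
  arma::mat M2(d, d, arma::fill::zeros);
  arma::mat chol_prop(d, d, arma::fill::zeros);
  arma::vec width = upper - lower;
  chol_prop.diag() = width / 20.0; // initial diagonal proposal
  double log_scale = 0.0;
  const double target = 0.28;
  const int adapt_interval = 100;

  const int n_keep = (n_steps - burn_in) / thinning;
  arma::mat draws(n_keep, d);
  arma::vec lls(n_keep);
  int kept = 0;
  long accepted = 0, proposed = 0;

  for (int step = 1; step <= n_steps; ++step) {
    arma::vec prop = theta + std::exp(log_scale) * (chol_prop.t() * rnorm_vec(d));
    ++proposed;
    bool inside = true;
    for (int i = 0; i < d; ++i) {
      if (prop[i] < lower[i] || prop[i] > upper[i]) { inside = false; break; }
    }
    bool acc = false;
    if (inside) {
      const double ll_prop = loglik_theta(x, y, prop, K, sf, sigma, lconst);
      const double la = beta_temp * (ll_prop - ll_cur);
      if (la >= 0.0 || std::log(R::unif_rand()) < la) {
        theta = prop;
        ll_cur = ll_prop;
        acc = true;
        ++accepted;
      }
    }

    if (step <= burn_in) {
      // Welford update of mean / scatter over the realized chain
      arma::vec delta = theta - mu;
      mu += delta / static_cast<double>(step + 1);
      M2 += delta * (theta - mu).t();
      // Robbins-Monro scale adaptation toward the target acceptance
      log_scale += (acc ? (1.0 - target) : -target) / std::sqrt(step / 50.0 + 1.0);
      if (step % adapt_interval == 0 && step >= 2 * d * 10) {
        arma::mat Sigma = M2 / static_cast<double>(step);
        Sigma.diag() += 1e-12 + 1e-8 * arma::square(width / 20.0).max();
        arma::mat C;
        if (arma::chol(C, (5.6644 / d) * Sigma)) { // 2.38^2 / d
          chol_prop = C;
          log_scale = std::min(std::max(log_scale, -8.0), 8.0);
        }
      }
    }

    if (step > burn_in && (step - burn_in) % thinning == 0 && kept < n_keep) {
      draws.row(kept) = theta.t();
      lls[kept] = ll_cur;
      ++kept;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["loglik"] = lls,
    _["accept_rate"] = static_cast<double>(accepted) / proposed
  );
}
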