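#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood of a logistic model at linear predictor eta:
// sum_i y_i * eta_i - log(1 + exp(eta_i))
static double bernoulli_loglik(const std::vector<double>& eta,
                               const IntegerVector& y) {
  double ll = 0.0;
  const int n = (int)eta.size();
  for (int i = 0; i < n; ++i) {
    ll += (y[i] == 1 ? eta[i] : 0.0) - softplus(eta[i]);
  }
  return ll;
}

// Random-walk Metropolis for Bayesian logistic regression with independent
// N(0, prior_sd^2) priors. Joint Gaussian proposals with per-coordinate
// scales: during burn-in the coordinate scales track the chain's running
// standard deviations (diagonal Haario-style adaptation) and a global
// factor is tuned toward ~30% acceptance; after burn-in the kernel is
// fixed. Posterior scales of the coordinates can differ by orders of
// magnitude here (a tightly identified intercept next to a weakly
// identified neighbourhood coefficient), which a single isotropic scale
// cannot serve. All randomness comes from R's RNG, so set.seed() in R
// makes chains reproducible.
//
// [[Rcpp::export]]
List mh_logistic_cpp(NumericMatrix X, IntegerVector y, NumericVector init,
                     int n_iter, int burn_in, int thin,
                     double prior_sd, double proposal_sd, int adapt_window) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (y.size() != n) stop("X and y disagree on the number of records");

  std::vector<double> beta(init.begin(), init.end());
  std::vector<double> beta_prop(p), eta(n, 0.0), eta_prop(n);
  std::vector<double> coord_sd(p, proposal_sd);

  // Welford accumulators for the chain's per-coordinate variance
  std::vector<double> w_mean(beta), w_m2(p, 0.0);
  long w_n = 1;

  for (int j = 0; j < p && n > 0; ++j) {
    const double b = beta[j];
    if (b != 0.0) {
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) eta[i] += b * xj[i];
    }
  }
  const double prior_prec = 1.0 / (prior_sd * prior_sd);
  double ll = bernoulli_loglik(eta, y);
  double lp = 0.0;
  for (int j = 0; j < p; ++j) lp -= 0.5 * prior_prec * beta[j] * beta[j];

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix draws(n_keep, p);
  NumericVector loglik_trace(n_keep);

  double scale = 1.0;
  const double iso_phase = std::min(500, burn_in / 5);  // isotropic warm-up
  int window_accepts = 0, window_len = 0;
  long post_accepts = 0, post_total = 0;
  int keep = 0;

  RNGScope scope;
  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int j = 0; j < p; ++j) {
      beta_prop[j] = beta[j] + scale * coord_sd[j] * norm_rand();
    }

    std::fill(eta_prop.begin(), eta_prop.end(), 0.0);
    for (int j = 0; j < p && n > 0; ++j) {
      const double b = beta_prop[j];
      if (b != 0.0) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta_prop[i] += b * xj[i];
      }
    }
    const double ll_prop = bernoulli_loglik(eta_prop, y);
    double lp_prop = 0.0;
    for (int j = 0; j < p; ++j) {
      lp_prop -= 0.5 * prior_prec * beta_prop[j] * beta_prop[j];
    }

    const bool accept =
      std::log(unif_rand()) < (ll_prop + lp_prop) - (ll + lp);
    if (accept) {
      beta.swap(beta_prop);
      eta.swap(eta_prop);
      ll = ll_prop;
      lp = lp_prop;
    }

    if (iter <= burn_in) {
      // track chain variance for the coordinate scales
      w_n += 1;
      for (int j = 0; j < p; ++j) {
        const double d = beta[j] - w_mean[j];
        w_mean[j] += d / w_n;
        w_m2[j] += d * (beta[j] - w_mean[j]);
      }
      window_accepts += accept ? 1 : 0;
      window_len += 1;
      if (window_len == adapt_window) {
        const double rate = (double)window_accepts / adapt_window;
        if (window_accepts == 0 && scale <= 1e-8) {
          stop("zero acceptance over a full adaptation window despite a "
               "collapsed proposal scale: change proposal_sd");
        }
        scale *= std::exp(rate - 0.3);
        if (iter > iso_phase && w_n > 10) {
          const double factor = 2.38 / std::sqrt((double)p);
          for (int j = 0; j < p; ++j) {
            const double sd_j = std::sqrt(w_m2[j] / (w_n - 1));
            if (sd_j > 1e-12) coord_sd[j] = factor * sd_j;
          }
        }
        window_accepts = 0;
        window_len = 0;
      }
    } else {
      post_accepts += accept ? 1 : 0;
      post_total += 1;
      if ((iter - burn_in) % thin == 0 && keep < n_keep) {
        for (int j = 0; j < p; ++j) draws(keep, j) = beta[j];
        loglik_trace[keep] = ll;
        ++keep;
      }
    }
  }
  if (post_total > 0 && post_accepts == 0) {
    stop("zero acceptance after burn-in: change proposal_sd");
  }

  return List::create(
    _["draws"] = draws(Range(0, keep - 1), _),
    _["loglik"] = loglik_trace[Range(0, keep - 1)],
    _["acceptance_rate"] = post_total > 0
        ? (double)post_accepts / (double)post_total : NA_REAL,
    _["proposal_scale"] = scale);
}
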