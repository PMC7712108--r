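#include <Rcpp.h>
using namespace Rcpp;

// Component-wise Metropolis-Hastings for Gumbel(mu, sigma) data under
// independent Gumbel(mu0, sigma0) x Rayleigh(lambda0) priors.
//
// The mu update is O(1): with S1 = sum_i exp(-(x_i - mu)/sigma) cached,
// sum_i exp(-(x_i - mu*)/sigma) = S1 * exp((mu* - mu)/sigma). The sigma
// update needs one O(n) pass. S1 is recomputed periodically to stop
// multiplicative drift. Uses R's RNG, so set.seed() on the R side makes
// chains bit-reproducible.
//
// Raw length is burn_in + thin * n_keep; draw j (1-based) is kept when
// j > burn_in and (j - burn_in) % thin == 0. Proposal scales adapt toward
// acceptance in [0.2, 0.5] during burn-in only, then freeze.

static double s1_sum(const NumericVector& x, double mu, double sigma) {
  double s = 0.0;
  for (int i = 0; i < x.size(); ++i) s += std::exp(-(x[i] - mu) / sigma);
  return s;
}

// [[Rcpp::export]]
List mh_gumbel_cpp(NumericVector x,
                   double mu0, double sigma0, double lambda0,
                   double v_mu, double v_sigma,
                   double init_mu, double init_sigma,
                   int burn_in, int thin, int n_keep,
                   bool adapt, bool fix_sigma) {
  const int n = x.size();
  const int total = burn_in + thin * n_keep;
  NumericVector mu_out(n_keep), sigma_out(n_keep);

  double mu = init_mu, sigma = init_sigma;
  double S1 = s1_sum(x, mu, sigma);        // sum exp(-(x - mu)/sigma)
  double sum_x = 0.0;
  for (int i = 0; i < n; ++i) sum_x += x[i];

  long acc_mu = 0, acc_sigma = 0;          // post burn-in
  int win_mu = 0, win_sigma = 0, win_n = 0; // adaptation window
  const int win_len = 100;
  int kept = 0;

  for (int j = 1; j <= total; ++j) {
    // --- mu update -------------------------------------------------------
    double mu_star = R::rnorm(mu, v_mu);
    double dmu = mu_star - mu;
    double S1_star = S1 * std::exp(dmu / sigma);
    double log_r =
      (n / sigma) * dmu
      + (mu - mu_star) / sigma0
      + std::exp(-(mu - mu0) / sigma0) - std::exp(-(mu_star - mu0) / sigma0)
      + S1 - S1_star;
    if (R_finite(log_r) || log_r == R_PosInf) {
      if (std::log(R::runif(0.0, 1.0)) < std::min(0.0, log_r)) {
        mu = mu_star;
        S1 = S1_star;
        if (j > burn_in) ++acc_mu;
        ++win_mu;
      }
    }

    // --- sigma update ----------------------------------------------------
    if (!fix_sigma) {
      double sig_star = R::rnorm(sigma, v_sigma);
      if (sig_star > 0.0) {
        double S1_prop = s1_sum(x, mu, sig_star);
        double sum_dev = sum_x - n * mu;
        double log_r_s =
          (n - 1) * (std::log(sigma) - std::log(sig_star))
          + (sigma * sigma - sig_star * sig_star) / (2.0 * lambda0 * lambda0)
          + (1.0 / sigma - 1.0 / sig_star) * sum_dev
          + S1 - S1_prop;
        if (R_finite(log_r_s) || log_r_s == R_PosInf) {
          if (std::log(R::runif(0.0, 1.0)) < std::min(0.0, log_r_s)) {
            sigma = sig_star;
            S1 = S1_prop;
            if (j > burn_in) ++acc_sigma;
            ++win_sigma;
          }
        }
      }
      // sig_star <= 0: certain rejection (prior support), still counts in
      // the adaptation window denominator
    }
    ++win_n;

    // --- burn-in adaptation ---------------------------------------------
    if (adapt && j <= burn_in && win_n == win_len) {
      double r_mu = (double)win_mu / win_len;
      if (r_mu < 0.2) v_mu *= 0.7; else if (r_mu > 0.5) v_mu *= 1.5;
      if (!fix_sigma) {
        double r_s = (double)win_sigma / win_len;
        if (r_s < 0.2) v_sigma *= 0.7; else if (r_s > 0.5) v_sigma *= 1.5;
      }
      win_mu = win_sigma = win_n = 0;
    }
    if (j % 1000 == 0) S1 = s1_sum(x, mu, sigma);  // kill drift

    if (j > burn_in && (j - burn_in) % thin == 0) {
      mu_out[kept] = mu;
      sigma_out[kept] = sigma;
      ++kept;
    }
  }

  double denom = (double)(total - burn_in);
  return List::create(
    _["mu"] = mu_out,
    _["sigma"] = sigma_out,
    _["acc_mu"] = acc_mu / denom,
    _["acc_sigma"] = fix_sigma ? NA_REAL : acc_sigma / denom,
    _["v_mu"] = v_mu,
    _["v_sigma"] = v_sigma);
}
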