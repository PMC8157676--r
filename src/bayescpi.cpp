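#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the single-trait BayesC-pi model
//
//   y = mu * 1 + M alpha + e,  e ~ N(0, sigma2_e I)
//   alpha_j = 0 with probability pi, ~ N(0, sigma2_alpha) otherwise
//   pi ~ Uniform(0,1); variances ~ scaled inverse chi-square.
//
// M is expected column-centered (the intercept absorbs the shift).
// A residual cache e = y - mu - M alpha is maintained across sweeps;
// delta_j and alpha_j are updated jointly, marginalizing alpha_j in the
// inclusion odds. Uses R's RNG, so runs are reproducible via set.seed().

static double draw_scaled_inv_chisq(double df, double scale_sum) {
  // scale_sum = nu * S^2 + data sum of squares; draw scale_sum / chisq(df)
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayescpi_mcmc")]]
List bayescpi_mcmc(NumericMatrix M, NumericVector y,
                   double nu_alpha, double scale_alpha,
                   double nu_e, double scale_e,
                   int n_iter, int burn_in, int thin,
                   double mu, NumericVector alpha_init,
                   IntegerVector delta_init,
                   double pi, double sigma2_alpha, double sigma2_e,
                   bool fix_pi, bool fix_sigma2_alpha, bool fix_sigma2_e) {
  const int n = M.nrow();
  const int p = M.ncol();
  const double pi_lo = 1e-8, pi_hi = 1.0 - 1e-8;

  NumericVector alpha = clone(alpha_init);
  IntegerVector delta = clone(delta_init);

  // column sums of squares (columns are centered upstream)
  NumericVector m2(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    m2[j] = s;
  }

  // residual cache
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    double fit = mu;
    for (int j = 0; j < p; ++j)
      if (alpha[j] != 0.0) fit += M(i, j) * alpha[j];
    e[i] = y[i] - fit;
  }

  const int n_store = (n_iter - burn_in) / thin;
  NumericMatrix alpha_store(n_store, p);
  IntegerMatrix delta_store(n_store, p);
  NumericVector mu_store(n_store), pi_store(n_store),
                s2a_store(n_store), s2e_store(n_store);

  if (pi < pi_lo) pi = pi_lo;
  if (pi > pi_hi) pi = pi_hi;

  int s = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // (1) intercept, flat prior
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(sigma2_e / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    // (2) joint (delta_j, alpha_j) per locus, sequential index order
    const double lambda = sigma2_e / sigma2_alpha;
    const double log_prior_odds = std::log(1.0 - pi) - std::log(pi);
    int m_in = 0;
    double ssq_alpha = 0.0;
    for (int j = 0; j < p; ++j) {
      const double aj_old = alpha[j];
      double rj = m2[j] * aj_old;
      for (int i = 0; i < n; ++i) rj += M(i, j) * e[i];
      const double cj = m2[j] + lambda;
      const double log_odds = log_prior_odds +
        0.5 * (std::log(lambda) - std::log(cj)) +
        rj * rj / (2.0 * sigma2_e * cj);
      double prob_in;
      if (log_odds > 35.0) prob_in = 1.0;
      else if (log_odds < -35.0) prob_in = 0.0;
      else prob_in = 1.0 / (1.0 + std::exp(-log_odds));

      double aj_new;
      if (R::unif_rand() < prob_in) {
        aj_new = rj / cj + R::norm_rand() * std::sqrt(sigma2_e / cj);
        delta[j] = 1;
        ++m_in;
        ssq_alpha += aj_new * aj_new;
      } else {
        aj_new = 0.0;
        delta[j] = 0;
      }
      if (aj_new != aj_old) {
        const double d = aj_old - aj_new;
        for (int i = 0; i < n; ++i) e[i] += M(i, j) * d;
      }
      alpha[j] = aj_new;
    }

    // (3) pi | delta, uniform prior conjugacy
    if (!fix_pi) {
      pi = R::rbeta((double)(p - m_in) + 1.0, (double)m_in + 1.0);
      if (pi < pi_lo) pi = pi_lo;
      if (pi > pi_hi) pi = pi_hi;
    }

    // (4) sigma2_alpha | included effects
    if (!fix_sigma2_alpha) {
      sigma2_alpha = draw_scaled_inv_chisq(
        nu_alpha + m_in, ssq_alpha + nu_alpha * scale_alpha);
    }

    // (5) sigma2_e | residuals
    if (!fix_sigma2_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = draw_scaled_inv_chisq(nu_e + n, sse + nu_e * scale_e);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && s < n_store) {
      alpha_store(s, _) = alpha;
      delta_store(s, _) = delta;
      mu_store[s] = mu;
      pi_store[s] = pi;
      s2a_store[s] = sigma2_alpha;
      s2e_store[s] = sigma2_e;
      ++s;
    }
  }

  return List::create(
    _["alpha"] = alpha_store, _["delta"] = delta_store,
    _["mu"] = mu_store, _["pi"] = pi_store,
    _["sigma2_alpha"] = s2a_store, _["sigma2_e"] = s2e_store,
    _["final_state"] = List::create(
      _["mu"] = mu, _["alpha"] = alpha, _["delta"] = delta,
      _["pi"] = pi, _["sigma2_alpha"] = sigma2_alpha,
      _["sigma2_e"] = sigma2_e));
}
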