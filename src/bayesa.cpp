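#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for BayesA: y = mu + M alpha + e, each
// marker effect alpha_j with its own variance sigma_j^2 carrying a
// scaled-inverse-chi-square(nu, S) prior (scaled-t marginal). Residual
// variance has a scaled-inverse-chi-square(nu_e, S_e) prior. Uses R's
// RNG so chains are reproducible under set.seed().
// [[Rcpp::export]]
List bayesa_gibbs(const NumericMatrix& M, const NumericVector& y,
                  int n_iter, int burn_in, double nu, double S,
                  double nu_e, double S_e) {
  const int n = M.nrow();
  const int p = M.ncol();
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");

  std::vector<double> alpha(p, 0.0), sigma2(p, S), C(p, 0.0);
  double mu = mean(y);
  double sigma_e2 = var(y) * 0.5 + 1e-8;

  const double* Mp = M.begin();  // column-major base pointer
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  for (int j = 0; j < p; ++j) {
    const double* mj = Mp + (size_t)j * n;
    double c = 0.0;
    for (int i = 0; i < n; ++i) c += mj[i] * mj[i];
    C[j] = c;
  }

  std::vector<double> alpha_sum(p, 0.0);
  double mu_sum = 0.0, se_sum = 0.0;
  NumericVector se_trace(n_iter);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i];
    em = em / n + mu;
    double mu_new = R::rnorm(em, std::sqrt(sigma_e2 / n));
    double dmu = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += dmu;
    mu = mu_new;

    // marker effects and their variances
    for (int j = 0; j < p; ++j) {
      double a_old = alpha[j];
      if (C[j] > 0.0) {
        const double* mj = Mp + (size_t)j * n;
        double rhs = 0.0;
        for (int i = 0; i < n; ++i) rhs += mj[i] * e[i];
        rhs += C[j] * a_old;
        double denom = C[j] + sigma_e2 / sigma2[j];
        double a_new = R::rnorm(rhs / denom, std::sqrt(sigma_e2 / denom));
        double da = a_old - a_new;
        if (da != 0.0) for (int i = 0; i < n; ++i) e[i] += mj[i] * da;
        alpha[j] = a_new;
      }
      // sigma_j^2 | alpha_j ~ scaled-inv-chi2(nu + 1, (nu S + alpha^2)/(nu + 1))
      sigma2[j] = (nu * S + alpha[j] * alpha[j]) / R::rchisq(nu + 1.0);
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = (sse + nu_e * S_e) / R::rchisq((double)n + nu_e);
    if (!std::isfinite(sigma_e2) || !std::isfinite(mu)) {
      stop("BayesA sampler diverged at iteration %d (non-finite state)", it + 1);
    }
    se_trace[it] = sigma_e2;

    if (it >= burn_in) {
      for (int j = 0; j < p; ++j) alpha_sum[j] += alpha[j];
      mu_sum += mu;
      se_sum += sigma_e2;
      ++kept;
    }
  }

  NumericVector alpha_mean(p);
  for (int j = 0; j < p; ++j) alpha_mean[j] = alpha_sum[j] / kept;
  return List::create(
    _["posterior_mean_effects"] = alpha_mean,
    _["posterior_mean_mu"] = mu_sum / kept,
    _["posterior_mean_sigma_e2"] = se_sum / kept,
    _["sigma_e2_trace"] = se_trace
  );
}
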