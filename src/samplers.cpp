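#include <Rcpp.h>
using namespace Rcpp;

// draws use R's RNG so set.seed() on the R side makes chains reproducible

static inline double rscaled_inv_chisq(double df, double S) {
  return df * S / R::rchisq(df);
}

// inverse-Gaussian(mu, lambda), Michael-Schucany-Haas
static inline double rinv_gauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// single-site Gibbs update of all marker effects; e is maintained as
// y - mu - Z beta. prior_prec[k] = prior precision of beta_k divided by
// sigma2e scaling handled by caller through `ratio` vector:
// full conditional: beta_k ~ N(rhs / c, sigma2e / c), c = z'z + ratio_k
static void update_effects(const NumericMatrix& Z, NumericVector& e,
                           NumericVector& beta, const NumericVector& zz,
                           const NumericVector& ratio, double sigma2e) {
  int n = Z.nrow(), m = Z.ncol();
  for (int k = 0; k < m; ++k) {
    const double* zk = &Z(0, k);
    double rhs = 0.0;
    for (int i = 0; i < n; ++i) rhs += zk[i] * e[i];
    rhs += zz[k] * beta[k];
    double c = zz[k] + ratio[k];
    double mean = rhs / c;
    double bnew = mean + R::norm_rand() * std::sqrt(sigma2e / c);
    double diff = beta[k] - bnew;
    if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += zk[i] * diff;
    beta[k] = bnew;
  }
}

static double update_mu(NumericVector& e, double mu, double sigma2e) {
  int n = e.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += e[i];
  double mu_new = mu + s / n + R::norm_rand() * std::sqrt(sigma2e / n);
  double diff = mu - mu_new;
  for (int i = 0; i < n; ++i) e[i] += diff;
  return mu_new;
}

// [[Rcpp::export]]
List gibbs_bayes_a(NumericVector y, NumericMatrix Z, int n_iter, int burn_in,
                   int thin, double nu, double Sb, double df_e, double Se) {
  int n = y.size(), m = Z.ncol();
  NumericVector zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, k) * Z(i, k);
    zz[k] = s;
  }
  double mu = mean(y);
  NumericVector beta(m), sigma2b(m, Sb), ratio(m), e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = var(y) / 2.0;
  int n_keep = 0;
  NumericVector beta_sum(m), beta2_sum(m), sigma2b_sum(m);
  double mu_sum = 0.0;
  std::vector<double> s2e_samples;
  for (int it = 0; it < n_iter; ++it) {
    mu = update_mu(e, mu, sigma2e);
    for (int k = 0; k < m; ++k) ratio[k] = sigma2e / sigma2b[k];
    update_effects(Z, e, beta, zz, ratio, sigma2e);
    for (int k = 0; k < m; ++k) {
      sigma2b[k] = rscaled_inv_chisq(nu + 1.0,
                                     (nu * Sb + beta[k] * beta[k]) / (nu + 1.0));
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = rscaled_inv_chisq(n + df_e, (sse + df_e * Se) / (n + df_e));
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      ++n_keep;
      mu_sum += mu;
      for (int k = 0; k < m; ++k) {
        beta_sum[k] += beta[k];
        beta2_sum[k] += beta[k] * beta[k];
        sigma2b_sum[k] += sigma2b[k];
      }
      s2e_samples.push_back(sigma2e);
    }
  }
  NumericVector beta_sd(m);
  for (int k = 0; k < m; ++k) {
    double mmean = beta_sum[k] / n_keep;
    beta_sd[k] = std::sqrt(std::max(beta2_sum[k] / n_keep - mmean * mmean, 0.0));
  }
  return List::create(
    _["mu"] = mu_sum / n_keep,
    _["beta"] = beta_sum / n_keep,
    _["beta_sd"] = beta_sd,
    _["sigma2_marker"] = sigma2b_sum / n_keep,
    _["sigma2e_samples"] = NumericVector(s2e_samples.begin(), s2e_samples.end()),
    _["n_saved"] = n_keep);
}

// [[Rcpp::export]]
List gibbs_bayesian_lasso(NumericVector y, NumericMatrix Z, int n_iter,
                          int burn_in, int thin, double lambda2_init,
                          bool lambda_fixed, double shape, double rate,
                          double df_e, double Se) {
  int n = y.size(), m = Z.ncol();
  NumericVector zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, k) * Z(i, k);
    zz[k] = s;
  }
  double mu = mean(y);
  NumericVector beta(m), tau2(m, 1.0), ratio(m), e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = var(y) / 2.0;
  double lambda2 = lambda2_init;
  int n_keep = 0;
  NumericVector beta_sum(m), beta2_sum(m);
  double mu_sum = 0.0;
  std::vector<double> s2e_samples, l2_samples;
  for (int it = 0; it < n_iter; ++it) {
    mu = update_mu(e, mu, sigma2e);
    // beta_k | tau2_k, sigma2e ~ N(0, tau2_k * sigma2e): ratio = 1 / tau2_k
    for (int k = 0; k < m; ++k) ratio[k] = 1.0 / tau2[k];
    update_effects(Z, e, beta, zz, ratio, sigma2e);
    for (int k = 0; k < m; ++k) {
      double b2 = std::max(beta[k] * beta[k], 1e-16);
      double inv_tau2 = rinv_gauss(std::sqrt(lambda2 * sigma2e / b2), lambda2);
      tau2[k] = 1.0 / std::max(inv_tau2, 1e-12);
    }
    double sse = 0.0, pen = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    for (int k = 0; k < m; ++k) pen += beta[k] * beta[k] / tau2[k];
    sigma2e = rscaled_inv_chisq(n + m + df_e,
                                (sse + pen + df_e * Se) / (n + m + df_e));
    if (!lambda_fixed) {
      double tsum = 0.0;
      for (int k = 0; k < m; ++k) tsum += tau2[k];
      lambda2 = R::rgamma(shape + m, 1.0 / (rate + tsum / 2.0));
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      ++n_keep;
      mu_sum += mu;
      for (int k = 0; k < m; ++k) {
        beta_sum[k] += beta[k];
        beta2_sum[k] += beta[k] * beta[k];
      }
      s2e_samples.push_back(sigma2e);
      l2_samples.push_back(lambda2);
    }
  }
  NumericVector beta_sd(m);
  for (int k = 0; k < m; ++k) {
    double mmean = beta_sum[k] / n_keep;
    beta_sd[k] = std::sqrt(std::max(beta2_sum[k] / n_keep - mmean * mmean, 0.0));
  }
  return List::create(
    _["mu"] = mu_sum / n_keep,
    _["beta"] = beta_sum / n_keep,
    _["beta_sd"] = beta_sd,
    _["sigma2e_samples"] = NumericVector(s2e_samples.begin(), s2e_samples.end()),
    _["lambda2_samples"] = NumericVector(l2_samples.begin(), l2_samples.end()),
    _["n_saved"] = n_keep);
}
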