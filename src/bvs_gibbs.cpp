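#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the two-component normal mixture
// ("spike and slab") SNP-effect model
//   y = mu + sum_j x_j beta_j + e,
//   beta_j | gamma_j ~ N(0, s1)  if gamma_j = 1   (large effects)
//                      N(0, s0)  if gamma_j = 0   (small effects)
//   gamma_j ~ Bernoulli(pi),  e ~ N(0, se I).
// Mixture variances and the residual variance get scaled-inverse-chi-square
// conjugate updates; after each draw the order constraint s1 >= s0 is
// enforced by swapping the two values (relabeling guard).
// Uses R's RNG so results are reproducible from set.seed().
//
// Optional polygenic term: when U (eigenvectors of the kinship matrix)
// and d (eigenvalues) are supplied, u = U v is added to the model with
// independent conditionals v_i ~ N(0, su * d_i); su gets its own
// scaled-inverse-chi-square update from sum(v_i^2 / d_i).
//
// [[Rcpp::export]]
List bvs_gibbs_cpp(NumericVector y, NumericMatrix X, double prior_pi,
                   double df_prior, double scale_s0, double scale_s1,
                   double df_resid, double scale_se,
                   int iterations, int burn_in, int thin,
                   bool update_variances, bool update_mu,
                   double s0_init, double s1_init, double se_init,
                   Nullable<NumericMatrix> U_ = R_NilValue,
                   Nullable<NumericVector> d_ = R_NilValue,
                   double su_scale = 0.0, double su_df = 4.0) {
  const int n = y.size();
  const int M = X.ncol();
  const bool polygenic = U_.isNotNull();
  NumericMatrix U = polygenic ? NumericMatrix(U_) : NumericMatrix(0, 0);
  NumericVector dvals = polygenic ? NumericVector(d_) : NumericVector(0);
  std::vector<double> v(polygenic ? n : 0, 0.0);
  double su = su_scale > 0 ? su_scale : 1.0;

  std::vector<double> xtx(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = update_mu ? Rcpp::mean(y) : 0.0;
  std::vector<double> beta(M, 0.0);
  std::vector<int> gamma(M, 0);
  double s0 = s0_init, s1 = s1_init, se = se_init;

  // residual e = y - mu - X beta (beta starts at 0)
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> pip(M, 0.0), beta_sum(M, 0.0);
  double s0_sum = 0.0, s1_sum = 0.0, se_sum = 0.0, mu_sum = 0.0;
  double su_sum = 0.0;
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= iterations; ++it) {
    for (int j = 0; j < M; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; gamma[j] = 0; continue; }
      // rhs = x_j' r_j with r_j the residual excluding SNP j
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];

      // log marginal likelihood of r_j under each component variance
      double v1 = s1 * xtx[j] + se;
      double v0 = s0 * xtx[j] + se;
      double lf1 = -0.5 * std::log(v1) + 0.5 * rhs * rhs * s1 / (se * v1);
      double lf0 = -0.5 * std::log(v0) + 0.5 * rhs * rhs * s0 / (se * v0);
      double lodds = std::log(prior_pi / (1.0 - prior_pi)) + lf1 - lf0;
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      int g = (R::unif_rand() < p1) ? 1 : 0;

      double sk = g ? s1 : s0;
      double cvar = se / (xtx[j] + se / sk);
      double cmean = rhs / (xtx[j] + se / sk);
      double bnew = R::rnorm(cmean, std::sqrt(cvar));
      double diff = bnew - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      }
      beta[j] = bnew;
      gamma[j] = g;
    }

    if (polygenic) {
      double ssv = 0.0;
      for (int i = 0; i < n; ++i) {
        if (dvals[i] <= 1e-10) { v[i] = 0.0; continue; }
        double rhs = 0.0;
        for (int k = 0; k < n; ++k) rhs += U(k, i) * e[k];
        rhs += v[i];  // columns of U are orthonormal: x'x = 1
        double prior_var = su * dvals[i];
        double cvar = se / (1.0 + se / prior_var);
        double cmean = rhs / (1.0 + se / prior_var);
        double vnew = R::rnorm(cmean, std::sqrt(cvar));
        double diff = vnew - v[i];
        if (diff != 0.0) {
          for (int k = 0; k < n; ++k) e[k] -= U(k, i) * diff;
        }
        v[i] = vnew;
        ssv += vnew * vnew / dvals[i];
      }
      if (update_variances) {
        su = (ssv + su_df * su_scale) / R::rchisq(su_df + n);
      }
    }

    if (update_mu) {
      double esum = 0.0;
      for (int i = 0; i < n; ++i) esum += e[i] + mu;
      double mnew = R::rnorm(esum / n, std::sqrt(se / n));
      double diff = mnew - mu;
      for (int i = 0; i < n; ++i) e[i] -= diff;
      mu = mnew;
    }

    if (update_variances) {
      double ss1 = 0.0, ss0 = 0.0;
      int m1 = 0, m0 = 0;
      for (int j = 0; j < M; ++j) {
        if (gamma[j]) { ss1 += beta[j] * beta[j]; ++m1; }
        else          { ss0 += beta[j] * beta[j]; ++m0; }
      }
      s1 = (ss1 + df_prior * scale_s1) / R::rchisq(df_prior + m1);
      s0 = (ss0 + df_prior * scale_s0) / R::rchisq(df_prior + m0);
      if (s1 < s0) std::swap(s1, s0);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      se = (sse + df_resid * scale_se) / R::rchisq(df_resid + n);
    }

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++kept;
      for (int j = 0; j < M; ++j) {
        pip[j] += gamma[j];
        beta_sum[j] += beta[j];
      }
      s0_sum += s0; s1_sum += s1; se_sum += se; mu_sum += mu;
      su_sum += su;
    }
  }

  NumericVector pip_out(M), beta_out(M);
  for (int j = 0; j < M; ++j) {
    pip_out[j] = pip[j] / kept;
    beta_out[j] = beta_sum[j] / kept;
  }
  return List::create(
    _["pip"] = pip_out, _["post_mean_effect"] = beta_out,
    _["sigma2_0"] = s0_sum / kept, _["sigma2_1"] = s1_sum / kept,
    _["sigma2_e"] = se_sum / kept, _["mu"] = mu_sum / kept,
    _["sigma2_u"] = polygenic ? su_sum / kept : NA_REAL,
    _["kept_samples"] = kept);
}
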