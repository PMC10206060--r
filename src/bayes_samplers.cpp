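#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for Bayesian whole-genome regression.
//
// Model: y = 1*mu + Z beta + e, e ~ N(0, sigma2_e I).
// model = 0 (BayesRR): beta_j ~ N(0, sigma2_b), one shared variance with a
//   scaled-inverse-chi-squared prior.
// model = 1 (BayesB): per-marker indicator with prior mass pi0 at zero
//   effect and, when included, beta_j ~ N(0, sigma2_bj) with a per-marker
//   scaled-inverse-chi-squared prior.
// Variances fixed at fix_vb / fix_ve (when > 0) give degenerate priors,
// used to check the conjugate posterior mean against closed-form ridge.
//
// Uses R's RNG (unif_rand / norm_rand / rchisq) so set.seed() in R makes
// the sampler fully reproducible.

// [[Rcpp::export]]
List gibbs_wgr(NumericMatrix Z, NumericVector y, int model,
               int iterations, int burn_in, double pi0,
               double nu_b, double s_b, double nu_e, double s_e,
               double fix_vb, double fix_ve) {
  const int n = Z.nrow(), p = Z.ncol();
  const bool vb_fixed = fix_vb > 0.0, ve_fixed = fix_ve > 0.0;

  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    xx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), vbj(p, vb_fixed ? fix_vb : s_b);
  double vb = vb_fixed ? fix_vb : s_b;
  double ve = ve_fixed ? fix_ve : (s_e > 0 ? s_e : 1.0);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_keep = iterations - burn_in;
  std::vector<double> b_sum(p, 0.0), b_sq(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0.0, vb_sum = 0.0, ve_sum = 0.0;

  for (int it = 0; it < iterations; ++it) {
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i];
    double mu_new = (esum / n + mu) + norm_rand() * std::sqrt(ve / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      rhs += xx[j] * beta[j];
      double bnew = 0.0;
      if (model == 0) {
        double c = xx[j] + ve / vb;
        bnew = rhs / c + norm_rand() * std::sqrt(ve / c);
      } else {
        double vj = vbj[j];
        // Bayes factor for inclusion with beta_j integrated out
        double lbf = 0.5 * (rhs * rhs * vj / (ve * (xx[j] * vj + ve)) -
                            std::log(xx[j] * vj / ve + 1.0));
        double p1 = (1.0 - pi0) / ((1.0 - pi0) + pi0 * std::exp(-lbf));
        if (unif_rand() < p1) {
          double c = xx[j] + ve / vj;
          bnew = rhs / c + norm_rand() * std::sqrt(ve / c);
          if (it >= burn_in) incl_sum[j] += 1.0;
        }
      }
      double db = bnew - beta[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * db;
      beta[j] = bnew;
    }

    // effect variances
    if (!vb_fixed) {
      if (model == 0) {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
        vb = (nu_b * s_b + ssb) / ::Rf_rchisq(nu_b + p);
      } else {
        for (int j = 0; j < p; ++j) {
          double df = nu_b + (beta[j] != 0.0 ? 1.0 : 0.0);
          vbj[j] = (nu_b * s_b + beta[j] * beta[j]) / ::Rf_rchisq(df);
        }
      }
    }

    // residual variance
    if (!ve_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      ve = (nu_e * s_e + sse) / ::Rf_rchisq(nu_e + n);
    }

    if (it >= burn_in) {
      mu_sum += mu;
      ve_sum += ve;
      double vb_mean = vb;
      if (model == 1) {
        vb_mean = 0.0;
        for (int j = 0; j < p; ++j) vb_mean += vbj[j];
        vb_mean /= std::max(p, 1);
      }
      vb_sum += vb_mean;
      for (int j = 0; j < p; ++j) {
        b_sum[j] += beta[j];
        b_sq[j] += beta[j] * beta[j];
      }
    }
  }

  NumericVector bmean(p), bsd(p), pincl(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = b_sum[j] / n_keep;
    double v = b_sq[j] / n_keep - bmean[j] * bmean[j];
    bsd[j] = std::sqrt(std::max(v, 0.0));
    pincl[j] = (model == 1) ? incl_sum[j] / n_keep : 1.0;
  }
  return List::create(_["mu"] = mu_sum / n_keep,
                      _["effects"] = bmean,
                      _["effect_sd"] = bsd,
                      _["p_include"] = pincl,
                      _["sigma2_b"] = vb_sum / n_keep,
                      _["sigma2_e"] = ve_sum / n_keep);
}
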