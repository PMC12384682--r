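#include <Rcpp.h>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Negative marginal log-likelihood of a logistic regression with one
// Gaussian random intercept per group, by adaptive Gauss-Hermite quadrature.
//
// theta     = c(beta, log_sigma); X n x p; y in {0,1}
// grp_start = 0-based row offsets per group, length G+1; rows sorted by group
// ghx, ghw  = standard Gauss-Hermite nodes/weights for weight exp(-x^2)
//
// Per group the integrand is centred at its conditional mode (inner Newton,
// globally concave) and scaled by the curvature there.
// [[Rcpp::export(name = ".agq_nll")]]
double agq_nll(NumericVector theta, NumericMatrix X, NumericVector y,
               IntegerVector grp_start, NumericVector ghx, NumericVector ghw) {
  const int n = X.nrow(), p = X.ncol(), G = grp_start.size() - 1,
            K = ghx.size();
  const double logsig = theta[p];
  const double sig = std::exp(logsig), sig2 = sig * sig;
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * theta[j];
    eta0[i] = s;
  }
  const double LOG2PI = 1.837877066409345483560659472811;
  double nll = 0.0;
  std::vector<double> lv(K);
  for (int g = 0; g < G; ++g) {
    const int a = grp_start[g], b = grp_start[g + 1];
    double m = 0.0;
    for (int it = 0; it < 100; ++it) {
      double g1 = -m / sig2, g2 = -1.0 / sig2;
      for (int i = a; i < b; ++i) {
        double e = eta0[i] + m;
        double pr = 1.0 / (1.0 + std::exp(-e));
        g1 += y[i] - pr;
        g2 -= pr * (1.0 - pr);
      }
      double step = -g1 / g2;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      m += step;
      if (std::fabs(step) < 1e-12) break;
    }
    double h = 1.0 / sig2;
    for (int i = a; i < b; ++i) {
      double e = eta0[i] + m;
      double pr = 1.0 / (1.0 + std::exp(-e));
      h += pr * (1.0 - pr);
    }
    const double tau = 1.0 / std::sqrt(h);
    double lmax = -1e308;
    for (int k = 0; k < K; ++k) {
      double bk = m + M_SQRT2 * tau * ghx[k];
      double lg = -0.5 * bk * bk / sig2 - 0.5 * LOG2PI - logsig;
      for (int i = a; i < b; ++i) {
        double e = eta0[i] + bk;
        lg += y[i] * e - log1p_exp(e);
      }
      lv[k] = std::log(ghw[k]) + ghx[k] * ghx[k] + lg;
      if (lv[k] > lmax) lmax = lv[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lv[k] - lmax);
    nll -= 0.5 * std::log(2.0) + std::log(tau) + lmax + std::log(s);
  }
  return nll;
}

// Conditional modes (empirical Bayes estimates) of the random intercepts at
// fixed parameters; same inner Newton as the quadrature centring.
// [[Rcpp::export(name = ".agq_modes")]]
NumericVector agq_modes(NumericVector theta, NumericMatrix X, NumericVector y,
                        IntegerVector grp_start) {
  const int p = X.ncol(), G = grp_start.size() - 1, n = X.nrow();
  const double sig2 = std::exp(2.0 * theta[p]);
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * theta[j];
    eta0[i] = s;
  }
  NumericVector out(G);
  for (int g = 0; g < G; ++g) {
    const int a = grp_start[g], b = grp_start[g + 1];
    double m = 0.0;
    for (int it = 0; it < 100; ++it) {
      double g1 = -m / sig2, g2 = -1.0 / sig2;
      for (int i = a; i < b; ++i) {
        double e = eta0[i] + m;
        double pr = 1.0 / (1.0 + std::exp(-e));
        g1 += y[i] - pr;
        g2 -= pr * (1.0 - pr);
      }
      double step = -g1 / g2;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      m += step;
      if (std::fabs(step) < 1e-12) break;
    }
    out[g] = m;
  }
  return out;
}
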