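#include <Rcpp.h>
using namespace Rcpp;

static inline double sgm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Binary hierarchical Gaussian filter, L = 3 or 4 levels.
//
// States: x1 binary outcome, x2 its logit-space tendency, x3 log-volatility
// of x2, x4 (L = 4 only) log-volatility of x3.  Step variance of level j is
// exp(ka[j] * mu_{j+1} + om[j]) for j < L and `th` for the top level.
// Precision-weighted variational updates; a trajectory is rejected (error
// trial returned, no throw) as soon as any posterior precision becomes
// non-positive or non-finite, so the inverter can discard the proposal.
//
// om: tonic log-volatilities, length L (slots 2..L-1 used, 1-based level j
//     at om[j-1]); ka: couplings, length L (slots 1..L-1 used, ka[0] is the
//     logit coupling, fixed 1 in practice); th: top-level random-walk
//     variance; mu0, sa0: initial means/variances for levels 2..L.
// [[Rcpp::export(name = ".hgf_filter_cpp")]]
List hgf_filter_cpp(IntegerVector u, int L, NumericVector om,
                    NumericVector ka, double th,
                    NumericVector mu0, NumericVector sa0) {
  int n = u.size();
  NumericMatrix mu(n, L + 1), sa(n, L + 1), muhat(n, L + 1), da(n, L + 1);
  // working copies of previous-trial posteriors, index 2..L
  std::vector<double> mu_p(L + 1), sa_p(L + 1);
  for (int j = 2; j <= L; ++j) {
    mu_p[j] = mu0[j - 2];
    sa_p[j] = sa0[j - 2];
  }
  int err_trial = 0;
  for (int k = 0; k < n && err_trial == 0; ++k) {
    // predictions
    double muhat2 = mu_p[2];
    double muhat1 = sgm(ka[0] * muhat2);
    double da1 = (double)u[k] - muhat1;

    std::vector<double> v(L + 1), pihat(L + 1), pi(L + 1), mu_n(L + 1),
        dav(L + 1);
    for (int j = 2; j <= L; ++j) {
      // kappa_j couples level j to j+1; 1-based level j sits at ka[j-1]
      v[j] = (j < L) ? std::exp(ka[j - 1] * mu_p[j + 1] + om[j - 1]) : th;
      pihat[j] = 1.0 / (sa_p[j] + v[j]);
      if (!std::isfinite(pihat[j]) || pihat[j] <= 0.0) { err_trial = k + 1; }
    }
    if (err_trial) break;

    // level 2: informed by the binary prediction error
    pi[2] = pihat[2] + ka[0] * ka[0] * muhat1 * (1.0 - muhat1);
    mu_n[2] = muhat2 + ka[0] / pi[2] * da1;
    dav[2] = (1.0 / pi[2] + (mu_n[2] - muhat2) * (mu_n[2] - muhat2)) *
                 pihat[2] - 1.0;

    // levels 3..L: informed by the volatility prediction error from below
    for (int j = 3; j <= L; ++j) {
      double w = v[j - 1] * pihat[j - 1];
      double d = dav[j - 1];
      double kjm1 = ka[j - 2];  // kappa_{j-1}
      pi[j] = pihat[j] +
              0.5 * kjm1 * kjm1 * w * (w + (2.0 * w - 1.0) * d);
      if (!std::isfinite(pi[j]) || pi[j] <= 0.0) { err_trial = k + 1; break; }
      mu_n[j] = mu_p[j] + 0.5 * kjm1 / pi[j] * w * d;
      dav[j] = (1.0 / pi[j] + (mu_n[j] - mu_p[j]) * (mu_n[j] - mu_p[j])) *
                   pihat[j] - 1.0;
    }
    if (err_trial) break;

    muhat(k, 1) = muhat1;
    da(k, 1) = da1;
    for (int j = 2; j <= L; ++j) {
      muhat(k, j) = mu_p[j];
      mu(k, j) = mu_n[j];
      sa(k, j) = 1.0 / pi[j];
      da(k, j) = dav[j];
      if (!std::isfinite(mu_n[j]) || !std::isfinite(sa(k, j)))
        err_trial = k + 1;
      mu_p[j] = mu_n[j];
      sa_p[j] = sa(k, j);
    }
  }
  return List::create(_["mu"] = mu, _["sa"] = sa, _["muhat"] = muhat,
                      _["da"] = da, _["error_trial"] = err_trial);
}

// Rescorla-Wagner delta rule: v_k = v_{k-1} + al * (u_k - v_{k-1}).
// Returns the prediction series v_prev (value before seeing u_k), the
// updated value v, and the prediction error da.
// [[Rcpp::export(name = ".rw_filter_cpp")]]
List rw_filter_cpp(IntegerVector u, double al, double v0) {
  int n = u.size();
  NumericVector v(n), vprev(n), da(n);
  double vp = v0;
  for (int k = 0; k < n; ++k) {
    vprev[k] = vp;
    da[k] = (double)u[k] - vp;
    vp += al * da[k];
    v[k] = vp;
  }
  return List::create(_["v"] = v, _["v_prev"] = vprev, _["da"] = da);
}

// Sutton K1 gain-adaptation rule: a per-trial log learning rate beta is
// moved by the correlation of the current prediction error with a decaying
// trace h of recent updates; al_k = min(exp(beta_k), 1) so the value update
// stays a convex combination.  mu_meta = 0 collapses to Rescorla-Wagner
// with al = al0 exactly.
// [[Rcpp::export(name = ".k1_filter_cpp")]]
List k1_filter_cpp(IntegerVector u, double al0, double mu_meta, double v0) {
  int n = u.size();
  NumericVector v(n), vprev(n), da(n), al(n);
  // track beta as an offset from log(al0): al0 * exp(0) == al0 exactly,
  // so mu_meta = 0 reproduces Rescorla-Wagner bit for bit
  double vp = v0, dbeta = 0.0, h = 0.0;
  for (int k = 0; k < n; ++k) {
    vprev[k] = vp;
    double d = (double)u[k] - vp;
    da[k] = d;
    dbeta += mu_meta * d * h;
    double a = al0 * std::exp(dbeta);
    if (a > 1.0) a = 1.0;
    al[k] = a;
    vp += a * d;
    v[k] = vp;
    h = h * std::max(0.0, 1.0 - a) + a * d;
  }
  return List::create(_["v"] = v, _["v_prev"] = vprev, _["da"] = da,
                      _["alpha"] = al);
}
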