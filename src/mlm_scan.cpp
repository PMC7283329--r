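// Per-marker REML mixed-linear-model scan (EMMA-style eigen rotation).
//
// Model per marker m:  y = X0 g + x_m b + u + e,  u ~ N(0, s2g K),
// e ~ N(0, s2e I).  With K = U D U' and delta = s2e / s2g, rotate by U':
// Var(U'y) = s2g diag(d_i + delta).  Inputs arrive already rotated.  The
// REML log-likelihood is profiled over s2g, leaving a 1-D search in delta:
// a 61-point log10 grid on [-5, 5] followed by golden-section refinement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct RemlFit {
  double ll, delta, sigma2g, beta, se, rss_w;
  bool ok;
};

// REML log-likelihood for fixed delta; X (n x p) and y rotated.
static double reml_ll(const mat& X, const vec& y, const vec& d, double delta,
                      double* beta_last, double* se_last, double* s2g_out) {
  const uword n = X.n_rows, p = X.n_cols;
  vec w = 1.0 / (d + delta);
  mat Xw = X.each_col() % w;
  mat XtWX = X.t() * Xw;
  vec XtWy = Xw.t() * y;
  mat XtWX_inv;
  if (!inv_sympd(XtWX_inv, XtWX)) {
    if (!pinv(XtWX_inv, XtWX)) return -datum::inf;
  }
  vec beta = XtWX_inv * XtWy;
  vec r = y - X * beta;
  double rss = dot(r % w, r);
  if (rss <= 0) return -datum::inf;
  double nf = double(n - p);
  double s2g = rss / nf;
  double logdetV = sum(log(d + delta));
  double sign, logdetX;
  log_det(logdetX, sign, XtWX);
  double ll = -0.5 * (nf * std::log(s2g) + logdetV + logdetX + nf);
  if (beta_last) *beta_last = beta(p - 1);
  if (se_last)   *se_last = std::sqrt(s2g * XtWX_inv(p - 1, p - 1));
  if (s2g_out)   *s2g_out = s2g;
  return ll;
}

static RemlFit reml_optimize(const mat& X, const vec& y, const vec& d) {
  RemlFit out; out.ok = false;
  const int ngrid = 61;
  double best_ll = -datum::inf, best_ld = 0;
  for (int i = 0; i < ngrid; ++i) {
    double ld = -5.0 + 10.0 * i / (ngrid - 1);
    double ll = reml_ll(X, y, d, std::pow(10.0, ld), nullptr, nullptr, nullptr);
    if (ll > best_ll) { best_ll = ll; best_ld = ld; }
  }
  if (!std::isfinite(best_ll)) return out;
  // golden-section refinement on log10(delta) in a bracket around the grid best
  double a = best_ld - 10.0 / (ngrid - 1), b = best_ld + 10.0 / (ngrid - 1);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double c = b - gr * (b - a), e = a + gr * (b - a);
  double fc = reml_ll(X, y, d, std::pow(10.0, c), nullptr, nullptr, nullptr);
  double fe = reml_ll(X, y, d, std::pow(10.0, e), nullptr, nullptr, nullptr);
  for (int it = 0; it < 40 && (b - a) > 1e-6; ++it) {
    if (fc > fe) { b = e; e = c; fe = fc; c = b - gr * (b - a);
      fc = reml_ll(X, y, d, std::pow(10.0, c), nullptr, nullptr, nullptr); }
    else { a = c; c = e; fc = fe; e = a + gr * (b - a);
      fe = reml_ll(X, y, d, std::pow(10.0, e), nullptr, nullptr, nullptr); }
  }
  double ld = (a + b) / 2.0;
  out.delta = std::pow(10.0, ld);
  out.ll = reml_ll(X, y, d, out.delta, &out.beta, &out.se, &out.sigma2g);
  out.ok = std::isfinite(out.ll);
  return out;
}

// [[Rcpp::export]]
Rcpp::List mlm_scan_cpp(const arma::mat& X0r,   // rotated covariates (n x p0), incl. intercept
                        const arma::mat& Gr,    // rotated genotypes (n x m)
                        const arma::vec& yr,    // rotated trait
                        const arma::vec& d) {   // eigenvalues of K
  const uword n = X0r.n_rows, p0 = X0r.n_cols, m = Gr.n_cols;
  vec beta(m), se(m), stat(m), delta(m), r2(m);
  vec df(m);
  mat X(n, p0 + 1);
  X.cols(0, p0 - 1) = X0r;
  for (uword j = 0; j < m; ++j) {
    X.col(p0) = Gr.col(j);
    RemlFit fit = reml_optimize(X, yr, d);
    if (!fit.ok || fit.se <= 0 || !std::isfinite(fit.se)) {
      beta(j) = datum::nan; se(j) = datum::nan; stat(j) = datum::nan;
      delta(j) = datum::nan; r2(j) = datum::nan; df(j) = double(n - p0 - 1);
      continue;
    }
    beta(j) = fit.beta; se(j) = fit.se; delta(j) = fit.delta;
    double t = fit.beta / fit.se;
    stat(j) = t * t;                         // F(1, n - p) Wald statistic
    df(j) = double(n - p0 - 1);
    // incremental variance explained at the full model's delta
    vec w = 1.0 / (d + fit.delta);
    mat X0w = X0r.each_col() % w;
    mat M0;
    if (inv_sympd(M0, X0r.t() * X0w)) {
      vec b0 = M0 * (X0w.t() * yr);
      vec r0 = yr - X0r * b0;
      double rss0 = dot(r0 % w, r0);
      double rss1 = fit.sigma2g * double(n - p0 - 1);
      r2(j) = rss0 > 0 ? std::max(0.0, 1.0 - rss1 / rss0) : datum::nan;
    } else r2(j) = datum::nan;
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta, Rcpp::Named("se") = se,
    Rcpp::Named("fstat") = stat, Rcpp::Named("df2") = df,
    Rcpp::Named("delta") = delta, Rcpp::Named("r2") = r2);
}
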