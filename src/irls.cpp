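#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted logistic IRLS with step-halving, an optional ridge on the
// non-intercept coefficients, and optional Firth bias reduction
// (Jeffreys-prior score adjustment) with FLIC intercept recalibration.
//
// The survey pseudo-MLE runs with ridge = 0, firth = false.  The
// imputation conditionals for the biomarker/self-report variables run
// with firth = true: near-deterministic variable pairs (blood and oral
// tests of one substance) separate the conditional likelihood, and an
// unpenalized fit saturates the chained-imputation transition kernel,
// while a ridge strong enough to tame separation shrinks the coupling
// and biases the stationary distribution.  Firth keeps separated fits
// finite with little shrinkage of identified coefficients; the intercept
// is then recalibrated by one-dimensional ML (FLIC) because the Firth
// adjustment pulls rare-event fitted probabilities toward 1/2.
//
// Step-halving is retrospective: each iteration evaluates the objective
// of the current beta from quantities it needs anyway, and backtracks
// toward the previous iterate when the objective rose.
// [[Rcpp::export(name = ".irls_logistic_cpp")]]
Rcpp::List irls_logistic_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::vec& w, int maxit, double tol,
                             double ridge, bool firth) {
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  double p0 = dot(w, y) / accu(w);
  p0 = std::min(std::max(p0, 1e-6), 1.0 - 1e-6);
  beta(0) = std::log(p0 / (1.0 - p0));
  vec ridgevec(p, fill::value(ridge));
  ridgevec(0) = 0.0;

  vec beta_prev = beta;
  double dev_prev = datum::inf;
  bool converged = false, failed = false;
  int halvings = 0;
  for (int it = 0; it < maxit + halvings && it < 4 * maxit; ++it) {
    vec eta = clamp(X * beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec mu1 = mu % (1.0 - mu);
    vec wt = w % mu1;
    wt.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    mat xtwx = X.t() * (X.each_col() % wt);
    xtwx.diag() += ridgevec;
    // objective of the CURRENT beta
    double dev = -2.0 * (dot(w, y % eta - log1p(exp(eta)))) +
                 dot(ridgevec, beta % beta);
    if (firth) {
      double ld, sgn;
      log_det(ld, sgn, xtwx);
      dev -= ld;
    }
    if (dev > dev_prev + 1e-8) {
      // overshoot: backtrack halfway toward the previous iterate
      beta = (beta + beta_prev) / 2.0;
      ++halvings;
      if (halvings > 30) { failed = true; break; }
      continue;
    }
    vec resid = w % (y - mu);
    if (firth) {
      mat xi;
      if (!inv_sympd(xi, xtwx)) {
        // collinear predictors: jitter the diagonal once
        xtwx.diag() += 1e-3;
        if (!inv_sympd(xi, xtwx)) { failed = true; break; }
      }
      vec h = sum((X * xi) % X, 1) % wt;
      resid += h % (0.5 - mu);
    }
    vec grad = X.t() * resid - ridgevec % beta;
    vec step;
    bool ok = solve(step, xtwx, grad, solve_opts::no_approx);
    if (!ok) {
      xtwx.diag() += 1e-3;
      ok = solve(step, xtwx, grad, solve_opts::no_approx);
    }
    if (!ok || !step.is_finite()) { failed = true; break; }
    beta_prev = beta;
    dev_prev = dev;
    beta += step;
    if (abs(step).max() < tol) { converged = true; break; }
  }
  if (firth && beta.is_finite()) {
    vec off = X * beta - X.col(0) * beta(0);
    double a = beta(0);
    for (int it = 0; it < 25; ++it) {
      vec eta = clamp(off + a, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      double g = dot(w, y - mu);
      double hinf = dot(w, mu % (1.0 - mu));
      if (hinf < 1e-10) break;
      double d = g / hinf;
      if (d > 1.0) d = 1.0; else if (d < -1.0) d = -1.0;
      a += d;
      if (std::abs(d) < 1e-10) break;
    }
    beta(0) = a;
  }
  bool separated = !beta.is_finite() || abs(beta).max() > 15.0;
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("converged") = converged && !failed,
      Rcpp::Named("separated") = separated);
}
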