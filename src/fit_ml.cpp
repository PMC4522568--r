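// Normal-theory ML discrepancy for covariance-structure models
//   F(theta) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p,
//   Sigma = Lambda Psi Lambda' + Theta (diagonal),
// with equality constraints encoded by shared parameter indices, and a
// BFGS minimizer whose line search backtracks out of the non-PD region.
// Parameters are unbounded: negative error variances and |correlation| > 1
// are representable so improper solutions are observable, not masked.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Index maps: L (9 x 4), P (4 x 4), Th (9): 1-based indices into the free
// parameter vector, 0 = fixed at zero (Psi diagonal is fixed at 1).
struct ModelMap {
  imat L;
  imat P;
  ivec Th;
  int p; // number of free parameters
};

static void build_matrices(const vec& th, const ModelMap& mm,
                           mat& Lam, mat& Psi, vec& Tht) {
  const int n = mm.L.n_rows, q = mm.L.n_cols;
  Lam.zeros(n, q);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < q; ++j)
      if (mm.L(i, j) > 0) Lam(i, j) = th(mm.L(i, j) - 1);
  Psi.eye(q, q);
  for (int a = 0; a < q; ++a)
    for (int b = a + 1; b < q; ++b)
      if (mm.P(a, b) > 0) { Psi(a, b) = th(mm.P(a, b) - 1); Psi(b, a) = Psi(a, b); }
  Tht.set_size(n);
  for (int i = 0; i < n; ++i) Tht(i) = th(mm.Th(i) - 1);
}

// Returns false when Sigma(theta) is not positive definite.
static bool eval_fml(const vec& th, const ModelMap& mm, const mat& S,
                     double logdetS, bool need_grad, double& f, vec& g) {
  const int n = S.n_rows;
  mat Lam, Psi;
  vec Tht;
  build_matrices(th, mm, Lam, Psi, Tht);
  mat Sigma = Lam * Psi * Lam.t();
  Sigma.diag() += Tht;

  mat R;
  if (!chol(R, Sigma)) return false;
  double logdet = 2.0 * accu(log(R.diag()));
  mat Rinv = inv(trimatu(R));
  mat Siginv = Rinv * Rinv.t();
  f = logdet + trace(S * Siginv) - logdetS - (double)n;

  if (need_grad) {
    mat G = Siginv - Siginv * S * Siginv; // dF/dSigma, symmetric
    mat dL = 2.0 * (G * Lam * Psi);
    mat dP = Lam.t() * G * Lam;
    g.zeros(mm.p);
    const int q = mm.L.n_cols;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < q; ++j)
        if (mm.L(i, j) > 0) g(mm.L(i, j) - 1) += dL(i, j);
    for (int a = 0; a < q; ++a)
      for (int b = a + 1; b < q; ++b)
        if (mm.P(a, b) > 0) g(mm.P(a, b) - 1) += 2.0 * dP(a, b);
    for (int i = 0; i < n; ++i) g(mm.Th(i) - 1) += G(i, i);
  }
  return true;
}

static ModelMap as_map(const arma::imat& L, const arma::imat& P,
                       const arma::ivec& Th, int p) {
  ModelMap mm;
  mm.L = L; mm.P = P; mm.Th = Th; mm.p = p;
  return mm;
}

// [[Rcpp::export]]
Rcpp::List fml_eval_cpp(const arma::vec& theta, const arma::imat& L,
                        const arma::imat& P, const arma::ivec& Th,
                        const arma::mat& S, bool gradient = true) {
  ModelMap mm = as_map(L, P, Th, theta.n_elem);
  mat Rs;
  if (!chol(Rs, S)) Rcpp::stop("S is not positive definite");
  double logdetS = 2.0 * accu(log(Rs.diag()));
  double f = datum::nan;
  vec g(theta.n_elem, fill::value(datum::nan));
  bool pd = eval_fml(theta, mm, S, logdetS, gradient, f, g);
  return Rcpp::List::create(
    Rcpp::Named("pd") = pd,
    Rcpp::Named("fml") = f,
    Rcpp::Named("gradient") = g);
}

// BFGS with inverse-Hessian updates. Stopping rule: max|grad| < gtol (a
// derivative criterion in the dialect of mainstream SEM software), plus an
// optional relative-parameter-change clause when xtol > 0; otherwise
// non-converged at max_iter.
// The line search (below) only accepts steps where Sigma stays positive
// definite; a fully stalled search ends the fit non-converged.
// [[Rcpp::export]]
Rcpp::List fit_ml_cpp(const arma::imat& L, const arma::imat& P,
                      const arma::ivec& Th, const arma::mat& S,
                      const arma::vec& start, int max_iter = 1000,
                      double gtol = 3e-5, double xtol = -1.0) {
  const int p = start.n_elem;
  ModelMap mm = as_map(L, P, Th, p);
  mat Rs;
  if (!chol(Rs, S)) Rcpp::stop("S is not positive definite");
  double logdetS = 2.0 * accu(log(Rs.diag()));

  vec th = start, g(p), gn(p);
  double f;
  std::string note = "";
  if (!eval_fml(th, mm, S, logdetS, true, f, g)) {
    return Rcpp::List::create(
      Rcpp::Named("par") = th, Rcpp::Named("converged") = false,
      Rcpp::Named("iterations") = 0, Rcpp::Named("fml") = NA_REAL,
      Rcpp::Named("max_grad") = NA_REAL,
      Rcpp::Named("note") = "starting Sigma not positive definite");
  }

  mat H = eye(p, p);
  bool converged = false;
  int iter = 0;
  double relstep = datum::inf;

  while (true) {
    if (g.has_nan()) { note = "gradient not finite"; break; }
    if (max(abs(g)) < gtol && (xtol <= 0.0 || relstep < xtol)) { converged = true; break; }
    if (iter >= max_iter) break; // non-converged at the iteration cap

    vec d = -(H * g);
    double gd = dot(g, d);
    if (!(gd < 0.0)) { H.eye(); d = -g; gd = dot(g, d); }

    // Weak-Wolfe bisection line search (Armijo c1 = 1e-4, curvature
    // c2 = 0.9). Steps where Sigma leaves the PD cone are treated like
    // Armijo failures and halved away; a search that never finds a
    // positive-definite decreasing step ends the fit as non-converged.
    const double c1 = 1e-4, c2 = 0.9;
    double lo = 0.0, hi = datum::inf, alpha = 1.0;
    double fn = f, f_acc = datum::nan, a_acc = 0.0;
    vec thn, gn_acc;
    bool ok = false, have_armijo = false;
    for (int h = 0; h < 60; ++h) {
      thn = th + alpha * d;
      double ftrial;
      bool pd = eval_fml(thn, mm, S, logdetS, true, ftrial, gn);
      if (!pd || !std::isfinite(ftrial) || ftrial > f + c1 * alpha * gd) {
        hi = alpha;
        alpha = 0.5 * (lo + hi);
      } else {
        // Armijo holds; remember the best feasible point seen
        have_armijo = true; a_acc = alpha; f_acc = ftrial; gn_acc = gn;
        if (dot(gn, d) < c2 * gd) { // curvature too steep: step too short
          lo = alpha;
          alpha = std::isinf(hi) ? 2.0 * alpha : 0.5 * (lo + hi);
        } else {
          ok = true; fn = ftrial; break;
        }
      }
      if (hi - lo < 1e-16 * std::max(1.0, hi)) break;
    }
    if (!ok && have_armijo) { // fall back to the last Armijo point
      ok = true; alpha = a_acc; fn = f_acc; gn = gn_acc;
      thn = th + alpha * d;
    }
    if (!ok) { note = "line search stalled (Sigma left the PD cone or no decrease)"; break; }
    vec s = alpha * d;
    vec y = gn - g;
    double sy = dot(s, y);
    if (sy > 1e-12) {
      if (iter == 0) H *= sy / dot(y, y); // scale H0 before the first update
      vec Hy = H * y;
      double yHy = dot(y, Hy);
      H += ((sy + yHy) / (sy * sy)) * (s * s.t()) - (Hy * s.t() + s * Hy.t()) / sy;
    }
    relstep = max(abs(s)) / std::max(1.0, max(abs(thn)));
    th = thn; f = fn; g = gn;
    ++iter;
  }

  return Rcpp::List::create(
    Rcpp::Named("par") = th,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("fml") = f,
    Rcpp::Named("max_grad") = g.has_nan() ? NA_REAL : max(abs(g)),
    Rcpp::Named("note") = note);
}
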