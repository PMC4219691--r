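#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One full cyclic coordinate-descent sweep in covariance form.
// s = G * beta is maintained incrementally, so a coordinate that does not
// move costs O(1) and a coordinate that moves costs O(p).
static double cd_sweep(const arma::mat& G, const arma::vec& c, double lambda,
                       arma::vec& beta, arma::vec& s) {
  const arma::uword p = c.n_elem;
  double max_delta = 0.0;
  for (arma::uword j = 0; j < p; ++j) {
    const double gjj = G(j, j);
    if (gjj <= 0.0) { beta[j] = 0.0; continue; }
    const double r = c[j] - s[j] + gjj * beta[j];
    const double bnew = soft_threshold(r, lambda) / gjj;
    const double d = bnew - beta[j];
    if (d != 0.0) {
      s += G.col(j) * d;
      beta[j] = bnew;
      const double ad = std::fabs(d);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

// Verify the KKT conditions of a candidate active set by solving the
// equality-constrained system G[A,A] x = c[A] - lambda * sign(beta[A])
// exactly, then checking sign consistency on A and the subgradient bound
// |c_j - (G x)_j| <= lambda on the complement. Returns true (and writes
// the polished solution into beta/s) only when the candidate is a genuine
// KKT point, i.e. an exact lasso solution. This escapes the slow tail of
// cyclic descent on strongly correlated designs.
static bool kkt_polish(const arma::mat& G, const arma::vec& c, double lambda,
                       arma::vec& beta, arma::vec& s, double kkt_tol) {
  const arma::uvec active = arma::find(beta != 0.0);
  if (active.n_elem == 0) {
    if (arma::abs(c).max() <= lambda + kkt_tol) { s.zeros(); return true; }
    return false;
  }
  const arma::vec sgn = arma::sign(beta.elem(active));
  const arma::mat GAA = G.submat(active, active);
  arma::vec x;
  const bool ok = arma::solve(x, GAA, c.elem(active) - lambda * sgn,
                              arma::solve_opts::no_approx);
  if (!ok) return false;
  for (arma::uword k = 0; k < x.n_elem; ++k)
    if (x[k] == 0.0 || (x[k] > 0.0) != (sgn[k] > 0.0)) return false;
  const arma::vec s_new = G.cols(active) * x;
  const arma::vec r = c - s_new;
  for (arma::uword j = 0; j < r.n_elem; ++j)
    if (beta[j] == 0.0 && std::fabs(r[j]) > lambda + kkt_tol) return false;
  beta.zeros();
  beta.elem(active) = x;
  s = s_new;
  return true;
}

// Primal active-set iteration: guess the support from the warm start (or
// from the univariate screen |c_j| > lambda when starting at zero), solve
// the equality-restricted system, drop sign-inconsistent coordinates, add
// subgradient violators from the complement, and repeat until the KKT
// conditions hold exactly. Returns false (leaving beta/s untouched) on a
// singular restricted Gram matrix or failure to settle, in which case the
// caller falls back to coordinate descent.
static bool active_set_solve(const arma::mat& G, const arma::vec& c,
                             double lambda, arma::vec& beta, arma::vec& s,
                             double kkt_tol) {
  const arma::uword p = c.n_elem;
  std::vector<char> in(p, 0);
  std::vector<double> sg(p, 0.0);
  const arma::uvec init = arma::find(beta != 0.0);
  if (init.n_elem > 0) {
    for (arma::uword k = 0; k < init.n_elem; ++k) {
      in[init[k]] = 1;
      sg[init[k]] = beta[init[k]] > 0.0 ? 1.0 : -1.0;
    }
  } else {
    for (arma::uword j = 0; j < p; ++j)
      if (G(j, j) > 0.0 && std::fabs(c[j]) > lambda) {
        in[j] = 1;
        sg[j] = c[j] > 0.0 ? 1.0 : -1.0;
      }
  }
  // One exchange (worst sign violation dropped, else worst subgradient
  // violator added) per restricted solve: batch exchanges oscillate on
  // correlated designs, single exchanges settle in roughly |support
  // difference| iterations.
  for (int iter = 0; iter < 500; ++iter) {
    std::vector<arma::uword> av;
    for (arma::uword j = 0; j < p; ++j) if (in[j]) av.push_back(j);
    if (av.empty()) {
      double cmax = 0.0;
      for (arma::uword j = 0; j < p; ++j)
        if (G(j, j) > 0.0 && std::fabs(c[j]) > cmax) cmax = std::fabs(c[j]);
      if (cmax <= lambda + kkt_tol) { beta.zeros(); s.zeros(); return true; }
      return false;
    }
    const arma::uvec A(av);
    arma::vec rhs = c.elem(A);
    for (arma::uword k = 0; k < A.n_elem; ++k) rhs[k] -= lambda * sg[A[k]];
    arma::vec x;
    if (!arma::solve(x, G.submat(A, A), rhs,
                     arma::solve_opts::no_approx + arma::solve_opts::likely_sympd))
      return false;
    double worst_flip = 0.0;
    arma::sword flip_k = -1;
    for (arma::uword k = 0; k < A.n_elem; ++k) {
      const double v = sg[A[k]] * x[k];   // negative when the sign flipped
      if (v <= 0.0 && v <= worst_flip) { worst_flip = v; flip_k = k; }
    }
    if (flip_k >= 0) { in[A[flip_k]] = 0; continue; }
    const arma::vec s_new = G.cols(A) * x;
    double worst_viol = lambda + kkt_tol;
    arma::sword add_j = -1;
    double add_sign = 0.0;
    for (arma::uword j = 0; j < p; ++j)
      if (!in[j] && G(j, j) > 0.0) {
        const double rj = c[j] - s_new[j];
        if (std::fabs(rj) > worst_viol) {
          worst_viol = std::fabs(rj);
          add_j = j;
          add_sign = rj > 0.0 ? 1.0 : -1.0;
        }
      }
    if (add_j >= 0) { in[add_j] = 1; sg[add_j] = add_sign; continue; }
    beta.zeros();
    beta.elem(A) = x;
    s = s_new;
    return true;
  }
  return false;
}

// Solve the intercept-free lasso in covariance form:
//
//   min_b  (1/2) b'Gb - c'b + lambda * ||b||_1
//
// with G = X'X/n and c = X'y/n, equivalent to
// (1/(2n)) ||y - Xb||^2 + lambda ||b||_1 up to a constant in y.
// An exact active-set solve is attempted first; on failure (singular
// restricted Gram matrix, e.g. exactly collinear columns, or active-set
// cycling) the solver falls back to cyclic coordinate descent with
// periodic exact KKT polishing of the settled support. Convergence is
// declared when a KKT point is verified or when the largest coefficient
// update in a sweep falls below `tol`. A zero diagonal entry
// (zero-variance column) pins its coefficient at 0.
// [[Rcpp::export]]
NumericVector cd_lasso_cov(const arma::mat& G, const arma::vec& c,
                           double lambda, const arma::vec& beta0,
                           double tol = 1e-7, int maxit = 100000) {
  const arma::uword p = c.n_elem;
  if (G.n_rows != p || G.n_cols != p)
    stop("dimension mismatch between Gram matrix and gradient vector");
  if (beta0.n_elem != p)
    stop("warm-start vector has wrong length");
  arma::vec beta = beta0;
  arma::vec s = G * beta;
  const double kkt_tol = 1e-9;
  if (active_set_solve(G, c, lambda, beta, s, kkt_tol))
    return NumericVector(beta.begin(), beta.end());
  const int polish_every = 5;
  arma::uvec last_support;
  for (int it = 0; it < maxit; ++it) {
    const double max_delta = cd_sweep(G, c, lambda, beta, s);
    if (max_delta < tol) break;
    if ((it + 1) % polish_every == 0) {
      // attempt the exact solve only once the support has settled
      arma::uvec support = arma::find(beta != 0.0);
      const bool same = support.n_elem == last_support.n_elem &&
        (support.n_elem == 0 || arma::all(support == last_support));
      last_support = support;
      if (same && kkt_polish(G, c, lambda, beta, s, kkt_tol)) break;
    }
  }
  return NumericVector(beta.begin(), beta.end());
}

// Permutation-counter inner loop: for each row of `perms` (a permutation
// of 1..n, 1-based), refit the lasso of the permuted response on X at the
// shared lambda and record which candidate columns (1-based `positions`)
// come out non-zero. Returns the m-vector of counters.
// [[Rcpp::export]]
IntegerVector count_permuted_selections(const arma::mat& X, const arma::vec& y,
                                        double lambda,
                                        const IntegerMatrix& perms,
                                        const IntegerVector& positions,
                                        double tol = 1e-7, int maxit = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) stop("response length does not match predictor rows");
  const arma::mat G = (X.t() * X) / double(n);
  const int B = perms.nrow();
  const int m = positions.size();
  IntegerVector counters(m);
  // warm-start each refit from the previous permuted support: supports at
  // a shared lambda overlap substantially, so the active-set solver only
  // has to perform the few exchanges that differ
  arma::vec yp(n), warm(p, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (arma::uword i = 0; i < n; ++i) yp[i] = y[perms(b, i) - 1];
    const arma::vec cc = (X.t() * yp) / double(n);
    NumericVector beta = cd_lasso_cov(G, cc, lambda, warm, tol, maxit);
    for (int k = 0; k < m; ++k)
      if (beta[positions[k] - 1] != 0.0) ++counters[k];
    warm = arma::vec(beta.begin(), p);
  }
  return counters;
}
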