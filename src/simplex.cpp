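// Dense primal simplex for network-flow linear programs.
//
// Solves  min c'x  s.t.  A x = b,  x >= 0  starting from a supplied feasible
// basis (one basic column per row).  The flow networks built by this package
// always admit such a basis directly (absorption arc + capacity slacks + one
// degenerate assignment arc per compound-peak row), so no phase-1 is needed.
//
// Numerical safeguards: Dantzig pricing with a Bland fallback after long
// degenerate stalls; reduced costs are recomputed from a fresh factorization
// before optimality is declared and periodically during long runs; the final
// basic solution is re-solved from the original data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Tableau {
  mat T;       // m x (n+1): basis-transformed [A | b]
  rowvec z;    // length n reduced costs
  double obj;  // current objective value
};

// Rebuild tableau and reduced costs from scratch for the current basis.
// Returns false if the basis matrix is numerically singular.
bool refactor(const mat& A, const vec& b, const vec& c,
              const uvec& basis, Tableau& tab) {
  mat B = A.cols(basis);
  mat rhs = join_rows(A, b);
  mat sol;
  if (!solve(sol, B, rhs, solve_opts::no_approx)) return false;
  tab.T = std::move(sol);
  vec cb = c.elem(basis);
  tab.z = c.t() - cb.t() * tab.T.cols(0, A.n_cols - 1);
  tab.z.elem(basis).zeros();
  tab.obj = dot(cb, tab.T.col(A.n_cols));
  return true;
}

} // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat& A, const arma::vec& b,
                         const arma::vec& c, const arma::uvec& basis0,
                         int max_iter = 200000, double tol_piv = 1e-10) {
  const uword m = A.n_rows, n = A.n_cols;
  if (b.n_elem != m || c.n_elem != n || basis0.n_elem != m)
    Rcpp::stop("inconsistent LP dimensions");
  if (basis0.max() >= n) Rcpp::stop("basis index out of range");

  uvec basis = basis0;
  std::vector<bool> is_basic(n, false);
  for (uword i = 0; i < m; ++i) is_basic[basis(i)] = true;

  // entering tolerance scaled per column (costs span ~1e-3 .. 1e6)
  vec tol_enter(n);
  for (uword j = 0; j < n; ++j)
    tol_enter(j) = 1e-9 * std::max(1.0, std::fabs(c(j)));

  Tableau tab;
  int status = 0; // 0 optimal, 2 unbounded, 3 iter limit, 4 singular basis
  if (!refactor(A, b, c, basis, tab)) status = 4;

  int iter = 0, degen_run = 0, since_refactor = 0;
  bool bland = false;
  const int refactor_every = 4000;

  while (status == 0 && iter < max_iter) {
    // entering variable
    sword enter = -1;
    double best = 0.0;
    for (uword j = 0; j < n; ++j) {
      if (is_basic[j]) continue;
      double zj = tab.z(j);
      if (zj < -tol_enter(j)) {
        if (bland) { enter = j; break; }
        if (zj < best) { best = zj; enter = j; }
      }
    }
    if (enter < 0) {
      // certify optimality against a fresh factorization
      if (!refactor(A, b, c, basis, tab)) { status = 4; break; }
      since_refactor = 0;
      bool clean = true;
      for (uword j = 0; j < n && clean; ++j)
        if (!is_basic[j] && tab.z(j) < -tol_enter(j)) clean = false;
      if (clean) break;
      continue;
    }

    // ratio test
    sword leave = -1;
    double best_ratio = datum::inf, best_piv = 0.0;
    for (uword i = 0; i < m; ++i) {
      double a = tab.T(i, enter);
      if (a > tol_piv) {
        double ratio = tab.T(i, n) / a;
        if (ratio < best_ratio - 1e-12) {
          best_ratio = ratio; leave = i; best_piv = a;
        } else if (ratio < best_ratio + 1e-12 && leave >= 0) {
          // tie-break: Bland -> smallest basic index; else largest pivot
          if (bland ? (basis(i) < basis(leave)) : (a > best_piv)) {
            leave = i; best_piv = a;
          }
        }
      }
    }
    if (leave < 0) { status = 2; break; }

    if (best_ratio < tol_piv) {
      if (++degen_run > 200) bland = true;
    } else {
      degen_run = 0; bland = false;
    }

    // pivot
    double piv = tab.T(leave, enter);
    tab.T.row(leave) /= piv;
    vec col = tab.T.col(enter);
    col(leave) = 0.0;
    tab.T -= col * tab.T.row(leave);
    tab.z -= tab.z(enter) * tab.T.submat(leave, 0, leave, n - 1);
    is_basic[basis(leave)] = false;
    is_basic[enter] = true;
    basis(leave) = enter;
    tab.z(enter) = 0.0;

    ++iter;
    if (++since_refactor >= refactor_every) {
      if (!refactor(A, b, c, basis, tab)) { status = 4; break; }
      since_refactor = 0;
    }
  }
  if (status == 0 && iter >= max_iter) status = 3;

  // final solution from the original data
  vec x(n, fill::zeros);
  double obj = NA_REAL;
  if (status == 0 || status == 3) {
    mat B = A.cols(basis);
    vec xb;
    if (solve(xb, B, b, solve_opts::no_approx)) {
      for (uword i = 0; i < m; ++i) {
        double v = xb(i);
        x(basis(i)) = (v < 0.0 && v > -1e-7) ? 0.0 : v;
      }
      obj = dot(c, x);
    } else {
      status = 4;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("x") = x,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("status") = status,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("basis") = basis + 1);
}
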