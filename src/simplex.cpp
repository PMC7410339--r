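// Dense two-phase primal simplex for small/medium LPs.
//
// Solves   min/max  c'x
//          s.t.     A x {<=,==,>=} rhs      (rel: -1, 0, +1)
//                   lb <= x <= ub           (entries may be +-Inf)
//
// The problem is brought to standard form internally (variable shifting /
// splitting, slack and artificial columns, finite upper bounds as extra
// rows).  Dantzig pricing with a Bland fallback guards against cycling;
// all comparisons use an absolute tolerance.  Intended for the desk-scale
// systems arising from cut-set MILP relaxations, FVA and feasibility
// probes; not a replacement for an industrial LP code.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double EPS = 1e-9;

enum LpStatus { LP_OPTIMAL = 0, LP_INFEASIBLE = 1, LP_UNBOUNDED = 2, LP_MAXITER = 3 };

// One simplex phase on the full tableau.
// tab: (m+1) x (ncol+1), objective in last row, rhs in last column.
// basis: length m. allowed[j]: whether column j may enter the basis.
static int simplex_core(std::vector<std::vector<double> >& tab,
                        std::vector<int>& basis,
                        const std::vector<bool>& allowed,
                        int m, int ncol, long max_iter) {
  long iter = 0;
  bool bland = false;
  long stall = 0;
  double last_obj = std::numeric_limits<double>::infinity();
  while (true) {
    if (++iter > max_iter) return LP_MAXITER;
    // switch to Bland's rule after a long degenerate stall (anti-cycling)
    double cur = tab[m][ncol];
    if (std::fabs(cur - last_obj) < 1e-12) ++stall; else stall = 0;
    last_obj = cur;
    if (stall > 200) bland = true;

    // pricing
    int enter = -1;
    double best = -EPS;
    for (int j = 0; j < ncol; ++j) {
      if (!allowed[j]) continue;
      double rc = tab[m][j];
      if (rc < -EPS) {
        if (bland) { enter = j; break; }
        if (rc < best) { best = rc; enter = j; }
      }
    }
    if (enter < 0) return LP_OPTIMAL;

    // ratio test, two passes: exact minimum ratio, then tie-break among the
    // near-minimal rows (largest pivot for stability; smallest basis index
    // under Bland's rule, which needs the exact minimum to guarantee
    // termination)
    double best_ratio = std::numeric_limits<double>::infinity();
    for (int i = 0; i < m; ++i) {
      double a = tab[i][enter];
      if (a > EPS) {
        double rhsv = tab[i][ncol];
        if (rhsv < 0) rhsv = 0;  // clamp drift
        double ratio = rhsv / a;
        if (ratio < best_ratio) best_ratio = ratio;
      }
    }
    if (!std::isfinite(best_ratio)) return LP_UNBOUNDED;
    int leave = -1;
    double best_piv = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = tab[i][enter];
      if (a > EPS) {
        double rhsv = tab[i][ncol];
        if (rhsv < 0) rhsv = 0;
        double ratio = rhsv / a;
        if (ratio <= best_ratio + 1e-9) {
          if (bland) {
            if (leave < 0 || basis[i] < basis[leave]) leave = i;
          } else if (a > best_piv) {
            best_piv = a;
            leave = i;
          }
        }
      }
    }

    // pivot
    double piv = tab[leave][enter];
    std::vector<double>& prow = tab[leave];
    for (int j = 0; j <= ncol; ++j) prow[j] /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = tab[i][enter];
      if (std::fabs(f) < EPS) continue;
      std::vector<double>& row = tab[i];
      for (int j = 0; j <= ncol; ++j) row[j] -= f * prow[j];
    }
    basis[leave] = enter;
  }
}

// [[Rcpp::export(name = ".lp_solve_cpp")]]
List lp_solve_cpp(NumericVector obj, NumericMatrix A, IntegerVector rel,
                  NumericVector rhs, NumericVector lb, NumericVector ub,
                  bool maximize) {
  const int n = obj.size();
  const int m0 = A.nrow();
  if (A.ncol() != n && !(m0 == 0 && n >= 0))
    stop("A has %d columns but objective has length %d", A.ncol(), n);

  // --- variable transformation to y >= 0 -----------------------------------
  // kind 0: x = lb + y            (lb finite)
  // kind 1: x = ub - y            (lb = -Inf, ub finite)
  // kind 2: x = y+ - y-           (free)
  std::vector<int> kind(n), col_of(n);
  std::vector<double> shift(n);
  int ncols = 0;
  int n_ubrow = 0;
  for (int j = 0; j < n; ++j) {
    bool lf = std::isfinite(lb[j]), uf = std::isfinite(ub[j]);
    if (lf && uf && ub[j] - lb[j] < -EPS)
      stop("lower bound exceeds upper bound for variable %d", j + 1);
    if (lf) {
      kind[j] = 0; shift[j] = lb[j]; col_of[j] = ncols; ncols += 1;
      if (uf && ub[j] - lb[j] < std::numeric_limits<double>::infinity()) ++n_ubrow;
    } else if (uf) {
      kind[j] = 1; shift[j] = ub[j]; col_of[j] = ncols; ncols += 1;
    } else {
      kind[j] = 2; shift[j] = 0.0; col_of[j] = ncols; ncols += 2;
    }
  }

  const int m = m0 + n_ubrow;
  // structural columns + one slack per row (equality rows get none, but
  // reserving per-row keeps indexing trivial; unused slots stay disallowed)
  std::vector<int> slack_col(m, -1);
  int ncol_struct = ncols;
  int nslack = 0;
  std::vector<int> row_rel(m);
  for (int i = 0; i < m0; ++i) row_rel[i] = rel[i];
  for (int i = m0; i < m; ++i) row_rel[i] = -1;  // ub rows are <=
  for (int i = 0; i < m; ++i) if (row_rel[i] != 0) ++nslack;
  const int ncol = ncol_struct + nslack + m;  // + artificials (one per row)
  const int art0 = ncol_struct + nslack;

  std::vector<std::vector<double> > tab(m + 1, std::vector<double>(ncol + 1, 0.0));

  // structural part, transformed rhs
  int ubr = m0;
  for (int i = 0; i < m0; ++i) {
    double b = rhs[i];
    for (int j = 0; j < n; ++j) {
      double a = A(i, j);
      if (a == 0.0) continue;
      b -= a * shift[j];
      if (kind[j] == 0) tab[i][col_of[j]] += a;
      else if (kind[j] == 1) tab[i][col_of[j]] -= a;
      else { tab[i][col_of[j]] += a; tab[i][col_of[j] + 1] -= a; }
    }
    tab[i][ncol] = b;
  }
  for (int j = 0; j < n; ++j) {
    if (kind[j] == 0 && std::isfinite(ub[j])) {
      tab[ubr][col_of[j]] = 1.0;
      tab[ubr][ncol] = ub[j] - lb[j];
      ++ubr;
    }
  }

  // slacks; then fix sign so rhs >= 0
  int sc = ncol_struct;
  for (int i = 0; i < m; ++i) {
    if (row_rel[i] == -1) { tab[i][sc] = 1.0; slack_col[i] = sc++; }
    else if (row_rel[i] == 1) { tab[i][sc] = -1.0; slack_col[i] = sc++; }
  }
  for (int i = 0; i < m; ++i) {
    if (tab[i][ncol] < 0) {
      for (int j = 0; j <= ncol; ++j) tab[i][j] = -tab[i][j];
    }
  }

  // phase 1: artificial basis, minimize their sum
  std::vector<int> basis(m);
  std::vector<bool> allowed(ncol, true);
  for (int i = 0; i < m; ++i) {
    // a positively-signed slack can serve as the initial basic variable
    if (slack_col[i] >= 0 && tab[i][slack_col[i]] > 0.5) {
      basis[i] = slack_col[i];
      allowed[art0 + i] = false;  // artificial never created
    } else {
      tab[i][art0 + i] = 1.0;
      basis[i] = art0 + i;
      for (int j = 0; j <= ncol; ++j) tab[m][j] -= tab[i][j];
      tab[m][art0 + i] += 1.0;
    }
  }

  const long max_iter = 20000L + 200L * (long)(m + ncol);
  int st = simplex_core(tab, basis, allowed, m, ncol, max_iter);
  if (st == LP_MAXITER)
    return List::create(_["status"] = (int)LP_MAXITER, _["x"] = R_NilValue, _["objval"] = NA_REAL);
  if (-tab[m][ncol] > 1e-7)  // artificials could not be driven to zero
    return List::create(_["status"] = (int)LP_INFEASIBLE, _["x"] = R_NilValue, _["objval"] = NA_REAL);

  // drive residual basic artificials out (degenerate pivots) or mark rows redundant
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= art0) {
      int enter = -1;
      for (int j = 0; j < art0; ++j) {
        if (std::fabs(tab[i][j]) > 1e-7) { enter = j; break; }
      }
      if (enter >= 0) {
        double piv = tab[i][enter];
        for (int j = 0; j <= ncol; ++j) tab[i][j] /= piv;
        for (int k = 0; k <= m; ++k) {
          if (k == i) continue;
          double f = tab[k][enter];
          if (std::fabs(f) < EPS) continue;
          for (int j = 0; j <= ncol; ++j) tab[k][j] -= f * tab[i][j];
        }
        basis[i] = enter;
      }
      // else: redundant row; artificial stays basic at value ~0 (harmless)
    }
  }
  // artificials are never allowed to re-enter
  for (int j = art0; j < ncol; ++j) allowed[j] = false;

  // phase 2 objective (minimization; negate c if maximizing)
  for (int j = 0; j <= ncol; ++j) tab[m][j] = 0.0;
  std::vector<double> cost(ncol, 0.0);
  for (int j = 0; j < n; ++j) {
    double c = maximize ? -obj[j] : obj[j];
    if (c == 0.0) continue;
    if (kind[j] == 0) cost[col_of[j]] += c;
    else if (kind[j] == 1) cost[col_of[j]] -= c;
    else { cost[col_of[j]] += c; cost[col_of[j] + 1] -= c; }
  }
  for (int j = 0; j < ncol; ++j) tab[m][j] = cost[j];
  for (int i = 0; i < m; ++i) {
    double cb = (basis[i] < ncol) ? cost[basis[i]] : 0.0;
    if (cb == 0.0) continue;
    for (int j = 0; j <= ncol; ++j) tab[m][j] -= cb * tab[i][j];
  }

  st = simplex_core(tab, basis, allowed, m, ncol, max_iter);
  if (st == LP_UNBOUNDED)
    return List::create(_["status"] = (int)LP_UNBOUNDED, _["x"] = R_NilValue, _["objval"] = NA_REAL);
  if (st == LP_MAXITER)
    return List::create(_["status"] = (int)LP_MAXITER, _["x"] = R_NilValue, _["objval"] = NA_REAL);

  // recover solution
  std::vector<double> y(ncol, 0.0);
  for (int i = 0; i < m; ++i)
    if (basis[i] < ncol) y[basis[i]] = tab[i][ncol];
  NumericVector x(n);
  for (int j = 0; j < n; ++j) {
    if (kind[j] == 0) x[j] = shift[j] + y[col_of[j]];
    else if (kind[j] == 1) x[j] = shift[j] - y[col_of[j]];
    else x[j] = y[col_of[j]] - y[col_of[j] + 1];
  }
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += obj[j] * x[j];
  return List::create(_["status"] = (int)LP_OPTIMAL, _["x"] = x, _["objval"] = objval);
}
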