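#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dense bounded-variable two-phase primal simplex.
//
// Solves   maximize  c'x   s.t.  A x = b,  lb <= x <= ub
// with all bounds finite (the R wrapper clamps +/-Inf to a large box).
// Phase 1 drives artificial variables out of the basis; nonbasic
// variables rest at one of their bounds.  Dantzig pricing with a
// permanent switch to Bland's rule once the objective stalls, which is
// sufficient anti-cycling for the problem sizes this package generates.
//
// status: 0 optimal, 1 infeasible, 2 iteration limit, 3 unbounded.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List simplex_solve(NumericMatrix A, NumericVector b, NumericVector c,
                   NumericVector lb, NumericVector ub,
                   double tol = 1e-9, int maxit = 50000) {
  const int m = A.nrow(), n = A.ncol();
  const int N = n + m;  // structural + artificial variables

  // column-major copy of [A | I_art] with artificial signs fixed below
  std::vector<double> T((size_t)m * N, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) T[(size_t)j * m + i] = A(i, j);

  std::vector<double> L(N), U(N);
  for (int j = 0; j < n; ++j) { L[j] = lb[j]; U[j] = ub[j]; }
  for (int j = n; j < N; ++j) { L[j] = 0.0; U[j] = INF; }

  // vstat: 0 nonbasic at lower, 1 nonbasic at upper, 2 basic
  std::vector<int> vstat(N, 0);
  std::vector<int> basis(m);
  std::vector<double> beta(m);  // B^{-1} b

  // start structural variables at the bound of smaller magnitude
  for (int j = 0; j < n; ++j)
    vstat[j] = (std::fabs(U[j]) < std::fabs(L[j])) ? 1 : 0;

  // residual r = b - A x0 decides artificial signs; basis = artificials
  double art0 = 0.0;  // total initial infeasibility
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < n; ++j) {
      double xv = (vstat[j] == 1) ? U[j] : L[j];
      r -= T[(size_t)j * m + i] * xv;
    }
    art0 += std::fabs(r);
    double sgn = (r >= 0.0) ? 1.0 : -1.0;
    // artificial column = sgn * e_i; scale row i by sgn so B^{-1} = I
    if (sgn < 0.0) {
      for (int j = 0; j < n; ++j) T[(size_t)j * m + i] = -T[(size_t)j * m + i];
      beta[i] = -b[i];
    } else beta[i] = b[i];
    T[(size_t)(n + i) * m + i] = 1.0;
    basis[i] = n + i;
    vstat[n + i] = 2;
  }

  std::vector<double> xB(m), cost(N, 0.0), zrow(N);
  bool phase1 = true;
  for (int j = n; j < N; ++j) cost[j] = -1.0;  // maximize -sum(artificials)

  // when the all-at-nearest-bound start already satisfies A x = b (always
  // the case for the split pFBA problems, whose variables all start at 0),
  // phase 1 has nothing to do: pin the artificials at zero and go straight
  // to the real objective
  if (art0 <= tol) {
    phase1 = false;
    for (int j = 0; j < N; ++j) cost[j] = (j < n) ? c[j] : 0.0;
    for (int j = n; j < N; ++j) U[j] = 0.0;
  }

  bool bland = false;
  double last_obj = -INF;
  int stall = 0;
  int iter = 0;
  int status = 2;

  while (iter++ < maxit) {
    // basic variable values: xB = beta - sum_j T_j * xN_j
    for (int i = 0; i < m; ++i) xB[i] = beta[i];
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == 2) continue;
      double xv = (vstat[j] == 1) ? U[j] : L[j];
      if (xv == 0.0) continue;
      const double *col = &T[(size_t)j * m];
      for (int i = 0; i < m; ++i) xB[i] -= col[i] * xv;
    }

    // reduced costs z_j = c_j - cB' T_j
    std::vector<double> cB(m);
    for (int i = 0; i < m; ++i) cB[i] = cost[basis[i]];
    double obj = 0.0;
    for (int i = 0; i < m; ++i) obj += cB[i] * xB[i];
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == 2 || j >= n) { zrow[j] = 0.0; continue; }
      // artificial columns are skipped: they never enter, and optimality
      // detection only needs the structural reduced costs
      double xv = (vstat[j] == 1) ? U[j] : L[j];
      if (xv != 0.0) obj += cost[j] * xv;
      double z = cost[j];
      const double *col = &T[(size_t)j * m];
      for (int i = 0; i < m; ++i) z -= cB[i] * col[i];
      zrow[j] = z;
    }

    if (obj <= last_obj + 1e-12) { if (++stall > 200) bland = true; }
    else { stall = 0; last_obj = obj; }

    // entering variable (maximization)
    int enter = -1; double best = tol;
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == 2) continue;
      if (j >= n) continue;                 // artificials never (re-)enter
      if (U[j] - L[j] < tol) continue;      // fixed variable
      double viol = 0.0;
      if (vstat[j] == 0 && zrow[j] > tol) viol = zrow[j];
      else if (vstat[j] == 1 && zrow[j] < -tol) viol = -zrow[j];
      else continue;
      if (bland) { enter = j; break; }
      if (viol > best) { best = viol; enter = j; }
    }

    if (enter < 0) {  // optimal for current phase
      if (phase1) {
        double art = 0.0;
        for (int i = 0; i < m; ++i) if (basis[i] >= n) art += std::fabs(xB[i]);
        for (int j = n; j < N; ++j) if (vstat[j] == 1) art += U[j];
        if (art > 1e-7) { status = 1; break; }
        // switch to phase 2
        phase1 = false;
        for (int j = 0; j < N; ++j) cost[j] = (j < n) ? c[j] : 0.0;
        // pin all artificials at 0: basic ones leave via degenerate pivots
        for (int j = n; j < N; ++j) { U[j] = 0.0; if (vstat[j] != 2) vstat[j] = 0; }
        last_obj = -INF; stall = 0; bland = false;
        continue;
      }
      status = 0;
      break;
    }

    const int dir = (vstat[enter] == 0) ? 1 : -1;
    const double *col = &T[(size_t)enter * m];

    // ratio test: bound flip vs basic variable hitting a bound
    double tbest = U[enter] - L[enter];  // bound-flip step (may be INF)
    int leave = -1; double leave_to_upper = 0.0;
    for (int i = 0; i < m; ++i) {
      double g = -dir * col[i];
      if (std::fabs(g) <= tol) continue;
      int k = basis[i];
      double t;
      double hits_upper;
      if (g > 0) { t = (U[k] - xB[i]) / g; hits_upper = 1.0; }
      else       { t = (L[k] - xB[i]) / g; hits_upper = 0.0; }
      if (t == INF) continue;
      if (t < 0) t = 0;  // numerical slop on an already-tight basic
      bool better = (t < tbest - 1e-12);
      bool tie = (std::fabs(t - tbest) <= 1e-12);
      // tie-break: prefer kicking artificials out, then Bland's smallest index
      if (tie && leave >= 0) {
        int kc = basis[leave];
        if ((k >= n) != (kc >= n)) better = (k >= n);
        else better = (k < kc);
      } else if (tie && leave < 0) {
        better = true;
      }
      if (better) { tbest = t; leave = i; leave_to_upper = hits_upper; }
    }

    if (tbest == INF) { status = 3; break; }  // unbounded direction

    if (leave < 0) {  // bound flip, no basis change
      vstat[enter] = 1 - vstat[enter];
      continue;
    }

    // pivot on (leave, enter); only columns with a nonzero pivot-row entry
    // change, which the stoichiometric tableaus keep sparse
    double piv = col[leave];
    for (int j = 0; j < N; ++j) T[(size_t)j * m + leave] /= piv;
    beta[leave] /= piv;
    std::vector<int> live;
    live.reserve(64);
    for (int j = 0; j < N; ++j)
      if (T[(size_t)j * m + leave] != 0.0) live.push_back(j);
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = T[(size_t)enter * m + i];
      if (f == 0.0) continue;
      for (int jj : live) {
        double *pcol = &T[(size_t)jj * m];
        pcol[i] -= f * pcol[leave];
      }
      beta[i] -= f * beta[leave];
    }
    int out = basis[leave];
    vstat[out] = (leave_to_upper > 0.5) ? 1 : 0;
    basis[leave] = enter;
    vstat[enter] = 2;
  }

  // recover solution
  NumericVector x(n);
  for (int i = 0; i < m; ++i) xB[i] = beta[i];
  for (int j = 0; j < N; ++j) {
    if (vstat[j] == 2) continue;
    double xv = (vstat[j] == 1) ? U[j] : L[j];
    if (xv == 0.0) continue;
    const double *col = &T[(size_t)j * m];
    for (int i = 0; i < m; ++i) xB[i] -= col[i] * xv;
  }
  for (int j = 0; j < n; ++j)
    x[j] = (vstat[j] == 2) ? 0.0 : ((vstat[j] == 1) ? U[j] : L[j]);
  for (int i = 0; i < m; ++i) if (basis[i] < n) x[basis[i]] = xB[i];
  double objective = 0.0;
  for (int j = 0; j < n; ++j) objective += c[j] * x[j];

  return List::create(_["status"] = status, _["objective"] = objective,
                      _["x"] = x, _["iterations"] = iter);
}
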