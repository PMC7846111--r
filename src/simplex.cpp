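#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Dense two-phase primal simplex with Bland's rule (anti-cycling).
//
// Solves  min c'x  s.t.  A x {<=,=,>=} b,  x >= 0.
// Problem sizes here are tiny (tens of variables), so a dense tableau is
// faster and more predictable than sparse machinery.  Bland's rule is slow
// in theory but immune to cycling, which matters because metabolic LPs are
// highly degenerate.
//
// dir codes per row: -1 (<=), 0 (=), +1 (>=).
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double TOL = 1e-9;

// [[Rcpp::export]]
List cpp_simplex(NumericVector obj, NumericMatrix A, NumericVector b,
                 IntegerVector dir, int maxit = 20000) {
  const int m = A.nrow();
  const int n = A.ncol();
  if (obj.size() != n || b.size() != m || dir.size() != m)
    stop("inconsistent LP dimensions");

  // column layout: [ x (n) | slacks (m, zero col when dir==0) | artificials (m) ]
  const int ns = m;            // one (possibly unused) slack slot per row
  const int N = n + ns + m;    // total structural columns
  const int bcol = N;          // RHS column index

  // tableau: m constraint rows + 2 objective rows (phase1, phase2)
  std::vector<std::vector<double> > T(m + 2, std::vector<double>(N + 1, 0.0));

  for (int i = 0; i < m; ++i) {
    double s = (b[i] < 0.0) ? -1.0 : 1.0;   // keep RHS non-negative
    for (int j = 0; j < n; ++j) T[i][j] = s * A(i, j);
    T[i][bcol] = s * b[i];
    int d = dir[i] * (s < 0 ? -1 : 1);
    if (d == -1) T[i][n + i] = 1.0;         // slack
    else if (d == 1) T[i][n + i] = -1.0;    // surplus
    T[i][n + ns + i] = 1.0;                 // artificial (always present)
  }

  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = n + ns + i;

  // phase-1 objective row: minimize sum of artificials.
  // reduced costs r_j = c_j - c_B' B^{-1} A_j; with c = e on artificials and
  // basis = artificials, r_j = -sum_i T[i][j] for structural j.
  const int P1 = m, P2 = m + 1;
  for (int j = 0; j <= N; ++j) {
    double acc = 0.0;
    for (int i = 0; i < m; ++i) acc += T[i][j];
    T[P1][j] = -acc;
  }
  for (int i = n + ns; i < N; ++i) T[P1][i] += 1.0; // c_j = 1 on artificials
  for (int j = 0; j < n; ++j) T[P2][j] = obj[j];    // phase-2 costs (not yet priced)

  std::vector<bool> allowed(N, true);

  int it = 0;
  int phase = 1;
  int objrow = P1;

  while (true) {
    // Bland: entering = smallest allowed index with reduced cost < -TOL
    int enter = -1;
    for (int j = 0; j < N; ++j) {
      if (!allowed[j]) continue;
      if (T[objrow][j] < -TOL) { enter = j; break; }
    }
    if (enter < 0) {
      if (phase == 1) {
        double p1 = -T[P1][bcol]; // phase-1 objective value
        if (p1 > 1e-7) {
          return List::create(_["status"] = 1, _["x"] = NumericVector(n),
                              _["value"] = NA_REAL, _["iter"] = it);
        }
        // drive artificials out of the basis where possible
        for (int i = 0; i < m; ++i) {
          if (basis[i] >= n + ns) {
            int piv = -1;
            for (int j = 0; j < n + ns; ++j)
              if (std::fabs(T[i][j]) > 1e-8) { piv = j; break; }
            if (piv >= 0) {
              // pivot (i, piv)
              double p = T[i][piv];
              for (int j = 0; j <= N; ++j) T[i][j] /= p;
              for (int r = 0; r < m + 2; ++r) {
                if (r == i) continue;
                double f = T[r][piv];
                if (f != 0.0)
                  for (int j = 0; j <= N; ++j) T[r][j] -= f * T[i][j];
              }
              basis[i] = piv;
            }
            // else: redundant row; artificial stays basic at zero
          }
        }
        for (int j = n + ns; j < N; ++j) allowed[j] = false;
        // phase-2 reduced costs are already canonical: the P2 row started as
        // the raw costs under the all-artificial basis (cost zero) and was
        // updated by every pivot since.
        phase = 2;
        objrow = P2;
        continue;
      }
      break; // phase 2 optimal
    }

    // ratio test; ties broken toward smallest basis index (Bland)
    int leave = -1;
    double best = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = T[i][enter];
      if (a > TOL) {
        double ratio = T[i][bcol] / a;
        if (leave < 0 || ratio < best - TOL ||
            (ratio < best + TOL && basis[i] < basis[leave])) {
          leave = i;
          best = ratio;
        }
      }
    }
    if (leave < 0) {
      // a column whose reduced cost is barely negative but with no
      // positive pivot entry is numerically null in phase 1 (the phase-1
      // objective is bounded below by zero), and with strictly positive
      // costs the same holds in phase 2: drop it and move on
      if (phase == 1 || T[objrow][enter] > -1e-7) {
        allowed[enter] = false;
        continue;
      }
      return List::create(_["status"] = 2, _["x"] = NumericVector(n),
                          _["value"] = NA_REAL, _["iter"] = it);
    }

    double p = T[leave][enter];
    for (int j = 0; j <= N; ++j) T[leave][j] /= p;
    for (int r = 0; r < m + 2; ++r) {
      if (r == leave) continue;
      double f = T[r][enter];
      if (f != 0.0)
        for (int j = 0; j <= N; ++j) T[r][j] -= f * T[leave][j];
    }
    basis[leave] = enter;

    if (++it > maxit)
      return List::create(_["status"] = 3, _["x"] = NumericVector(n),
                          _["value"] = NA_REAL, _["iter"] = it);
  }

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T[i][bcol];
  double value = 0.0;
  for (int j = 0; j < n; ++j) value += obj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["value"] = value,
                      _["iter"] = it);
}
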