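#include <Rcpp.h>
using namespace Rcpp;

// Gaussian elimination with partial pivoting for the small (p <= items)
// active-set KKT systems. Returns false when numerically singular.
static bool solve_small(std::vector<double> A, std::vector<double> b,
                        int m, std::vector<double> &x) {
  for (int col = 0; col < m; ++col) {
    int piv = col;
    double best = std::fabs(A[col * m + col]);
    for (int r = col + 1; r < m; ++r) {
      double v = std::fabs(A[col * m + r]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != col) {
      for (int c = 0; c < m; ++c) std::swap(A[c * m + col], A[c * m + piv]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < m; ++r) {
      double f = A[col * m + r] / A[col * m + col];
      if (f == 0.0) continue;
      for (int c = col; c < m; ++c) A[c * m + r] -= f * A[c * m + col];
      b[r] -= f * b[col];
    }
  }
  x.assign(m, 0.0);
  for (int r = m - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < m; ++c) s -= A[c * m + r] * x[c];
    x[r] = s / A[r * m + r];
  }
  return true;
}

// Lasso solutions along a descending penalty grid from Gram quantities.
//
// Minimizes (1/(2n)) * ||y - X b||^2 + lambda * ||b||_1 given XtX = X'X and
// Xty = X'y for centered X and y (no intercept needed). Per penalty: cyclic
// coordinate descent sweeps (warm-started from the previous solution); after
// each sweep the active-set stationarity system
//   (XtX b)_A = (Xty)_A - n * lambda * sign(b_A)
// is solved exactly and accepted when the signs are self-consistent and the
// inactive coordinates satisfy |Xty_j - (XtX b)_j| <= n * lambda, which
// yields solutions at solver precision; otherwise sweeps continue until the
// largest coefficient change falls below tol.
//
// [[Rcpp::export]]
NumericMatrix lasso_path_gram(NumericMatrix XtX, NumericVector Xty, double n,
                              NumericVector lambda, double tol,
                              int max_sweeps) {
  const int p = Xty.size();
  const int nl = lambda.size();
  if (XtX.nrow() != p || XtX.ncol() != p)
    stop("XtX must be %d x %d", p, p);
  NumericMatrix beta(p, nl);
  std::vector<double> b(p, 0.0), bstar, A, rhs;
  std::vector<int> act;
  const double kkt_slack = 1e-9 * (n > 1.0 ? n : 1.0);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    const double nlam = n * lam;
    // warm start still all-zero: accept the exact zero solution whenever
    // every gradient is within the penalty (so lambda >= lambda_max gives
    // exact zeros rather than roundoff-sized coefficients)
    bool warm_zero = true;
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) { warm_zero = false; break; }
    if (warm_zero) {
      bool ok = true;
      for (int j = 0; j < p && ok; ++j)
        if (std::fabs(Xty[j]) > nlam + kkt_slack) ok = false;
      if (ok) continue;   // beta(, l) stays zero
    }
    int sweep = 0;
    for (;;) {
      if (++sweep > max_sweeps)
        stop("coordinate descent did not converge (tol=%g, max_sweeps=%d)",
             tol, max_sweeps);
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double ajj = XtX(j, j) / n;
        if (ajj <= 0.0) { b[j] = 0.0; continue; }
        double rho = Xty[j];
        for (int k = 0; k < p; ++k)
          if (k != j) rho -= XtX(j, k) * b[k];
        rho /= n;
        double bj = 0.0;
        if (rho > lam) bj = (rho - lam) / ajj;
        else if (rho < -lam) bj = (rho + lam) / ajj;
        const double d = std::fabs(bj - b[j]);
        if (d > delta) delta = d;
        b[j] = bj;
      }
      // exact solve on the current active set
      act.clear();
      for (int j = 0; j < p; ++j) if (b[j] != 0.0) act.push_back(j);
      const int m = (int)act.size();
      bool accepted = false;
      if (m > 0) {
        A.resize((size_t)m * m);
        rhs.resize(m);
        for (int c = 0; c < m; ++c) {
          for (int r = 0; r < m; ++r) A[(size_t)c * m + r] = XtX(act[r], act[c]);
          rhs[c] = Xty[act[c]] - nlam * (b[act[c]] > 0 ? 1.0 : -1.0);
        }
        if (solve_small(A, rhs, m, bstar)) {
          bool ok = true;
          for (int c = 0; c < m && ok; ++c) {
            double s = b[act[c]] > 0 ? 1.0 : -1.0;
            if (bstar[c] * s < 0.0) ok = false;   // sign flipped: reject
          }
          if (ok) {
            for (int j = 0; j < p && ok; ++j) {
              if (b[j] != 0.0) continue;
              double g = Xty[j];
              for (int c = 0; c < m; ++c) g -= XtX(j, act[c]) * bstar[c];
              if (std::fabs(g) > nlam + kkt_slack) ok = false;
            }
          }
          if (ok) {
            for (int c = 0; c < m; ++c) b[act[c]] = bstar[c];
            accepted = true;
          }
        }
      } else {
        // all-zero candidate: accept iff every gradient is within the penalty
        bool ok = true;
        for (int j = 0; j < p && ok; ++j)
          if (std::fabs(Xty[j]) > nlam + kkt_slack) ok = false;
        accepted = ok;
      }
      if (accepted || delta <= tol) break;
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}

// 32-bit FNV-1a hash of each string, masked to a non-negative R integer.
// Used for subject-order-invariant cross-validation fold assignment.
//
// [[Rcpp::export]]
IntegerVector fnv1a_hash(CharacterVector x) {
  const int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t h = 2166136261u;
    const char *s = CHAR(STRING_ELT(x, i));
    for (; *s; ++s) {
      h ^= static_cast<uint8_t>(*s);
      h *= 16777619u;
    }
    out[i] = static_cast<int>(h & 0x7fffffffu);
  }
  return out;
}
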