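#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Semi-global (glocal) affine-gap DP over a precomputed cell score matrix.
//
// cell(i-1, j-1) holds the match term for profile column i vs target base j
// (already alpha*tau + beta*sigma).  Three matrices:
//   D: column i deleted (consumes no target base)
//   I: target base j inserted (consumes no column)
//   M: best score ending at (i, j)
// Initialization: M(0,0)=0, M(i,0)=e0+i*ee, M(0,j)=0, D(0,j)=I(i,0)=-inf.
// Final score = max_j M(n, j); ties resolved toward smaller j.
// Traceback preference on ties: match (diagonal) > D > I.
// [[Rcpp::export]]
List dp_semiglobal(NumericMatrix cell, double e0, double ee) {
  const int n = cell.nrow(), m = cell.ncol();
  const double NEG = -1e30, tol = 1e-9;
  NumericMatrix D(n + 1, m + 1), I(n + 1, m + 1), M(n + 1, m + 1);
  M(0, 0) = 0.0; D(0, 0) = NEG; I(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) { M(0, j) = 0.0; D(0, j) = NEG; I(0, j) = NEG; }
  for (int i = 1; i <= n; ++i) { M(i, 0) = e0 + i * ee; D(i, 0) = NEG; I(i, 0) = NEG; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double d  = std::max(M(i - 1, j) + e0 + ee, D(i - 1, j) + ee);
      const double in = std::max(M(i, j - 1) + e0 + ee, I(i, j - 1) + ee);
      const double dg = M(i - 1, j - 1) + cell(i - 1, j - 1);
      D(i, j) = d; I(i, j) = in;
      M(i, j) = std::max(dg, std::max(d, in));
    }
  }
  int jbest = 0; double best = M(n, 0);
  for (int j = 1; j <= m; ++j) if (M(n, j) > best + tol) { best = M(n, j); jbest = j; }

  // traceback
  std::vector<int> pi, pj;
  int i = n, j = jbest;
  char st = 'M';
  int jmin = INT_MAX, jmax = -1;
  while (true) {
    if (st == 'M') {
      if (i == 0) break;               // free target prefix
      if (j == 0) break;               // init: columns 1..i deleted vs empty prefix
      const double dg = M(i - 1, j - 1) + cell(i - 1, j - 1);
      if (std::abs(M(i, j) - dg) < tol) {
        pi.push_back(i); pj.push_back(j);
        if (j < jmin) jmin = j;
        if (j > jmax) jmax = j;
        --i; --j;
      } else if (std::abs(M(i, j) - D(i, j)) < tol) {
        st = 'D';
      } else {
        st = 'I';
      }
    } else if (st == 'D') {
      const double open = M(i - 1, j) + e0 + ee;
      st = (std::abs(D(i, j) - open) < tol) ? 'M' : 'D';
      --i;
    } else { // 'I'
      if (j < jmin) jmin = j;
      if (j > jmax) jmax = j;
      const double open = M(i, j - 1) + e0 + ee;
      st = (std::abs(I(i, j) - open) < tol) ? 'M' : 'I';
      --j;
    }
  }
  const int npairs = (int) pi.size();
  IntegerMatrix pairs(npairs, 2);
  for (int k = 0; k < npairs; ++k) {      // reverse into ascending order
    pairs(k, 0) = pi[npairs - 1 - k];
    pairs(k, 1) = pj[npairs - 1 - k];
  }
  return List::create(
    _["score"] = best,
    _["end_j"] = jbest,
    _["pairs"] = pairs,
    _["target_start"] = (jmin == INT_MAX) ? 0 : jmin,
    _["target_end"]   = (jmax < 0) ? 0 : jmax);
}
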