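#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// seq encoded 1=A, 2=C, 3=G, 4=U, 5=X (X never pairs)
static inline bool canonical(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 1 && b == 4) ||  // A-U
         (a == 2 && b == 3) ||  // C-G
         (a == 3 && b == 4);    // G-U
}

// Base-pair maximization (Nussinov) with canonical pairs incl. G-U and a
// minimum hairpin loop of 3 unpaired bases (no pair with j - i < 4).
// Deterministic traceback: prefer leaving j unpaired, otherwise the smallest
// admissible pairing partner k.
// Returns 1-based partner vector, 0 = unpaired.
// [[Rcpp::export]]
IntegerVector nussinov_fold(IntegerVector seq) {
  const int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < 5) return partner;
  std::vector<std::vector<int> > g(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = g[i][j - 1];                       // j unpaired
      for (int k = i; k <= j - 4; ++k) {
        if (!canonical(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? g[i][k - 1] : 0) + (k + 1 <= j - 1 ? g[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      g[i][j] = best;
    }
  }
  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4) continue;
    if (g[i][j] == g[i][j - 1]) {                   // prefer j unpaired
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - 4; ++k) {
      if (!canonical(seq[k], seq[j])) continue;
      const int v = 1 + (k > i ? g[i][k - 1] : 0) + (k + 1 <= j - 1 ? g[k + 1][j - 1] : 0);
      if (v == g[i][j]) {                           // smallest k wins
        partner[k] = j + 1;
        partner[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return partner;
}
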