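#include <Rcpp.h>
using namespace Rcpp;

// Longest common subsequence length over integer code-point vectors.
// Two-row dynamic program, O(n*m) time, O(min(n,m)) space.
// [[Rcpp::export]]
int lcs_length_int(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  if (m > n) { IntegerVector tmp = a; a = b; b = tmp; int t = n; n = m; m = t; }
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] >= cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
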