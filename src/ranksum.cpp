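#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Column-wise Wilcoxon rank-sum building blocks.
//
// For each column of `x` returns the Mann-Whitney U statistic of group 1
// (labels == 1), the tie-correction term sum(t^3 - t) over tied groups, and
// whether any tie is present.  The p-value computation (exact via the
// Wilcoxon distribution for small tie-free groups, tie-corrected normal
// approximation otherwise) stays in R where pwilcox/pnorm live.
// [[Rcpp::export]]
List cpp_ranksum_stats(NumericMatrix x, IntegerVector g) {
  const int n = x.nrow(), p = x.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (g[i] == 1) ++n1;

  NumericVector u(p), tieterm(p);
  LogicalVector hasties(p);
  std::vector<int> ord(n);
  std::vector<double> ranks(n);

  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    double tt = 0.0;
    bool ties = false;
    int i = 0;
    while (i < n) {
      int k = i + 1;
      while (k < n && col[ord[k]] == col[ord[i]]) ++k;
      const double t = k - i;
      const double r = (i + 1 + k) / 2.0;  // average rank (1-based)
      for (int m = i; m < k; ++m) ranks[ord[m]] = r;
      if (t > 1) { ties = true; tt += t * t * t - t; }
      i = k;
    }
    double r1 = 0.0;
    for (int m = 0; m < n; ++m) if (g[m] == 1) r1 += ranks[m];
    u[j] = r1 - n1 * (n1 + 1.0) / 2.0;
    tieterm[j] = tt;
    hasties[j] = ties;
  }
  return List::create(_["u"] = u, _["tieterm"] = tieterm,
                      _["hasties"] = hasties, _["n1"] = n1,
                      _["n2"] = n - n1);
}
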