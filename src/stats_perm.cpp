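#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Exact permutation two-sided p-value for the Spearman correlation of two
// midrank vectors.  Permuting y over its multiset leaves rank norms fixed,
// so |rho| is monotone in |S - c| with S = sum(rx * y_perm) and
// c = sum(rx) * sum(ry) / n; std::next_permutation enumerates the distinct
// arrangements of a multiset, each equally likely under the null.
// [[Rcpp::export]]
double cpp_spearman_perm_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> y(ry.begin(), ry.end());
  std::sort(y.begin(), y.end());
  double sx = std::accumulate(rx.begin(), rx.end(), 0.0);
  double sy = std::accumulate(ry.begin(), ry.end(), 0.0);
  double c = sx * sy / n;
  double sobs = 0.0;
  for (int i = 0; i < n; ++i) sobs += rx[i] * ry[i];
  double dev = std::abs(sobs - c) - 1e-9;
  double total = 0.0, extreme = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * y[i];
    total += 1.0;
    if (std::abs(s - c) >= dev) extreme += 1.0;
  } while (std::next_permutation(y.begin(), y.end()));
  return extreme / total;
}
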