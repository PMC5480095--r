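#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Standardized pairwise rank-sum statistic (midranks, tie-corrected
// variance) of the treatment values against the control values.
static double pair_z(const std::vector<double>& ctrl,
                     const std::vector<double>& trt) {
  const int n0 = ctrl.size(), n1 = trt.size();
  const int n = n0 + n1;
  std::vector<std::pair<double, int> > v;
  v.reserve(n);
  for (int i = 0; i < n0; ++i) v.push_back(std::make_pair(ctrl[i], 0));
  for (int i = 0; i < n1; ++i) v.push_back(std::make_pair(trt[i], 1));
  std::sort(v.begin(), v.end());
  double ranksum_trt = 0.0, tie_term = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j].first == v[i].first) ++j;
    const double midrank = 0.5 * ((i + 1) + j); // average of ranks i+1..j
    const double t = j - i;
    if (t > 1) tie_term += t * t * t - t;
    for (int k = i; k < j; ++k)
      if (v[k].second == 1) ranksum_trt += midrank;
    i = j;
  }
  const double e = n1 * (n + 1) / 2.0;
  double var = (double)n0 * n1 / 12.0 *
    ((n + 1) - tie_term / ((double)n * (n - 1)));
  if (var <= 0) return 0.0;
  return (ranksum_trt - e) / std::sqrt(var);
}

// [[Rcpp::export]]
NumericVector steel_observed_z(NumericVector x, IntegerVector g, int k) {
  // g: 0 = control, 1..k = treatments
  std::vector<double> ctrl;
  std::vector<std::vector<double> > trt(k);
  for (int i = 0; i < x.size(); ++i) {
    if (g[i] == 0) ctrl.push_back(x[i]);
    else trt[g[i] - 1].push_back(x[i]);
  }
  NumericVector z(k);
  for (int j = 0; j < k; ++j) z[j] = pair_z(ctrl, trt[j]);
  return z;
}

// Permutation null of the maximum absolute standardized pairwise statistic
// over the k many-to-one comparisons. Uses R's RNG (honours set.seed()).
// [[Rcpp::export]]
NumericVector steel_perm_null(NumericVector x, IntegerVector g, int k, int B) {
  const int n = x.size();
  std::vector<int> labels(g.begin(), g.end());
  NumericVector out(B);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates shuffle of the group labels
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(labels[i], labels[j]);
    }
    std::vector<double> ctrl;
    std::vector<std::vector<double> > trt(k);
    for (int i = 0; i < n; ++i) {
      if (labels[i] == 0) ctrl.push_back(x[i]);
      else trt[labels[i] - 1].push_back(x[i]);
    }
    double mx = 0.0;
    for (int j = 0; j < k; ++j) {
      double z = std::fabs(pair_z(ctrl, trt[j]));
      if (z > mx) mx = z;
    }
    out[b] = mx;
  }
  return out;
}
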