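#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact penalized least-squares segmentation of a sequence into
// constant-mean segments (PELT: pruned exact linear time).  Minimizes
//   sum over segments of within-segment squared deviations
//   + penalty * (number of change points).
// Ties in cost are broken towards fewer change points.
// Returns 0-based change-point indices; a change point at k means the
// level changes between x[k-1] and x[k].
// [[Rcpp::export]]
IntegerVector pelt_mean_cpp(NumericVector x, double penalty, int min_seg = 1) {
  const int n = x.size();
  if (n < 1) return IntegerVector(0);
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  // cost of half-open segment [a, b)
  auto segcost = [&](int a, int b) -> double {
    const double s = S[b] - S[a];
    const double s2 = S2[b] - S2[a];
    const int m = b - a;
    double c = s2 - s * s / m;
    return c > 0.0 ? c : 0.0;
  };

  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> last(n + 1, 0), K(n + 1, 0);
  F[0] = -penalty;
  K[0] = 0;
  std::vector<int> cand;
  cand.push_back(0);
  const double tol = 1e-9;

  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int arg = -1, bestK = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      const int s = cand[i];
      if (t - s < min_seg) continue;
      const double v = F[s] + segcost(s, t) + penalty;
      const int k = K[s] + 1;
      if (v < best - tol || (v <= best + tol && (arg < 0 || k < bestK))) {
        best = v;
        arg = s;
        bestK = k;
      }
    }
    F[t] = best;
    last[t] = arg;
    K[t] = bestK;
    // prune candidates that can never be optimal again
    std::vector<int> keep;
    keep.reserve(cand.size() + 1);
    for (size_t i = 0; i < cand.size(); ++i) {
      const int s = cand[i];
      if (t - s < min_seg || F[s] + segcost(s, t) <= F[t] + tol) {
        keep.push_back(s);
      }
    }
    keep.push_back(t);
    cand.swap(keep);
  }

  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    const int s = last[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}
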