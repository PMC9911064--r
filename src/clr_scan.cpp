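#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Composite-likelihood sweep scan inner loop.
//
// pos:    sorted SNP positions (one chromosome)
// jcls:   1-based spectrum class index per SNP (derived or minor count)
// mids:   test positions (window midpoints)
// alphas: finite sweep intensities (the Inf null is implicit: Lambda is
//         clamped at 0)
// logT:   (G+1) x J matrix; row g is the log sweep spectrum at
//         pe = g/G, so the last row is exactly the log background
// logbg:  log background spectrum (== last row of logT)
//
// SNPs with alpha*d large enough that pe rounds to the last row contribute
// exactly the background term, which cancels in the ratio, so only SNPs
// within dmax = log(2G)/alpha of the test position are visited.
// [[Rcpp::export]]
NumericMatrix clr_scan_cpp(NumericVector pos, IntegerVector jcls,
                           NumericVector mids, NumericVector alphas,
                           NumericMatrix logT, NumericVector logbg) {
  const int W = mids.size(), A = alphas.size(), S = pos.size();
  const int G = logT.nrow() - 1;
  NumericMatrix out(W, 2);
  std::vector<double> dmax(A);
  for (int a = 0; a < A; ++a)
    dmax[a] = std::log(2.0 * G) / alphas[a];
  for (int w = 0; w < W; ++w) {
    const double x = mids[w];
    double best = 0.0;        // the null (alpha = Inf) scores 0
    double ahat = R_PosInf;
    for (int a = 0; a < A; ++a) {
      const double alpha = alphas[a];
      const double lo = x - dmax[a], hi = x + dmax[a];
      int s0 = std::lower_bound(pos.begin(), pos.end(), lo) - pos.begin();
      int s1 = std::upper_bound(pos.begin(), pos.end(), hi) - pos.begin();
      if (s0 >= s1) continue;
      double sum = 0.0;
      for (int s = s0; s < s1; ++s) {
        const double d = std::fabs(pos[s] - x);
        const double pe = 1.0 - std::exp(-alpha * d);
        int g = (int)std::lround(pe * G);
        if (g > G) g = G;
        const int j = jcls[s] - 1;
        sum += logT(g, j) - logbg[j];
      }
      if (sum > best) { best = sum; ahat = alpha; }
    }
    out(w, 0) = 2.0 * best;
    out(w, 1) = ahat;
  }
  if (S == 0)
    for (int w = 0; w < W; ++w) { out(w, 0) = NA_REAL; out(w, 1) = NA_REAL; }
  return out;
}
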