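#include <Rcpp.h>
using namespace Rcpp;

// Pearson correlation between ref[u0..u1] (0-based, inclusive) and the
// sample x linearly warped so that positions [a, b] map onto [u0, u1].
// Zero-variance segments are defined to have correlation 0.
static double seg_corr(const double* x, int nx, const NumericVector& ref,
                       int u0, int u1, double a, double b) {
  int len = u1 - u0 + 1;
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int t = 0; t < len; ++t) {
    double pos = a + (b - a) * (double)t / (double)(len - 1);
    int lo = (int)std::floor(pos);
    if (lo < 0) lo = 0;
    if (lo > nx - 2) lo = nx - 2;
    double frac = pos - lo;
    double v = x[lo] * (1.0 - frac) + x[lo + 1] * frac;
    double r = ref[u0 + t];
    sx += v; sy += r; sxx += v * v; syy += r * r; sxy += v * r;
  }
  double n = (double)len;
  double vx = sxx - sx * sx / n;
  double vy = syy - sy * sy / n;
  double cxy = sxy - sx * sy / n;
  if (vx <= 1e-12 || vy <= 1e-12) return 0.0;
  return cxy / std::sqrt(vx * vy);
}

// Exact DP over boundary offsets: internal boundary i may sit at
// bounds[i] + d with d in [-slack, slack]; endpoints are fixed. The benefit
// is the sum of per-segment warped correlations with the reference.
// [[Rcpp::export(name = ".cow_align_cpp")]]
List cow_align_cpp(NumericMatrix X, NumericVector ref,
                   IntegerVector bounds, int slack) {
  int m = X.nrow(), n = X.ncol();
  int N = bounds.size() - 1;          // number of segments
  int W = 2 * slack + 1;
  NumericMatrix aligned(m, n);
  NumericVector scores(m);
  IntegerMatrix offsets(m, N + 1);
  std::vector<double> F((N + 1) * W, R_NegInf);
  std::vector<int> back((N + 1) * W, 0);
  std::vector<double> row(n);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) row[j] = X(i, j);
    std::fill(F.begin(), F.end(), R_NegInf);
    // offset index w corresponds to d = w - slack
    F[slack] = 0.0;                   // boundary 0 fixed at offset 0
    for (int seg = 1; seg <= N; ++seg) {
      int dlo = (seg == N) ? 0 : -slack;
      int dhi = (seg == N) ? 0 : slack;
      int plo = (seg == 1) ? 0 : -slack;
      int phi = (seg == 1) ? 0 : slack;
      for (int d = dlo; d <= dhi; ++d) {
        double best = R_NegInf;
        int barg = 0;
        // visit predecessor offsets 0, -1, +1, -2, ... so that ties
        // (e.g. zero-variance segments) keep boundaries at their
        // reference positions and self-alignment is the identity map
        for (int k = 0; k <= 2 * slack; ++k) {
          int dp = (k % 2) ? -(k + 1) / 2 : k / 2;   // 0, -1, 1, -2, 2, ...
          if (dp < plo || dp > phi) continue;
          double prev = F[(seg - 1) * W + (dp + slack)];
          if (!R_FINITE(prev)) continue;
          double c = seg_corr(row.data(), n, ref, bounds[seg - 1], bounds[seg],
                              bounds[seg - 1] + dp, bounds[seg] + d);
          if (prev + c > best) { best = prev + c; barg = dp; }
        }
        F[seg * W + (d + slack)] = best;
        back[seg * W + (d + slack)] = barg;
      }
    }
    scores[i] = F[N * W + slack];
    // backtrack boundary offsets
    int d = 0;
    for (int seg = N; seg >= 1; --seg) {
      offsets(i, seg) = d;
      d = back[seg * W + (d + slack)];
    }
    offsets(i, 0) = 0;
    // reconstruct the warped signal on the reference grid
    for (int seg = 1; seg <= N; ++seg) {
      int u0 = bounds[seg - 1], u1 = bounds[seg];
      double a = u0 + offsets(i, seg - 1), b = u1 + offsets(i, seg);
      int len = u1 - u0 + 1;
      for (int t = 0; t < len; ++t) {
        double pos = a + (b - a) * (double)t / (double)(len - 1);
        int lo = (int)std::floor(pos);
        if (lo < 0) lo = 0;
        if (lo > n - 2) lo = n - 2;
        double frac = pos - lo;
        aligned(i, u0 + t) = row[lo] * (1.0 - frac) + row[lo + 1] * frac;
      }
    }
  }
  return List::create(_["aligned"] = aligned, _["scores"] = scores,
                      _["offsets"] = offsets);
}
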