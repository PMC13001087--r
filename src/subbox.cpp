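// Sliding sub-box particle-count moments for the density-fluctuation
// (small-subvolume) Kirkwood-Buff estimator.  Windows are [x0, x0 + L) x
// [y0, y0 + L) over the full slab height; membership is half-open on both
// axes so that tiling never double-counts a particle.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// x, y: coordinates relative to the box origin, one frame.
// Returns c(n_windows, sum N, sum N^2).
// With wrap = true the window origins cover [0, Lx) at the given stride and
// windows wrap around periodically; otherwise origins stop at Lx - L.
// [[Rcpp::export]]
NumericVector cpp_subbox_moments(NumericVector x, NumericVector y,
                                 double Lx, double Ly, double L,
                                 double stride, bool wrap) {
  const int n = x.size();
  std::vector<double> xs, ys;
  xs.reserve(n * 2); ys.reserve(n * 2);
  for (int i = 0; i < n; ++i) { xs.push_back(x[i]); ys.push_back(y[i]); }
  if (wrap) {
    for (int i = 0; i < n; ++i) {
      bool cx = x[i] < L, cy = y[i] < L;
      if (cx) { xs.push_back(x[i] + Lx); ys.push_back(y[i]); }
      if (cy) { xs.push_back(x[i]); ys.push_back(y[i] + Ly); }
      if (cx && cy) { xs.push_back(x[i] + Lx); ys.push_back(y[i] + Ly); }
    }
  }
  const int m = xs.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xs[a] < xs[b]; });
  std::vector<double> sx(m), sy(m);
  for (int i = 0; i < m; ++i) { sx[i] = xs[ord[i]]; sy[i] = ys[ord[i]]; }

  const int nx = wrap ? (int)std::floor((Lx - 1e-12) / stride) + 1
                      : (int)std::floor((Lx - L) / stride + 1e-9) + 1;
  const int ny = wrap ? (int)std::floor((Ly - 1e-12) / stride) + 1
                      : (int)std::floor((Ly - L) / stride + 1e-9) + 1;
  if (nx < 1 || ny < 1) stop("sub-box side exceeds the box extents");

  double nwin = 0.0, s1 = 0.0, s2 = 0.0;
  std::vector<double> strip;
  for (int ix = 0; ix < nx; ++ix) {
    double x0 = ix * stride;
    int i0 = std::lower_bound(sx.begin(), sx.end(), x0) - sx.begin();
    int i1 = std::lower_bound(sx.begin(), sx.end(), x0 + L) - sx.begin();
    strip.clear();
    for (int i = i0; i < i1; ++i) strip.push_back(sy[i]);
    std::sort(strip.begin(), strip.end());
    const int ns = strip.size();
    int lo = 0, hi = 0;
    for (int iy = 0; iy < ny; ++iy) {
      double y0 = iy * stride;
      while (lo < ns && strip[lo] < y0) ++lo;
      while (hi < ns && strip[hi] < y0 + L) ++hi;
      double cnt = (double)(hi - lo);
      nwin += 1.0; s1 += cnt; s2 += cnt * cnt;
    }
  }
  return NumericVector::create(nwin, s1, s2);
}
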