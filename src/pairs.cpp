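// Pair-distance histograms and Debye sums.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Histogram of pair separations below bin_width * n_bins (unordered pairs).
// Per-axis minimum-image convention on periodic axes.  Uses a 2D x-y cell
// grid when the lateral extents allow it, otherwise falls back to the
// all-pairs loop.
// [[Rcpp::export]]
NumericVector cpp_pair_counts(NumericMatrix coords, double bin_width,
                              int n_bins, NumericVector origin,
                              NumericVector extents, LogicalVector periodic) {
  const int n = coords.nrow();
  const double rmax = bin_width * n_bins, rmax2 = rmax * rmax;
  const double Lx = extents[0], Ly = extents[1], Lz = extents[2];
  const bool px = periodic[0], py = periodic[1], pz = periodic[2];
  NumericVector counts(n_bins);

  const int ncx = (int)std::floor(Lx / rmax);
  const int ncy = (int)std::floor(Ly / rmax);
  const bool use_cells = (n > 256 && ncx >= 3 && ncy >= 3);

  if (!use_cells) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = coords(i, 0) - coords(j, 0);
        if (px) dx = min_image(dx, Lx);
        if (std::fabs(dx) >= rmax) continue;
        double dy = coords(i, 1) - coords(j, 1);
        if (py) dy = min_image(dy, Ly);
        if (std::fabs(dy) >= rmax) continue;
        double dz = coords(i, 2) - coords(j, 2);
        if (pz) dz = min_image(dz, Lz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rmax2) continue;
        int k = (int)std::floor(std::sqrt(r2) / bin_width);
        if (k >= 0 && k < n_bins) counts[k] += 1.0;
      }
    }
    return counts;
  }

  const double wx = Lx / ncx, wy = Ly / ncy;
  std::vector< std::vector<int> > cells((size_t)ncx * ncy);
  std::vector<int> cix(n), ciy(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((coords(i, 0) - origin[0]) / wx);
    int iy = (int)std::floor((coords(i, 1) - origin[1]) / wy);
    if (ix < 0) ix = 0; if (ix >= ncx) ix = ncx - 1;
    if (iy < 0) iy = 0; if (iy >= ncy) iy = ncy - 1;
    cix[i] = ix; ciy[i] = iy;
    cells[(size_t)ix * ncy + iy].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    for (int ox = -1; ox <= 1; ++ox) {
      int jx = cix[i] + ox;
      if (px) jx = (jx + ncx) % ncx;
      else if (jx < 0 || jx >= ncx) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        int jy = ciy[i] + oy;
        if (py) jy = (jy + ncy) % ncy;
        else if (jy < 0 || jy >= ncy) continue;
        const std::vector<int>& cell = cells[(size_t)jx * ncy + jy];
        for (size_t m = 0; m < cell.size(); ++m) {
          int j = cell[m];
          if (j <= i) continue;
          double dx = coords(i, 0) - coords(j, 0);
          if (px) dx = min_image(dx, Lx);
          if (std::fabs(dx) >= rmax) continue;
          double dy = coords(i, 1) - coords(j, 1);
          if (py) dy = min_image(dy, Ly);
          if (std::fabs(dy) >= rmax) continue;
          double dz = coords(i, 2) - coords(j, 2);
          if (pz) dz = min_image(dz, Lz);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rmax2) continue;
          int k = (int)std::floor(std::sqrt(r2) / bin_width);
          if (k >= 0 && k < n_bins) counts[k] += 1.0;
        }
      }
    }
  }
  return counts;
}

// Debye pair sum S(q) = 1 + (2/N) sum_{i<j} sin(q r_ij)/(q r_ij) over pairs
// with r_ij < r_max (r_max <= 0 means no cutoff).
// [[Rcpp::export]]
NumericVector cpp_debye_sum(NumericMatrix coords, NumericVector q,
                            bool use_min_image, NumericVector extents,
                            double r_max) {
  const int n = coords.nrow(), nq = q.size();
  const double Lx = extents[0], Ly = extents[1], Lz = extents[2];
  const bool cutoff = r_max > 0.0;
  NumericVector s(nq);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      if (use_min_image) {
        dx = min_image(dx, Lx);
        dy = min_image(dy, Ly);
        dz = min_image(dz, Lz);
      }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (cutoff && r >= r_max) continue;
      for (int k = 0; k < nq; ++k) {
        double x = q[k] * r;
        s[k] += (x < 1e-12) ? 1.0 : std::sin(x) / x;
      }
    }
  }
  for (int k = 0; k < nq; ++k) s[k] = 1.0 + 2.0 * s[k] / n;
  return s;
}
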