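// Sphere-cuboid intersection volumes for finite-box RDF normalisation.
//
// The spherical shell around a particle is clipped by the box walls.  The
// clipped sphere volume is computed by integrating, along z, the exact area
// of a disk intersected with an axis-aligned rectangle; the z-integral is
// evaluated with panel-wise Gauss-Legendre quadrature, with panels split at
// every z where the slice circle becomes tangent to a wall or passes through
// a rectangle corner, so the integrand is analytic inside each panel.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;
static const double D_INF = 1e30; // "wall at infinity" for periodic axes

// 16-point Gauss-Legendre nodes/weights on [-1, 1]
static const int GLN = 16;
static const double GLX[GLN] = {
  -0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
  -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
  -0.2816035507792589, -0.0950125098376374,  0.0950125098376374,
   0.2816035507792589,  0.4580167776572274,  0.6178762444026438,
   0.7554044083550030,  0.8656312023878318,  0.9445750230732326,
   0.9894009349916499 };
static const double GLW[GLN] = {
  0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
  0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
  0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
  0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
  0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
  0.0271524594117541 };

// antiderivative of sqrt(rho^2 - u^2)
static inline double int_sqrt(double u, double rho) {
  double t = rho * rho - u * u;
  if (t < 0.0) t = 0.0;
  double s = u / rho;
  if (s > 1.0) s = 1.0; else if (s < -1.0) s = -1.0;
  return 0.5 * (u * std::sqrt(t) + rho * rho * std::asin(s));
}

// exact area of {u^2 + v^2 <= rho^2} intersected with [x0,x1] x [y0,y1]
static double disk_rect_area(double rho, double x0, double x1,
                             double y0, double y1) {
  if (rho <= 0.0) return 0.0;
  double a = std::max(x0, -rho), b = std::min(x1, rho);
  if (b <= a) return 0.0;
  double bp[8];
  int nbp = 0;
  bp[nbp++] = a; bp[nbp++] = b;
  const double ys[2] = { y0, y1 };
  for (int t = 0; t < 2; ++t) {
    double ay = std::fabs(ys[t]);
    if (ay < rho) {
      double u = std::sqrt(rho * rho - ys[t] * ys[t]);
      if (-u > a && -u < b) bp[nbp++] = -u;
      if ( u > a &&  u < b) bp[nbp++] = u;
    }
  }
  std::sort(bp, bp + nbp);
  double area = 0.0;
  for (int k = 0; k + 1 < nbp; ++k) {
    double u1 = bp[k], u2 = bp[k + 1];
    if (u2 - u1 <= 0.0) continue;
    double um = 0.5 * (u1 + u2);
    double h = std::sqrt(std::max(0.0, rho * rho - um * um));
    if (std::min(y1, h) <= std::max(y0, -h)) continue;
    double du = u2 - u1;
    double ii = int_sqrt(u2, rho) - int_sqrt(u1, rho);
    double top = (y1 < h) ? y1 * du : ii;
    double bot = (y0 > -h) ? y0 * du : -ii;
    area += top - bot;
  }
  return area;
}

// volume of sphere of radius r centred at the origin intersected with the
// cuboid [-dxm, dxp] x [-dym, dyp] x [-dzm, dzp]; all d >= 0 (centre inside)
static double sphere_box_volume(double r, double dxm, double dxp,
                                double dym, double dyp,
                                double dzm, double dzp) {
  if (r <= 0.0) return 0.0;
  double zl = std::max(-r, -dzm), zh = std::min(r, dzp);
  if (zh <= zl) return 0.0;
  // critical lateral distances: tangency to a wall or passage through a corner
  std::vector<double> dcrit;
  const double dx[2] = { dxm, dxp }, dy[2] = { dym, dyp };
  for (int i = 0; i < 2; ++i) if (dx[i] < r) dcrit.push_back(dx[i]);
  for (int i = 0; i < 2; ++i) if (dy[i] < r) dcrit.push_back(dy[i]);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      if (dx[i] >= r || dy[j] >= r) continue;
      double d = std::hypot(dx[i], dy[j]);
      if (d < r) dcrit.push_back(d);
    }
  std::vector<double> bp;
  bp.push_back(zl); bp.push_back(zh);
  for (size_t i = 0; i < dcrit.size(); ++i) {
    double z = std::sqrt(r * r - dcrit[i] * dcrit[i]);
    if ( z > zl &&  z < zh) bp.push_back(z);
    if (-z > zl && -z < zh) bp.push_back(-z);
  }
  std::sort(bp.begin(), bp.end());
  double vol = 0.0;
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double z1 = bp[k], z2 = bp[k + 1];
    if (z2 - z1 <= 0.0) continue;
    double c = 0.5 * (z1 + z2), hw = 0.5 * (z2 - z1);
    for (int i = 0; i < GLN; ++i) {
      double z = c + hw * GLX[i];
      double rho = std::sqrt(std::max(0.0, r * r - z * z));
      vol += GLW[i] * hw * disk_rect_area(rho, -dxm, dxp, -dym, dyp);
    }
  }
  return vol;
}

// sphere clipped on ONE axis only (two parallel planes): closed form
static inline double sphere_slab_volume(double r, double dm, double dp) {
  double zl = std::max(-r, -dm), zh = std::min(r, dp);
  if (zh <= zl) return 0.0;
  double fl = PI_ * (r * r * zl - zl * zl * zl / 3.0);
  double fh = PI_ * (r * r * zh - zh * zh * zh / 3.0);
  return fh - fl;
}

// clipped sphere volume with per-axis fast paths
static double clipped_sphere_volume(double r, const double d[6]) {
  double dmin = d[0];
  for (int i = 1; i < 6; ++i) dmin = std::min(dmin, d[i]);
  if (r <= dmin) return 4.0 * PI_ / 3.0 * r * r * r;
  bool cx = std::min(d[0], d[1]) < r;
  bool cy = std::min(d[2], d[3]) < r;
  bool cz = std::min(d[4], d[5]) < r;
  int nclip = (cx ? 1 : 0) + (cy ? 1 : 0) + (cz ? 1 : 0);
  if (nclip == 1) {
    if (cx) return sphere_slab_volume(r, d[0], d[1]);
    if (cy) return sphere_slab_volume(r, d[2], d[3]);
    return sphere_slab_volume(r, d[4], d[5]);
  }
  return sphere_box_volume(r, d[0], d[1], d[2], d[3], d[4], d[5]);
}

static void wall_distances(const double* p, const double* origin,
                           const double* extents, const int* periodic,
                           double d[6]) {
  for (int a = 0; a < 3; ++a) {
    if (periodic[a]) {
      d[2 * a] = D_INF; d[2 * a + 1] = D_INF;
    } else {
      d[2 * a]     = p[a] - origin[a];
      d[2 * a + 1] = origin[a] + extents[a] - p[a];
    }
  }
}

// [[Rcpp::export]]
double cpp_shell_volume(NumericVector center, double r_in, double r_out,
                        NumericVector origin, NumericVector extents,
                        LogicalVector periodic) {
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  double d[6];
  double p[3] = { center[0], center[1], center[2] };
  double o[3] = { origin[0], origin[1], origin[2] };
  double e[3] = { extents[0], extents[1], extents[2] };
  wall_distances(p, o, e, per, d);
  for (int i = 0; i < 6; ++i)
    if (d[i] < 0.0) stop("shell center lies outside the box");
  return clipped_sphere_volume(r_out, d) - clipped_sphere_volume(r_in, d);
}

// Sum over particles of the clipped shell volume for every bin.
// edges has length n_bins + 1; returns a vector of length n_bins.
// [[Rcpp::export]]
NumericVector cpp_sum_shell_volumes(NumericMatrix coords, NumericVector edges,
                                    NumericVector origin, NumericVector extents,
                                    LogicalVector periodic) {
  int n = coords.nrow(), nb = edges.size() - 1;
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  double o[3] = { origin[0], origin[1], origin[2] };
  double e[3] = { extents[0], extents[1], extents[2] };
  NumericVector out(nb);
  double d[6];
  for (int i = 0; i < n; ++i) {
    double p[3] = { coords(i, 0), coords(i, 1), coords(i, 2) };
    wall_distances(p, o, e, per, d);
    for (int k = 0; k < 6; ++k)
      if (d[k] < -1e-9) stop("particle %d lies outside the box", i + 1);
    for (int k = 0; k < 6; ++k) if (d[k] < 0.0) d[k] = 0.0;
    double vprev = clipped_sphere_volume(edges[0], d);
    for (int k = 0; k < nb; ++k) {
      double v = clipped_sphere_volume(edges[k + 1], d);
      out[k] += v - vprev;
      vprev = v;
    }
  }
  return out;
}
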