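// Metropolis Monte Carlo sampler for simple pair-potential fluids in fully
// periodic orthorhombic boxes.  Single-particle displacement moves,
// minimum-image convention, incremental energy bookkeeping with periodic
// full recomputation to monitor drift.  Energies are in units of kB*T
// (beta = 1 throughout).

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

static const double INF_U = std::numeric_limits<double>::infinity();

struct Potential {
  int kind;        // 0 ideal, 1 hard sphere, 2 square well, 3 yukawa, 4 tabulated
  double sigma, sigma2, eps, kappa, width, rc, rc2;
  std::vector<double> tr, tu;

  double operator()(double r2) const {
    if (kind == 0) return 0.0;
    if (r2 >= rc2) return 0.0;
    if (kind != 4 && r2 < sigma2) return INF_U;
    switch (kind) {
      case 1: return 0.0;
      case 2: {
        double r = std::sqrt(r2);
        return (r < sigma + width) ? -eps : 0.0;
      }
      case 3: {
        double r = std::sqrt(r2);
        return eps * (sigma / r) * std::exp(-kappa * (r - sigma));
      }
      case 4: {
        double r = std::sqrt(r2);
        if (r < tr.front()) return INF_U;
        if (r >= tr.back()) return 0.0;
        size_t hi = std::upper_bound(tr.begin(), tr.end(), r) - tr.begin();
        size_t lo = hi - 1;
        double f = (r - tr[lo]) / (tr[hi] - tr[lo]);
        return tu[lo] + f * (tu[hi] - tu[lo]);
      }
    }
    return 0.0;
  }
};

struct CellList {
  int nc[3];
  double w[3], L[3];
  std::vector< std::vector<int> > cells;

  void init(const double Lbox[3], double rc) {
    for (int a = 0; a < 3; ++a) {
      L[a] = Lbox[a];
      nc[a] = std::max(1, (int)std::floor(Lbox[a] / rc));
      w[a] = Lbox[a] / nc[a];
    }
    cells.assign((size_t)nc[0] * nc[1] * nc[2], std::vector<int>());
  }
  int cell_of(const double* p) const {
    int ix = std::min(nc[0] - 1, (int)std::floor(p[0] / w[0]));
    int iy = std::min(nc[1] - 1, (int)std::floor(p[1] / w[1]));
    int iz = std::min(nc[2] - 1, (int)std::floor(p[2] / w[2]));
    return (ix * nc[1] + iy) * nc[2] + iz;
  }
  void insert(int i, int c) { cells[c].push_back(i); }
  void remove(int i, int c) {
    std::vector<int>& v = cells[c];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); return; }
  }
  // unique neighbour cell indices (handles nc < 3 without double counting)
  void neighbours(int c, std::vector<int>& out) const {
    int iz = c % nc[2], iy = (c / nc[2]) % nc[1], ix = c / (nc[1] * nc[2]);
    int uxs[3], uys[3], uzs[3];
    int nux = uniq_axis(ix, nc[0], uxs);
    int nuy = uniq_axis(iy, nc[1], uys);
    int nuz = uniq_axis(iz, nc[2], uzs);
    out.clear();
    for (int a = 0; a < nux; ++a)
      for (int b = 0; b < nuy; ++b)
        for (int d = 0; d < nuz; ++d)
          out.push_back((uxs[a] * nc[1] + uys[b]) * nc[2] + uzs[d]);
  }
  static int uniq_axis(int i, int n, int* out) {
    int cnt = 0;
    for (int o = -1; o <= 1; ++o) {
      int j = ((i + o) % n + n) % n;
      bool seen = false;
      for (int k = 0; k < cnt; ++k) if (out[k] == j) seen = true;
      if (!seen) out[cnt++] = j;
    }
    return cnt;
  }
};

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// [[Rcpp::export]]
List cpp_run_mc(int n, NumericVector extents, int kind, double sigma,
                double eps, double kappa, double width,
                NumericVector table_r, NumericVector table_u,
                double cutoff, int n_equil, int n_frames, int sample_every,
                double max_disp, double seed_lo, double seed_hi, bool tune) {
  const double L[3] = { extents[0], extents[1], extents[2] };
  Potential pot;
  pot.kind = kind; pot.sigma = sigma; pot.sigma2 = sigma * sigma;
  pot.eps = eps; pot.kappa = kappa; pot.width = width;
  pot.rc = cutoff; pot.rc2 = cutoff * cutoff;
  pot.tr.assign(table_r.begin(), table_r.end());
  pot.tu.assign(table_u.begin(), table_u.end());

  std::mt19937_64 rng((uint64_t)seed_lo + ((uint64_t)seed_hi << 32));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> pos(3 * (size_t)n);
  CellList cl;
  cl.init(L, std::max(cutoff, 1e-6));
  std::vector<int> cell(n);
  std::vector<int> nb;

  // energy of a trial point against all particles except `self`
  auto point_energy = [&](const double* p, int self) -> double {
    double e = 0.0;
    cl.neighbours(cl.cell_of(p), nb);
    for (size_t m = 0; m < nb.size(); ++m) {
      const std::vector<int>& v = cl.cells[nb[m]];
      for (size_t k = 0; k < v.size(); ++k) {
        int j = v[k];
        if (j == self) continue;
        double dx = min_image(p[0] - pos[3 * j],     L[0]);
        double dy = min_image(p[1] - pos[3 * j + 1], L[1]);
        double dz = min_image(p[2] - pos[3 * j + 2], L[2]);
        double u = pot(dx * dx + dy * dy + dz * dz);
        if (u == INF_U) return INF_U;
        e += u;
      }
    }
    return e;
  };

  // random sequential insertion (retry budget guards dense hard cores)
  const int max_tries = 200 * n + 1000;
  int tries = 0;
  for (int i = 0; i < n; ++i) {
    for (;;) {
      if (++tries > max_tries)
        stop("could not insert %d particles without overlap; lower the density", n);
      double p[3] = { U(rng) * L[0], U(rng) * L[1], U(rng) * L[2] };
      if (point_energy(p, -1) < INF_U) {
        pos[3 * i] = p[0]; pos[3 * i + 1] = p[1]; pos[3 * i + 2] = p[2];
        cell[i] = cl.cell_of(p);
        cl.insert(i, cell[i]);
        break;
      }
    }
  }

  auto total_energy = [&]() -> double {
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      e += point_energy(&pos[3 * i], i);
    return 0.5 * e;
  };

  double utot = total_energy();
  double drift = 0.0;
  long acc_sample = 0, att_sample = 0;
  long acc_win = 0, att_win = 0;
  const double disp_cap = 0.5 * std::min(L[0], std::min(L[1], L[2]));
  if (max_disp > disp_cap) max_disp = disp_cap;

  List frames(n_frames);
  int recorded = 0;
  const int total_sweeps = n_equil + n_frames * sample_every;

  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    bool sampling = sweep > n_equil;
    for (int mv = 0; mv < n; ++mv) {
      int i = (int)(U(rng) * n);
      if (i >= n) i = n - 1;
      double oldp[3] = { pos[3 * i], pos[3 * i + 1], pos[3 * i + 2] };
      double newp[3];
      for (int a = 0; a < 3; ++a) {
        double x = oldp[a] + (2.0 * U(rng) - 1.0) * max_disp;
        x -= L[a] * std::floor(x / L[a]);
        if (x >= L[a]) x = 0.0;  // rounding guard: keep [0, L)
        newp[a] = x;
      }
      double e_old = point_energy(oldp, i);
      double e_new = point_energy(newp, i);
      bool accept = false;
      if (e_new < INF_U) {
        double du = e_new - e_old;
        accept = (du <= 0.0) || (U(rng) < std::exp(-du));
      }
      if (sampling) { ++att_sample; if (accept) ++acc_sample; }
      else { ++att_win; if (accept) ++acc_win; }
      if (accept) {
        pos[3 * i] = newp[0]; pos[3 * i + 1] = newp[1]; pos[3 * i + 2] = newp[2];
        int cnew = cl.cell_of(newp);
        if (cnew != cell[i]) {
          cl.remove(i, cell[i]);
          cl.insert(i, cnew);
          cell[i] = cnew;
        }
        utot += e_new - e_old;
      }
    }
    if (!sampling && tune && sweep % 50 == 0 && att_win > 0) {
      double rate = (double)acc_win / att_win;
      if (rate > 0.5) max_disp = std::min(max_disp * 1.15, disp_cap);
      else if (rate < 0.3) max_disp *= 0.85;
      acc_win = 0; att_win = 0;
    }
    if (sweep % 1000 == 0) {
      double full = total_energy();
      drift = std::max(drift, std::fabs(full - utot));
      utot = full;
    }
    if (sampling && (sweep - n_equil) % sample_every == 0 && recorded < n_frames) {
      NumericMatrix f(n, 3);
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) f(i, a) = pos[3 * i + a];
      frames[recorded++] = f;
    }
  }
  double full = total_energy();
  drift = std::max(drift, std::fabs(full - utot));

  double acc_rate = att_sample > 0 ? (double)acc_sample / att_sample : NA_REAL;
  return List::create(_["frames"] = frames,
                      _["acceptance_rate"] = acc_rate,
                      _["max_displacement"] = max_disp,
                      _["energy_drift"] = drift,
                      _["final_energy"] = full);
}
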