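// Compiled kernels: coarse-grained MD (harmonic bond network, truncated
// Lennard-Jones against a frozen substrate, anchor-point springs,
// velocity-Verlet with group thermostats), contact counting, mesh
// connectivity, and P1 elasticity assembly.
//
// Internal MD units: nm, Da, kJ/mol; the derived time unit is exactly 1 ps,
// so velocities are nm/ps and forces kJ/mol/nm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <functional>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- PRNG ----
// splitmix64: deterministic, seedable, independent of R's RNG.
struct Rng {
  uint64_t s;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : s(seed), has_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
  // Marsaglia-Tsang, shape a >= 1
  double gamma(double a) {
    double d = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal();
      double t = 1.0 + c * x;
      if (t <= 0) continue;
      double v = t * t * t;
      double u = unif();
      if (std::log(u) < 0.5 * x * x + d - d * v + d * std::log(v))
        return d * v;
    }
  }
  // chi-squared with k degrees of freedom (k >= 1)
  double chisq(int k) {
    if (k <= 0) return 0.0;
    if (k == 1) { double z = normal(); return z * z; }
    return 2.0 * gamma(0.5 * k);
  }
};

// ---------------------------------------------------- substrate cell grid --
// Neighbour search against the frozen substrate. Two paths: a regular
// planar monolayer (y = 0 lattice, descriptor passed from R) enumerated by
// direct index windows, and a generic cell grid for substrates with an
// amorphous bulk.
struct SubGrid {
  double cell, x0, y0, z0, ymax, cutoff;
  std::unordered_map<long long, std::vector<int>> cells;
  const double* sx; const double* sy; const double* sz;
  int ns;
  // planar lattice descriptor (nx * nz beads at y = 0): bead k = ix + nx*iz
  bool planar = false;
  double lx0, lz0, ls;
  int lnx, lnz;

  long long key(int ix, int iy, int iz) const {
    return (long long)ix + 100000LL * ((long long)iy + 100000LL * (long long)iz);
  }
  void build(const NumericMatrix& sub, double cutoff_,
             const NumericVector& lattice) {
    ns = sub.nrow();
    cell = cutoff_; cutoff = cutoff_;
    if (ns == 0) { sx = sy = sz = nullptr; return; }
    sx = &sub(0, 0); sy = &sub(0, 1); sz = &sub(0, 2);
    ymax = *std::max_element(sy, sy + ns);
    if (lattice.size() == 5) {
      planar = true;
      lx0 = lattice[0]; lz0 = lattice[1]; ls = lattice[2];
      lnx = (int)lattice[3]; lnz = (int)lattice[4];
      return;
    }
    x0 = *std::min_element(sx, sx + ns);
    y0 = *std::min_element(sy, sy + ns);
    z0 = *std::min_element(sz, sz + ns);
    for (int i = 0; i < ns; ++i) {
      int ix = (int)std::floor((sx[i] - x0) / cell);
      int iy = (int)std::floor((sy[i] - y0) / cell);
      int iz = (int)std::floor((sz[i] - z0) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
  template <class F>
  void for_neighbours(double x, double y, double z, F&& f) const {
    if (ns == 0) return;
    if (y - ymax >= cutoff) return;   // entirely out of range
    if (planar) {
      double d2 = cutoff * cutoff - y * y;
      if (d2 <= 0) return;
      double r = std::sqrt(d2);
      int ix0 = std::max(0, (int)std::ceil((x - r - lx0) / ls));
      int ix1 = std::min(lnx - 1, (int)std::floor((x + r - lx0) / ls));
      int iz0 = std::max(0, (int)std::ceil((z - r - lz0) / ls));
      int iz1 = std::min(lnz - 1, (int)std::floor((z + r - lz0) / ls));
      for (int iz = iz0; iz <= iz1; ++iz)
        for (int ix = ix0; ix <= ix1; ++ix) f(ix + lnx * iz);
      return;
    }
    int ix = (int)std::floor((x - x0) / cell);
    int iy = (int)std::floor((y - y0) / cell);
    int iz = (int)std::floor((z - z0) / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) f(j);
        }
  }
};

// ------------------------------------------------------------ force eval --
// Fills f (3n), fap (3nap), fsub (3*n_spat, force on beads from substrate),
// returns potential energy. All arrays zeroed here.
static double compute_forces(
    int n, const std::vector<double>& x, std::vector<double>& f,
    const int* bi, const int* bj, const double* b0, const double* bk, int nb,
    const SubGrid& grid, double eps, double sigma, double rcut,
    const int* ap_bead, const double* apx, const double* ap_b0, double ap_k,
    int nap, std::vector<double>& fap,
    const int* spat_id, int n_spat, std::vector<double>& fsub,
    const double* fext) {
  std::fill(f.begin(), f.end(), 0.0);
  std::fill(fap.begin(), fap.end(), 0.0);
  std::fill(fsub.begin(), fsub.end(), 0.0);
  double epot = 0.0;

  // harmonic bonds  V = 0.5 K (r - b0)^2
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12) stop("overlapping beads in bond %d (r < 1e-6 nm)", b + 1);
    double r = std::sqrt(r2);
    double dr = r - b0[b];
    epot += 0.5 * bk[b] * dr * dr;
    double fmag = -bk[b] * dr / r;  // along (j - i), acting on j
    f[3 * j] += fmag * dx; f[3 * j + 1] += fmag * dy; f[3 * j + 2] += fmag * dz;
    f[3 * i] -= fmag * dx; f[3 * i + 1] -= fmag * dy; f[3 * i + 2] -= fmag * dz;
  }

  // truncated (unshifted) LJ against the frozen substrate
  if (grid.ns > 0 && eps > 0) {
    double rc2 = rcut * rcut;
    double s2 = sigma * sigma;
    for (int i = 0; i < n; ++i) {
      double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      double fx = 0, fy = 0, fz = 0;
      grid.for_neighbours(xi, yi, zi, [&](int j) {
        double dx = xi - grid.sx[j];
        double dy = yi - grid.sy[j];
        double dz = zi - grid.sz[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) return;
        if (r2 < 1e-12) stop("spatula bead overlapping substrate bead");
        double sr2 = s2 / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        epot += 4.0 * eps * (sr12 - sr6);
        double fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;  // F = fr * d
        fx += fr * dx; fy += fr * dy; fz += fr * dz;
      });
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      if (n_spat > 0) {
        int s = spat_id[i] - 1;
        fsub[3 * s] += fx; fsub[3 * s + 1] += fy; fsub[3 * s + 2] += fz;
      }
    }
  }

  // anchor-point springs  V = 0.5 k (|r_bead - r_ap| - b0)^2
  for (int a = 0; a < nap; ++a) {
    int i = ap_bead[a];
    double dx = x[3 * i] - apx[3 * a];
    double dy = x[3 * i + 1] - apx[3 * a + 1];
    double dz = x[3 * i + 2] - apx[3 * a + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;  // zero-length spring exerts no force
    double dr = r - ap_b0[a];
    epot += 0.5 * ap_k * dr * dr;
    double fmag = -ap_k * dr / r;  // on the bead, along (bead - ap)
    f[3 * i] += fmag * dx; f[3 * i + 1] += fmag * dy; f[3 * i + 2] += fmag * dz;
    // reaction on the AP (transferred to the FE node)
    fap[3 * a] -= fmag * dx; fap[3 * a + 1] -= fmag * dy; fap[3 * a + 2] -= fmag * dz;
  }

  // constant external per-bead force (e.g. a static weight)
  if (fext) {
    for (int i = 0; i < 3 * n; ++i) f[i] += fext[i];
  }
  return epot;
}

// [[Rcpp::export(name = ".md_energy_forces_cpp")]]
List md_energy_forces_cpp(NumericMatrix pos,
                          IntegerVector bi, IntegerVector bj,
                          NumericVector b0, NumericVector bk,
                          NumericMatrix sub, double eps, double sigma,
                          double rcut,
                          IntegerVector ap_bead, NumericMatrix ap_pos,
                          NumericVector ap_b0, double ap_k,
                          IntegerVector spat_id, int n_spat,
                          Nullable<NumericMatrix> ext_force = R_NilValue,
                          NumericVector sub_lattice = NumericVector(0)) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  int nb = bi.size(), nap = ap_bead.size();
  std::vector<int> bi0(nb), bj0(nb), ap0(nap), sid(n, 1);
  for (int b = 0; b < nb; ++b) { bi0[b] = bi[b] - 1; bj0[b] = bj[b] - 1; }
  for (int a = 0; a < nap; ++a) ap0[a] = ap_bead[a] - 1;
  if (spat_id.size() == n) for (int i = 0; i < n; ++i) sid[i] = spat_id[i];
  std::vector<double> apx(3 * nap);
  for (int a = 0; a < nap; ++a)
    for (int d = 0; d < 3; ++d) apx[3 * a + d] = ap_pos(a, d);
  SubGrid grid; grid.build(sub, rcut > 0 ? rcut : 1.0, sub_lattice);
  std::vector<double> fap(3 * std::max(nap, 1)), fsub(3 * std::max(n_spat, 1));
  std::vector<double> fe;
  const double* fep = nullptr;
  if (ext_force.isNotNull()) {
    NumericMatrix ef(ext_force);
    fe.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fe[3 * i + d] = ef(i, d);
    fep = fe.data();
  }
  double epot = compute_forces(n, x, f, bi0.data(), bj0.data(),
                               b0.begin(), bk.begin(), nb, grid, eps, sigma,
                               rcut, ap0.data(), apx.data(), ap_b0.begin(),
                               ap_k, nap, fap,
                               sid.data(), n_spat, fsub, fep);
  NumericMatrix F(n, 3), FAP(nap, 3), FSUB(std::max(n_spat, 1), 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = f[3 * i + d];
  for (int a = 0; a < nap; ++a)
    for (int d = 0; d < 3; ++d) FAP(a, d) = fap[3 * a + d];
  for (int s = 0; s < std::max(n_spat, 1); ++s)
    for (int d = 0; d < 3; ++d) FSUB(s, d) = fsub[3 * s + d];
  return List::create(_["energy"] = epot, _["forces"] = F,
                      _["ap_forces"] = FAP, _["sub_forces"] = FSUB);
}

// thermostat velocity scale factor for one group
static double thermo_scale(Rng& rng, double K, int ndf, double Kbar,
                           double dt, double tau, bool berendsen) {
  if (tau <= 0 || ndf <= 0 || K <= 0) return 1.0;
  if (berendsen) {
    double Tratio = Kbar / K;
    double l2 = 1.0 + dt / tau * (Tratio - 1.0);
    if (l2 < 0.25) l2 = 0.25;  // cap extreme rescaling
    if (l2 > 4.0) l2 = 4.0;
    return std::sqrt(l2);
  }
  // stochastic (canonical-sampling) velocity rescaling
  double c = std::exp(-dt / tau);
  if (Kbar <= 0) return std::sqrt(c);  // T0 = 0: pure exponential damping
  double R1 = rng.normal();
  double S = rng.chisq(ndf - 1);
  double a2 = c + (1.0 - c) * (S + R1 * R1) * Kbar / (ndf * K) +
    2.0 * R1 * std::sqrt(c * (1.0 - c) * Kbar / (ndf * K));
  if (a2 < 0) a2 = 0;
  return std::sqrt(a2);
}

// [[Rcpp::export(name = ".md_run_phase_cpp")]]
List md_run_phase_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                      IntegerVector bi, IntegerVector bj,
                      NumericVector b0, NumericVector bk,
                      NumericMatrix sub, double eps, double sigma, double rcut,
                      IntegerVector ap_bead, NumericMatrix ap_pos,
                      NumericVector ap_b0, double ap_k,
                      IntegerVector group, IntegerVector spat_id, int n_spat,
                      double dt, int n_steps, double T0,
                      double tau_out, double tau_in, double kB,
                      double window_frac, double seed,
                      Nullable<NumericMatrix> ext_force = R_NilValue,
                      NumericVector sub_lattice = NumericVector(0)) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
  int nb = bi.size(), nap = ap_bead.size();
  std::vector<int> bi0(nb), bj0(nb), ap0(nap), sid(n, 1);
  for (int b = 0; b < nb; ++b) { bi0[b] = bi[b] - 1; bj0[b] = bj[b] - 1; }
  for (int a = 0; a < nap; ++a) ap0[a] = ap_bead[a] - 1;
  if (spat_id.size() == n) for (int i = 0; i < n; ++i) sid[i] = spat_id[i];
  std::vector<double> apx(3 * std::max(nap, 1));
  for (int a = 0; a < nap; ++a)
    for (int d = 0; d < 3; ++d) apx[3 * a + d] = ap_pos(a, d);
  std::vector<double> fe;
  const double* fep = nullptr;
  if (ext_force.isNotNull()) {
    NumericMatrix ef(ext_force);
    fe.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fe[3 * i + d] = ef(i, d);
    fep = fe.data();
  }
  SubGrid grid; grid.build(sub, rcut > 0 ? rcut : 1.0, sub_lattice);
  std::vector<double> fap(3 * std::max(nap, 1)), fsub(3 * std::max(n_spat, 1));
  Rng rng((uint64_t)(seed < 0 ? -seed : seed) * 2862933555777941757ULL + 3037000493ULL);

  // group bookkeeping: 0 = outside BD (CSVR), 1 = inside BD (Berendsen)
  int n_out = 0, n_in = 0;
  for (int i = 0; i < n; ++i) (group[i] == 1 ? n_in : n_out)++;
  int ndf_out = 3 * n_out, ndf_in = 3 * n_in;
  double Kbar_out = 0.5 * ndf_out * kB * T0;
  double Kbar_in = 0.5 * ndf_in * kB * T0;

  std::vector<double> fap_acc(3 * std::max(nap, 1), 0.0);
  std::vector<double> fsub_acc(3 * std::max(n_spat, 1), 0.0);
  double Tout_acc = 0, Tin_acc = 0;
  int window_start = (int)std::floor(n_steps * (1.0 - window_frac));
  int n_win = 0, n_temp = 0;

  compute_forces(n, x, f, bi0.data(), bj0.data(), b0.begin(), bk.begin(), nb,
                 grid, eps, sigma, rcut, ap0.data(), apx.data(),
                 ap_b0.begin(), ap_k, nap, fap, sid.data(), n_spat, fsub, fep);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / mass[i];
      v[3 * i] += h * f[3 * i];
      v[3 * i + 1] += h * f[3 * i + 1];
      v[3 * i + 2] += h * f[3 * i + 2];
      x[3 * i] += dt * v[3 * i];
      x[3 * i + 1] += dt * v[3 * i + 1];
      x[3 * i + 2] += dt * v[3 * i + 2];
    }
    compute_forces(n, x, f, bi0.data(), bj0.data(), b0.begin(), bk.begin(),
                   nb, grid, eps, sigma, rcut, ap0.data(), apx.data(),
                   ap_b0.begin(), ap_k, nap, fap, sid.data(), n_spat, fsub,
                   fep);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / mass[i];
      v[3 * i] += h * f[3 * i];
      v[3 * i + 1] += h * f[3 * i + 1];
      v[3 * i + 2] += h * f[3 * i + 2];
    }

    // group kinetic energies and thermostats
    if (tau_out > 0 || tau_in > 0) {
      double K_out = 0, K_in = 0;
      for (int i = 0; i < n; ++i) {
        double k = 0.5 * mass[i] * (v[3 * i] * v[3 * i] +
                                    v[3 * i + 1] * v[3 * i + 1] +
                                    v[3 * i + 2] * v[3 * i + 2]);
        if (group[i] == 1) K_in += k; else K_out += k;
      }
      double s_out = thermo_scale(rng, K_out, ndf_out, Kbar_out, dt, tau_out,
                                  false);
      double s_in = thermo_scale(rng, K_in, ndf_in, Kbar_in, dt, tau_in,
                                 true);
      for (int i = 0; i < n; ++i) {
        double s = (group[i] == 1) ? s_in : s_out;
        v[3 * i] *= s; v[3 * i + 1] *= s; v[3 * i + 2] *= s;
      }
      if (ndf_out > 0) { Tout_acc += 2.0 * K_out * s_out * s_out / (ndf_out * kB); }
      if (ndf_in > 0) { Tin_acc += 2.0 * K_in * s_in * s_in / (ndf_in * kB); }
      n_temp++;
    }

    if (step > window_start) {
      for (int a = 0; a < 3 * nap; ++a) fap_acc[a] += fap[a];
      for (int s = 0; s < 3 * n_spat; ++s) fsub_acc[s] += fsub[s];
      n_win++;
    }
    if (step % 200 == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate at MD step %d", step);
    }
  }

  NumericMatrix POS(n, 3), VEL(n, 3), FAP(std::max(nap, 1), 3),
    FSUB(std::max(n_spat, 1), 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { POS(i, d) = x[3 * i + d]; VEL(i, d) = v[3 * i + d]; }
  double wn = n_win > 0 ? (double)n_win : 1.0;
  for (int a = 0; a < nap; ++a)
    for (int d = 0; d < 3; ++d) FAP(a, d) = fap_acc[3 * a + d] / wn;
  for (int s = 0; s < std::max(n_spat, 1); ++s)
    for (int d = 0; d < 3; ++d) FSUB(s, d) = fsub_acc[3 * s + d] / wn;
  return List::create(
    _["pos"] = POS, _["vel"] = VEL,
    _["fap_avg"] = FAP, _["fsub_avg"] = FSUB,
    _["T_out"] = n_temp > 0 ? Tout_acc / n_temp : NA_REAL,
    _["T_in"] = n_temp > 0 ? Tin_acc / n_temp : NA_REAL,
    _["n_window"] = n_win);
}

// [[Rcpp::export(name = ".count_contacts_cpp")]]
IntegerVector count_contacts_cpp(NumericMatrix pos, IntegerVector spat_id,
                                 int n_spat, NumericMatrix sub,
                                 double cutoff,
                                 NumericVector sub_lattice = NumericVector(0)) {
  SubGrid grid; grid.build(sub, cutoff, sub_lattice);
  IntegerVector out(n_spat);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < pos.nrow(); ++i) {
    double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    int cnt = 0;
    grid.for_neighbours(xi, yi, zi, [&](int j) {
      double dx = xi - grid.sx[j], dy = yi - grid.sy[j], dz = zi - grid.sz[j];
      if (dx * dx + dy * dy + dz * dz < c2) cnt++;
    });
    out[spat_id[i] - 1] += cnt;
  }
  return out;
}

// ------------------------------------------------------- mesh components --
// [[Rcpp::export(name = ".cc_label_tets_cpp")]]
List cc_label_tets_cpp(int n_nodes, IntegerMatrix tets) {
  std::vector<int> parent(n_nodes + 1);
  for (int i = 0; i <= n_nodes; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  int m = tets.nrow();
  for (int t = 0; t < m; ++t) {
    unite(tets(t, 0), tets(t, 1));
    unite(tets(t, 0), tets(t, 2));
    unite(tets(t, 0), tets(t, 3));
  }
  IntegerVector node_comp(n_nodes), tet_comp(m);
  for (int i = 1; i <= n_nodes; ++i) node_comp[i - 1] = find(i);
  for (int t = 0; t < m; ++t) tet_comp[t] = find(tets(t, 0));
  return List::create(_["node_comp"] = node_comp, _["tet_comp"] = tet_comp);
}

// ----------------------------------------------------------- P1 assembly --
// Element stiffness for linear (4-node) tetrahedra, isotropic elasticity.
// Returns COO triplets (1-based DOF indices: 3*(node-1)+comp).
// [[Rcpp::export(name = ".fem_assemble_p1_cpp")]]
List fem_assemble_p1_cpp(NumericMatrix nodes, IntegerMatrix tets,
                         double lambda, double mu) {
  int m = tets.nrow();
  std::vector<int> I; I.reserve(144 * (size_t)m);
  std::vector<int> J; J.reserve(144 * (size_t)m);
  std::vector<double> V; V.reserve(144 * (size_t)m);

  // isotropic D (Voigt order xx, yy, zz, xy, yz, xz; engineering shear)
  double D[6][6] = {{0}};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) D[i][j] = lambda;
  for (int i = 0; i < 3; ++i) D[i][i] = lambda + 2 * mu;
  for (int i = 3; i < 6; ++i) D[i][i] = mu;

  for (int t = 0; t < m; ++t) {
    int nd[4] = {tets(t, 0) - 1, tets(t, 1) - 1, tets(t, 2) - 1,
                 tets(t, 3) - 1};
    double X[4][3];
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) X[a][d] = nodes(nd[a], d);
    // Jacobian columns: edges from node 0
    double Jm[3][3];
    for (int d = 0; d < 3; ++d) {
      Jm[d][0] = X[1][d] - X[0][d];
      Jm[d][1] = X[2][d] - X[0][d];
      Jm[d][2] = X[3][d] - X[0][d];
    }
    double det =
      Jm[0][0] * (Jm[1][1] * Jm[2][2] - Jm[1][2] * Jm[2][1]) -
      Jm[0][1] * (Jm[1][0] * Jm[2][2] - Jm[1][2] * Jm[2][0]) +
      Jm[0][2] * (Jm[1][0] * Jm[2][1] - Jm[1][1] * Jm[2][0]);
    if (det <= 0) stop("inverted element Jacobian in element %d", t + 1);
    double vol = det / 6.0;
    // inverse transpose of J gives gradients of the reference coordinates
    double inv[3][3];
    inv[0][0] = (Jm[1][1] * Jm[2][2] - Jm[1][2] * Jm[2][1]) / det;
    inv[0][1] = (Jm[0][2] * Jm[2][1] - Jm[0][1] * Jm[2][2]) / det;
    inv[0][2] = (Jm[0][1] * Jm[1][2] - Jm[0][2] * Jm[1][1]) / det;
    inv[1][0] = (Jm[1][2] * Jm[2][0] - Jm[1][0] * Jm[2][2]) / det;
    inv[1][1] = (Jm[0][0] * Jm[2][2] - Jm[0][2] * Jm[2][0]) / det;
    inv[1][2] = (Jm[0][2] * Jm[1][0] - Jm[0][0] * Jm[1][2]) / det;
    inv[2][0] = (Jm[1][0] * Jm[2][1] - Jm[1][1] * Jm[2][0]) / det;
    inv[2][1] = (Jm[0][1] * Jm[2][0] - Jm[0][0] * Jm[2][1]) / det;
    inv[2][2] = (Jm[0][0] * Jm[1][1] - Jm[0][1] * Jm[1][0]) / det;
    // shape-function gradients: g[a][d] = dN_a/dx_d
    double g[4][3];
    for (int d = 0; d < 3; ++d) {
      g[1][d] = inv[0][d];
      g[2][d] = inv[1][d];
      g[3][d] = inv[2][d];
      g[0][d] = -inv[0][d] - inv[1][d] - inv[2][d];
    }
    // B (6 x 12)
    double B[6][12] = {{0}};
    for (int a = 0; a < 4; ++a) {
      int c = 3 * a;
      B[0][c] = g[a][0];
      B[1][c + 1] = g[a][1];
      B[2][c + 2] = g[a][2];
      B[3][c] = g[a][1]; B[3][c + 1] = g[a][0];
      B[4][c + 1] = g[a][2]; B[4][c + 2] = g[a][1];
      B[5][c] = g[a][2]; B[5][c + 2] = g[a][0];
    }
    double DB[6][12];
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 12; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += D[i][k] * B[k][j];
        DB[i][j] = s;
      }
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += B[k][i] * DB[k][j];
        double ke = s * vol;
        if (ke == 0.0) continue;
        int gi = 3 * nd[i / 3] + i % 3 + 1;
        int gj = 3 * nd[j / 3] + j % 3 + 1;
        I.push_back(gi); J.push_back(gj); V.push_back(ke);
      }
  }
  return List::create(_["i"] = wrap(I), _["j"] = wrap(J), _["v"] = wrap(V));
}
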