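// Compiled kernels: receptor-peptide interaction energy, the refinement
// potential (nonbonded + chain-glue bonds + harmonic positional restraints)
// with its analytic gradient, steepest-descent minimization, and BAOAB
// Langevin sampling. Units: Angstrom, kJ/mol, amu, ps. All pair sums are
// plain double-precision accumulation in a fixed (row-major, i<j) order so
// results are deterministic.

#include <Rcpp.h>

#include <cmath>
#include <cstdint>
using namespace Rcpp;

// acceleration [A/ps^2] = ACC_CONV * force [kJ/mol/A] / mass [amu]
static const double ACC_CONV = 100.0;
static const double KB = 0.00831446; // kJ/mol/K

// --- counter-free sequential splitmix64 stream -----------------------------
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double uniform() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gaussian() {
    double u1 = uniform(), u2 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct System {
  int n;
  std::vector<double> x, y, z;     // coords
  std::vector<double> q, sig, eps; // per-atom nonbonded parameters
  std::vector<int> bi, bj;         // bonds
  std::vector<double> br0;
  double k_bond;
  std::vector<int> ridx;           // restrained atoms
  std::vector<double> rx, ry, rz;  // restraint targets
  double k_restr;
  std::vector<char> excl; // dense n*n matrix (systems are a few hundred atoms)
  double cutoff, dielectric, kcoul;

  bool excluded(int i, int j) const { return excl[(size_t)i * n + j] != 0; }
};

struct EnergyBreakdown {
  double elec = 0, vdw = 0, bond = 0, restraint = 0;
  double total() const { return elec + vdw + bond + restraint; }
};

// Full internal potential and (optionally) its gradient.
static EnergyBreakdown potential(const System& s, std::vector<double>* gx,
                                 std::vector<double>* gy, std::vector<double>* gz) {
  EnergyBreakdown e;
  const double cut2 = s.cutoff * s.cutoff;
  if (gx) {
    std::fill(gx->begin(), gx->end(), 0.0);
    std::fill(gy->begin(), gy->end(), 0.0);
    std::fill(gz->begin(), gz->end(), 0.0);
  }
  for (int i = 0; i < s.n - 1; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      if (s.excluded(i, j)) continue;
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      double r = std::sqrt(r2);
      if (r <= 0.0) stop("coincident atoms (pair %d, %d)", i + 1, j + 1);
      double sij = 0.5 * (s.sig[i] + s.sig[j]);
      double eij = std::sqrt(s.eps[i] * s.eps[j]);
      double qq = s.kcoul * s.q[i] * s.q[j] / s.dielectric;
      double ec = qq / r;
      double sr2 = sij * sij / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      e.elec += ec;
      e.vdw += 4.0 * eij * (sr12 - sr6);
      if (gx) {
        // dE/dr terms
        double dEdr = -ec / r + 4.0 * eij * (-12.0 * sr12 + 6.0 * sr6) / r;
        double f = dEdr / r;
        (*gx)[i] += f * dx; (*gy)[i] += f * dy; (*gz)[i] += f * dz;
        (*gx)[j] -= f * dx; (*gy)[j] -= f * dy; (*gz)[j] -= f * dz;
      }
    }
  }
  for (size_t b = 0; b < s.bi.size(); ++b) {
    int i = s.bi[b], j = s.bj[b];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - s.br0[b];
    e.bond += 0.5 * s.k_bond * dr * dr;
    if (gx && r > 0) {
      double f = s.k_bond * dr / r;
      (*gx)[i] += f * dx; (*gy)[i] += f * dy; (*gz)[i] += f * dz;
      (*gx)[j] -= f * dx; (*gy)[j] -= f * dy; (*gz)[j] -= f * dz;
    }
  }
  for (size_t a = 0; a < s.ridx.size(); ++a) {
    int i = s.ridx[a];
    double dx = s.x[i] - s.rx[a], dy = s.y[i] - s.ry[a], dz = s.z[i] - s.rz[a];
    e.restraint += 0.5 * s.k_restr * (dx * dx + dy * dy + dz * dz);
    if (gx) {
      (*gx)[i] += s.k_restr * dx;
      (*gy)[i] += s.k_restr * dy;
      (*gz)[i] += s.k_restr * dz;
    }
  }
  return e;
}

static System build_system(NumericMatrix coords, NumericVector charge,
                           NumericVector sigma, NumericVector eps,
                           IntegerMatrix bonds, NumericVector bond_r0,
                           double k_bond, IntegerMatrix excl_pairs,
                           IntegerVector restr_idx, NumericMatrix restr_target,
                           double k_restr, double cutoff, double dielectric,
                           double kcoul) {
  System s;
  s.n = coords.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = coords(i, 0); s.y[i] = coords(i, 1); s.z[i] = coords(i, 2);
  }
  s.q = as<std::vector<double>>(charge);
  s.sig = as<std::vector<double>>(sigma);
  s.eps = as<std::vector<double>>(eps);
  for (int b = 0; b < bonds.nrow(); ++b) {
    s.bi.push_back(bonds(b, 0) - 1);
    s.bj.push_back(bonds(b, 1) - 1);
    s.br0.push_back(bond_r0[b]);
  }
  s.k_bond = k_bond;
  s.excl.assign((size_t)s.n * s.n, 0);
  for (int p = 0; p < excl_pairs.nrow(); ++p) {
    int a = excl_pairs(p, 0) - 1, b = excl_pairs(p, 1) - 1;
    s.excl[(size_t)a * s.n + b] = 1;
    s.excl[(size_t)b * s.n + a] = 1;
  }
  for (int a = 0; a < restr_idx.size(); ++a) {
    s.ridx.push_back(restr_idx[a] - 1);
    s.rx.push_back(restr_target(a, 0));
    s.ry.push_back(restr_target(a, 1));
    s.rz.push_back(restr_target(a, 2));
  }
  s.k_restr = k_restr;
  s.cutoff = R_finite(cutoff) ? cutoff : 1e30;
  s.dielectric = dielectric;
  s.kcoul = kcoul;
  return s;
}

// [[Rcpp::export]]
List cpp_cross_energy(NumericMatrix coords, IntegerVector rec_idx,
                      IntegerVector pep_idx, NumericVector charge,
                      NumericVector sigma, NumericVector eps, double cutoff,
                      double dielectric, double kcoul) {
  double cut = R_finite(cutoff) ? cutoff : 1e30;
  double cut2 = cut * cut;
  double elec = 0, vdw = 0;
  for (int a = 0; a < rec_idx.size(); ++a) {
    int i = rec_idx[a] - 1;
    for (int b = 0; b < pep_idx.size(); ++b) {
      int j = pep_idx[b] - 1;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      if (r2 <= 0.0) stop("coincident atoms (receptor atom %d, peptide atom %d)", i + 1, j + 1);
      double r = std::sqrt(r2);
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double eij = std::sqrt(eps[i] * eps[j]);
      elec += kcoul * charge[i] * charge[j] / (dielectric * r);
      double sr2 = sij * sij / r2;
      double sr6 = sr2 * sr2 * sr2;
      vdw += 4.0 * eij * (sr6 * sr6 - sr6);
    }
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw,
                      _["total"] = elec + vdw);
}

// [[Rcpp::export]]
List cpp_potential(NumericMatrix coords, NumericVector charge,
                   NumericVector sigma, NumericVector eps, IntegerMatrix bonds,
                   NumericVector bond_r0, double k_bond,
                   IntegerMatrix excl_pairs, IntegerVector restr_idx,
                   NumericMatrix restr_target, double k_restr, double cutoff,
                   double dielectric, double kcoul, bool grad) {
  System s = build_system(coords, charge, sigma, eps, bonds, bond_r0, k_bond,
                          excl_pairs, restr_idx, restr_target, k_restr, cutoff,
                          dielectric, kcoul);
  std::vector<double> gx, gy, gz;
  if (grad) { gx.resize(s.n); gy.resize(s.n); gz.resize(s.n); }
  EnergyBreakdown e = potential(s, grad ? &gx : nullptr, grad ? &gy : nullptr,
                                grad ? &gz : nullptr);
  List out = List::create(
      _["energy"] = e.total(), _["elec"] = e.elec, _["vdw"] = e.vdw,
      _["bond"] = e.bond, _["restraint"] = e.restraint);
  if (grad) {
    NumericMatrix g(s.n, 3);
    for (int i = 0; i < s.n; ++i) {
      g(i, 0) = gx[i]; g(i, 1) = gy[i]; g(i, 2) = gz[i];
    }
    out["gradient"] = g;
  }
  return out;
}

// Report the closest atom pair (used for the "clashing input" diagnostic).
static void closest_pair(const System& s, int& pi, int& pj, double& pr) {
  pr = R_PosInf; pi = pj = 0;
  for (int i = 0; i < s.n - 1; ++i)
    for (int j = i + 1; j < s.n; ++j) {
      if (s.excluded(i, j)) continue;
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < pr) { pr = r; pi = i + 1; pj = j + 1; }
    }
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, NumericVector charge,
                  NumericVector sigma, NumericVector eps, IntegerMatrix bonds,
                  NumericVector bond_r0, double k_bond,
                  IntegerMatrix excl_pairs, IntegerVector fixed_idx,
                  double cutoff, double dielectric, double kcoul,
                  int max_steps, double initial_step, double tol) {
  // no positional restraints during minimization: fixed atoms are projected
  // out of the gradient instead
  IntegerVector no_restr(0);
  NumericMatrix no_target(0, 3);
  System s = build_system(coords, charge, sigma, eps, bonds, bond_r0, k_bond,
                          excl_pairs, no_restr, no_target, 0.0, cutoff,
                          dielectric, kcoul);
  std::vector<bool> fixed(s.n, false);
  for (int a = 0; a < fixed_idx.size(); ++a) fixed[fixed_idx[a] - 1] = true;

  std::vector<double> gx(s.n), gy(s.n), gz(s.n);
  EnergyBreakdown e = potential(s, &gx, &gy, &gz);
  if (!R_finite(e.total())) {
    int pi, pj; double pr;
    closest_pair(s, pi, pj, pr);
    stop("clashing input: non-finite energy at start (worst pair %d, %d at %.3g A)",
         pi, pj, pr);
  }
  std::vector<double> trace;
  trace.push_back(e.total());
  double alpha = initial_step;
  int steps_done = 0;
  std::vector<double> tx(s.n), ty(s.n), tz(s.n);
  for (int step = 0; step < max_steps; ++step) {
    double gmax = 0;
    for (int i = 0; i < s.n; ++i) {
      if (fixed[i]) { gx[i] = gy[i] = gz[i] = 0.0; continue; }
      gmax = std::max(gmax, std::abs(gx[i]));
      gmax = std::max(gmax, std::abs(gy[i]));
      gmax = std::max(gmax, std::abs(gz[i]));
    }
    if (gmax == 0.0) break;
    // trial displacement: largest component moves by alpha
    for (int i = 0; i < s.n; ++i) {
      tx[i] = s.x[i] - alpha * gx[i] / gmax;
      ty[i] = s.y[i] - alpha * gy[i] / gmax;
      tz[i] = s.z[i] - alpha * gz[i] / gmax;
    }
    std::swap(s.x, tx); std::swap(s.y, ty); std::swap(s.z, tz);
    EnergyBreakdown et = potential(s, &gx, &gy, &gz);
    if (R_finite(et.total()) && et.total() < e.total()) {
      e = et;
      trace.push_back(e.total());
      alpha *= 1.2;
      ++steps_done;
    } else {
      std::swap(s.x, tx); std::swap(s.y, ty); std::swap(s.z, tz); // reject
      EnergyBreakdown er = potential(s, &gx, &gy, &gz); // restore gradient
      e = er;
      alpha *= 0.5;
    }
    if (alpha < tol) break;
  }
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  return List::create(_["coords"] = out, _["trace"] = wrap(trace),
                      _["steps"] = steps_done,
                      _["energy"] = e.total());
}

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords, NumericVector mass,
                  NumericVector charge, NumericVector sigma, NumericVector eps,
                  IntegerMatrix bonds, NumericVector bond_r0, double k_bond,
                  IntegerMatrix excl_pairs, IntegerVector restr_idx,
                  NumericMatrix restr_target, double k_restr, double cutoff,
                  double dielectric, double kcoul, double dt_fs,
                  double temperature, double friction, int n_steps,
                  int frame_interval, double seed) {
  System s = build_system(coords, charge, sigma, eps, bonds, bond_r0, k_bond,
                          excl_pairs, restr_idx, restr_target, k_restr, cutoff,
                          dielectric, kcoul);
  const double dt = dt_fs * 1e-3; // ps
  SplitMix rng((uint64_t)seed * 2654435761ULL + 1442695040888963407ULL);
  std::vector<double> vx(s.n, 0), vy(s.n, 0), vz(s.n, 0);
  std::vector<double> m = as<std::vector<double>>(mass);
  if (temperature > 0) {
    for (int i = 0; i < s.n; ++i) {
      double sd = std::sqrt(ACC_CONV * KB * temperature / m[i]);
      vx[i] = sd * rng.gaussian();
      vy[i] = sd * rng.gaussian();
      vz[i] = sd * rng.gaussian();
    }
  }
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  std::vector<double> gx(s.n), gy(s.n), gz(s.n);
  EnergyBreakdown e = potential(s, &gx, &gy, &gz);

  int n_frames = n_steps / frame_interval;
  List frames(n_frames);
  NumericVector times(n_frames), pot(n_frames), elec(n_frames),
      vdw(n_frames), restr(n_frames);
  int f = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < s.n; ++i) {
      double a = -ACC_CONV / m[i];
      vx[i] += 0.5 * dt * a * gx[i];
      vy[i] += 0.5 * dt * a * gy[i];
      vz[i] += 0.5 * dt * a * gz[i];
    }
    // A: half drift
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
    }
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < s.n; ++i) {
      double sd = temperature > 0
                      ? std::sqrt(ACC_CONV * KB * temperature / m[i])
                      : 0.0;
      vx[i] = c1 * vx[i] + c2 * sd * rng.gaussian();
      vy[i] = c1 * vy[i] + c2 * sd * rng.gaussian();
      vz[i] = c1 * vz[i] + c2 * sd * rng.gaussian();
    }
    // A: half drift
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += 0.5 * dt * vx[i];
      s.y[i] += 0.5 * dt * vy[i];
      s.z[i] += 0.5 * dt * vz[i];
    }
    // B: half kick with new forces
    e = potential(s, &gx, &gy, &gz);
    if (!R_finite(e.total()) || e.total() > 1e6) {
      stop("unstable integration: potential energy diverged at step %d", step);
    }
    for (int i = 0; i < s.n; ++i) {
      double a = -ACC_CONV / m[i];
      vx[i] += 0.5 * dt * a * gx[i];
      vy[i] += 0.5 * dt * a * gy[i];
      vz[i] += 0.5 * dt * a * gz[i];
    }
    if (step % frame_interval == 0 && f < n_frames) {
      NumericMatrix fr(s.n, 3);
      for (int i = 0; i < s.n; ++i) {
        fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i];
      }
      frames[f] = fr;
      times[f] = step * dt;
      pot[f] = e.total();
      elec[f] = e.elec;
      vdw[f] = e.vdw;
      restr[f] = e.restraint;
      ++f;
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["potential"] = pot, _["elec"] = elec, _["vdw"] = vdw,
                      _["restraint"] = restr);
}
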