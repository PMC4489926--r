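// Kremer-Grest bead-spring chain with two optional adhesive pairs:
// WCA excluded volume on all pairs, FENE bonds along the backbone (plus
// permanent adhesion bonds), a short-range attractive Gaussian between
// designated sticky pairs, and an optional harmonic bending term.
// Dynamics: BAOAB Langevin splitting (velocity Verlet when the
// thermostat is off).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

struct Params {
  int n;
  double sigma, eps, mass, kfene, r0, u0, lam, kbend, kbt;
  int tA, tO, sX, sY; // 0-based sticky indices, -1 when the pair is absent
};

static Params parse_params(const List& pl) {
  Params p;
  p.n = as<int>(pl["n_beads"]);
  p.sigma = as<double>(pl["sigma"]);
  p.eps = as<double>(pl["epsilon"]);
  p.mass = as<double>(pl["mass"]);
  p.kfene = as<double>(pl["kappa_fene"]);
  p.r0 = as<double>(pl["r0_fene"]);
  p.u0 = as<double>(pl["u0_sticky"]);
  p.lam = as<double>(pl["lambda_sticky"]);
  p.kbend = as<double>(pl["kappa_bend"]);
  p.kbt = as<double>(pl["kbt"]);
  auto pair_of = [&](const char* key, int& a, int& b) {
    RObject o = pl[key];
    if (o.isNULL()) { a = -1; b = -1; return; }
    IntegerVector v(o);
    if (v.size() != 2 || IntegerVector::is_na(v[0]) || IntegerVector::is_na(v[1])) {
      a = -1; b = -1; return;
    }
    a = v[0] - 1; b = v[1] - 1; // R side is 1-based
  };
  pair_of("sticky_terminal_pair", p.tA, p.tO);
  pair_of("sticky_internal_pair", p.sX, p.sY);
  return p;
}

struct EnergyTerms {
  double wca = 0.0, fene = 0.0, stick = 0.0, bend = 0.0;
  double total() const { return wca + fene + stick + bend; }
};

// WCA + FENE + sticky Gaussian + bending.  Returns false on FENE
// overstretch (bond length at or beyond R0).  `nbr` lists candidate WCA
// pairs (flattened i,j); bonds lists FENE-bonded pairs.
static bool forces_energy(const std::vector<double>& x, const Params& p,
                          const std::vector<std::array<int, 2>>& bonds,
                          const std::vector<int>& nbr,
                          std::vector<double>* f, EnergyTerms* e) {
  const double s2 = p.sigma * p.sigma;
  const double rc2 = std::cbrt(2.0) * s2; // (2^{1/6} sigma)^2
  if (f) std::fill(f->begin(), f->end(), 0.0);

  // WCA over candidate pairs
  for (size_t k = 0; k + 1 < nbr.size(); k += 2) {
    const int i = nbr[k], j = nbr[k + 1];
    const double dx = x[3 * i] - x[3 * j];
    const double dy = x[3 * i + 1] - x[3 * j + 1];
    const double dz = x[3 * i + 2] - x[3 * j + 2];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    const double sr2 = s2 / r2;
    const double sr6 = sr2 * sr2 * sr2;
    if (e) e->wca += 4.0 * p.eps * (sr6 * sr6 - sr6) + p.eps;
    if (f) {
      const double fr = 4.0 * p.eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
      (*f)[3 * i] += fr * dx; (*f)[3 * i + 1] += fr * dy; (*f)[3 * i + 2] += fr * dz;
      (*f)[3 * j] -= fr * dx; (*f)[3 * j + 1] -= fr * dy; (*f)[3 * j + 2] -= fr * dz;
    }
  }

  // FENE bonds
  const double r02 = p.r0 * p.r0;
  const double A = 0.5 * p.kfene * (p.r0 / p.sigma) * (p.r0 / p.sigma);
  for (const auto& b : bonds) {
    const int i = b[0], j = b[1];
    const double dx = x[3 * i] - x[3 * j];
    const double dy = x[3 * i + 1] - x[3 * j + 1];
    const double dz = x[3 * i + 2] - x[3 * j + 2];
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= r02 * (1.0 - 1e-12)) return false;
    if (e) e->fene += -A * std::log1p(-d2 / r02);
    if (f) {
      const double fr = -2.0 * A / (r02 - d2);
      (*f)[3 * i] += fr * dx; (*f)[3 * i + 1] += fr * dy; (*f)[3 * i + 2] += fr * dz;
      (*f)[3 * j] -= fr * dx; (*f)[3 * j + 1] -= fr * dy; (*f)[3 * j + 2] -= fr * dz;
    }
  }

  // sticky Gaussian wells, exactly two possible pairs
  const double rmin = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  const double rmax = rmin + 5.0 * p.sigma;
  const int pr[2][2] = { { p.tA, p.tO }, { p.sX, p.sY } };
  for (int q = 0; q < 2; ++q) {
    const int i = pr[q][0], j = pr[q][1];
    if (i < 0 || j < 0) continue;
    const double dx = x[3 * i] - x[3 * j];
    const double dy = x[3 * i + 1] - x[3 * j + 1];
    const double dz = x[3 * i + 2] - x[3 * j + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < rmin || r > rmax) continue;
    const double g = std::exp(-(r - rmin) * (r - rmin) / (2.0 * p.lam * p.lam));
    if (e) e->stick += -p.u0 * g;
    if (f) {
      const double dudr = p.u0 * (r - rmin) / (p.lam * p.lam) * g;
      const double fr = -dudr / r;
      (*f)[3 * i] += fr * dx; (*f)[3 * i + 1] += fr * dy; (*f)[3 * i + 2] += fr * dz;
      (*f)[3 * j] -= fr * dx; (*f)[3 * j + 1] -= fr * dy; (*f)[3 * j + 2] -= fr * dz;
    }
  }

  // bending: harmonic in the triplet angle about pi
  if (p.kbend > 0.0) {
    for (int i = 1; i + 1 < p.n; ++i) {
      const double ax = x[3 * (i - 1)] - x[3 * i];
      const double ay = x[3 * (i - 1) + 1] - x[3 * i + 1];
      const double az = x[3 * (i - 1) + 2] - x[3 * i + 2];
      const double bx = x[3 * (i + 1)] - x[3 * i];
      const double by = x[3 * (i + 1) + 1] - x[3 * i + 1];
      const double bz = x[3 * (i + 1) + 2] - x[3 * i + 2];
      const double r1 = std::sqrt(ax * ax + ay * ay + az * az);
      const double r2 = std::sqrt(bx * bx + by * by + bz * bz);
      const double cx = ay * bz - az * by;
      const double cy = az * bx - ax * bz;
      const double cz = ax * by - ay * bx;
      const double sn = std::sqrt(cx * cx + cy * cy + cz * cz) / (r1 * r2);
      const double cs = (ax * bx + ay * by + az * bz) / (r1 * r2);
      const double th = std::atan2(sn, cs);
      const double dth = th - M_PI;
      if (e) e->bend += 0.5 * p.kbend * dth * dth;
      if (f) {
        const double a = -p.kbend * dth / std::max(sn, 1e-8);
        const double a11 = a * cs / (r1 * r1);
        const double a12 = -a / (r1 * r2);
        const double a22 = a * cs / (r2 * r2);
        const double f1x = a11 * ax + a12 * bx, f1y = a11 * ay + a12 * by, f1z = a11 * az + a12 * bz;
        const double f3x = a22 * bx + a12 * ax, f3y = a22 * by + a12 * ay, f3z = a22 * bz + a12 * az;
        (*f)[3 * (i - 1)] += f1x; (*f)[3 * (i - 1) + 1] += f1y; (*f)[3 * (i - 1) + 2] += f1z;
        (*f)[3 * (i + 1)] += f3x; (*f)[3 * (i + 1) + 1] += f3y; (*f)[3 * (i + 1) + 2] += f3z;
        (*f)[3 * i] -= f1x + f3x; (*f)[3 * i + 1] -= f1y + f3y; (*f)[3 * i + 2] -= f1z + f3z;
      }
    }
  }
  return true;
}

static std::vector<std::array<int, 2>> backbone_bonds(const Params& p, bool bt, bool bi) {
  std::vector<std::array<int, 2>> bonds;
  bonds.reserve(p.n + 1);
  for (int i = 0; i + 1 < p.n; ++i) bonds.push_back({ i, i + 1 });
  if (bt && p.tA >= 0) bonds.push_back({ p.tA, p.tO });
  if (bi && p.sX >= 0) bonds.push_back({ p.sX, p.sY });
  return bonds;
}

static void all_pairs(int n, std::vector<int>& nbr) {
  nbr.clear();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { nbr.push_back(i); nbr.push_back(j); }
}

static void build_verlet(const std::vector<double>& x, int n, double rl2,
                         std::vector<int>& nbr) {
  nbr.clear();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < rl2) { nbr.push_back(i); nbr.push_back(j); }
    }
  }
}

static std::vector<double> flatten(const NumericMatrix& m) {
  std::vector<double> x(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = m(i, k);
  return x;
}

static NumericMatrix unflatten(const std::vector<double>& x, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = x[3 * i + k];
  return m;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, List params, bool bonded_term, bool bonded_int) {
  Params p = parse_params(params);
  std::vector<double> x = flatten(pos);
  std::vector<int> nbr;
  all_pairs(p.n, nbr);
  auto bonds = backbone_bonds(p, bonded_term, bonded_int);
  EnergyTerms e;
  bool ok = forces_energy(x, p, bonds, nbr, nullptr, &e);
  return List::create(_["ok"] = ok, _["wca"] = e.wca, _["fene"] = e.fene,
                      _["stick"] = e.stick, _["bend"] = e.bend,
                      _["total"] = e.total());
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, List params, bool bonded_term, bool bonded_int) {
  Params p = parse_params(params);
  std::vector<double> x = flatten(pos);
  std::vector<int> nbr;
  all_pairs(p.n, nbr);
  auto bonds = backbone_bonds(p, bonded_term, bonded_int);
  std::vector<double> f(3 * p.n);
  bool ok = forces_energy(x, p, bonds, nbr, &f, nullptr);
  return List::create(_["ok"] = ok, _["forces"] = unflatten(f, p.n));
}

static double pair_dist(const std::vector<double>& x, int i, int j) {
  const double dx = x[3 * i] - x[3 * j];
  const double dy = x[3 * i + 1] - x[3 * j + 1];
  const double dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, List params,
             bool bonded_term, bool bonded_int,
             double dt, double gamma, double capture_distance,
             double max_steps, double seed,
             bool thermostat, double sample_every, bool sample_frames,
             bool stop_on_circularization) {
  Params p = parse_params(params);
  const int n = p.n;
  std::vector<double> x = flatten(pos), v = flatten(vel);
  std::vector<double> f(3 * n);
  auto bonds = backbone_bonds(p, bonded_term, bonded_int);

  const double skin = 0.35 * p.sigma;
  const double rc = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  const double rl2 = (rc + skin) * (rc + skin);
  std::vector<int> nbr;
  std::vector<double> xref(3 * n);
  build_verlet(x, n, rl2, nbr);
  xref = x;

  Xoshiro rng(static_cast<uint64_t>(seed));
  const double c1 = (thermostat && gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (thermostat && gamma > 0.0)
      ? std::sqrt((1.0 - c1 * c1) * p.kbt / p.mass) : 0.0;
  const bool do_o = thermostat && gamma > 0.0;

  bool bt = bonded_term, bi = bonded_int;
  bool circular = false;
  double cap_step_term = -1.0, cap_step_int = -1.0;
  std::string err = "";

  std::vector<double> ke_samples;
  std::vector<double> frames;
  long long nsamp_every = (sample_every > 0.5) ? (long long)(sample_every + 0.5) : 0;

  if (!forces_energy(x, p, bonds, nbr, &f, nullptr)) {
    err = "fene_overstretch";
  }

  const double half = 0.5 * dt, invm = 1.0 / p.mass;
  long long steps_done = 0;
  const long long mx = (long long)max_steps;

  for (long long step = 0; step < mx && err.empty(); ++step) {
    for (int k = 0; k < 3 * n; ++k) v[k] += half * invm * f[k]; // B
    for (int k = 0; k < 3 * n; ++k) x[k] += half * v[k];        // A
    if (do_o) {
      for (int k = 0; k < 3 * n; ++k) v[k] = c1 * v[k] + c2 * rng.gauss(); // O
    }
    for (int k = 0; k < 3 * n; ++k) x[k] += half * v[k];        // A

    // neighbor list freshness
    double md2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = x[3 * i] - xref[3 * i];
      const double dy = x[3 * i + 1] - xref[3 * i + 1];
      const double dz = x[3 * i + 2] - xref[3 * i + 2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > md2) md2 = d2;
    }
    if (md2 > 0.25 * skin * skin) {
      build_verlet(x, n, rl2, nbr);
      xref = x;
    }

    if (!forces_energy(x, p, bonds, nbr, &f, nullptr)) {
      err = "fene_overstretch";
      steps_done = step + 1;
      break;
    }
    for (int k = 0; k < 3 * n; ++k) v[k] += half * invm * f[k]; // B
    steps_done = step + 1;

    // permanent adhesion events (flags never unset)
    if (p.sX >= 0 && !bi && pair_dist(x, p.sX, p.sY) <= capture_distance) {
      bi = true;
      bonds.push_back({ p.sX, p.sY });
      cap_step_int = (double)steps_done;
    }
    if (p.tA >= 0 && !bt && pair_dist(x, p.tA, p.tO) <= capture_distance) {
      bt = true;
      bonds.push_back({ p.tA, p.tO });
      cap_step_term = (double)steps_done;
      circular = true;
      if (stop_on_circularization) break;
    }

    if (nsamp_every > 0 && steps_done % nsamp_every == 0) {
      double ke = 0.0;
      for (int k = 0; k < 3 * n; ++k) ke += v[k] * v[k];
      ke_samples.push_back(0.5 * p.mass * ke);
      if (sample_frames) frames.insert(frames.end(), x.begin(), x.end());
    }
  }

  List out = List::create(
      _["positions"] = unflatten(x, n), _["velocities"] = unflatten(v, n),
      _["steps"] = (double)steps_done, _["circularized"] = circular,
      _["bonded_termini"] = bt, _["bonded_internal"] = bi,
      _["capture_step_terminal"] = cap_step_term,
      _["capture_step_internal"] = cap_step_int,
      _["error"] = err, _["ke_samples"] = wrap(ke_samples));
  if (sample_frames) {
    NumericVector fr = wrap(frames);
    out["frames"] = fr; // flat, 3*n per frame, row-major by bead
  }
  return out;
}
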