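// Velocity-Verlet Langevin integrator for the bead-spring ring melt:
// WCA pair repulsion, FENE bonds, cosine bending, and per-monomer
// thermostat temperatures (hot/cold labels).  Single-threaded,
// deterministic given (seed, step offset).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 keyed by (seed, global step, atom, lane).
// Reproducible independently of evaluation order.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0, 1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// one standard Gaussian for (seed, step, atom, lane) via Box-Muller
static inline double gauss_at(uint64_t seed, uint64_t step, uint64_t atom,
                              uint64_t lane) {
  uint64_t k = splitmix64(seed ^ (step * 0xD1342543DE82EF95ULL));
  uint64_t h1 = splitmix64(k ^ (atom * 0x2545F4914F6CDD1DULL + lane));
  uint64_t h2 = splitmix64(h1 ^ 0x632BE59BD9B4E019ULL);
  double u1 = u01(h1), u2 = u01(h2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// variance-1 uniform kick (LAMMPS fix-langevin semantics): sqrt(12)*(u-1/2).
// The thermostat applies ~1/(gamma*dt) kicks per relaxation time, so the
// stationary velocity distribution is Maxwell-Boltzmann by the CLT.
static inline double ukick_at(uint64_t seed, uint64_t step, uint64_t atom,
                              uint64_t lane) {
  uint64_t k = splitmix64(seed ^ (step * 0xD1342543DE82EF95ULL));
  uint64_t h1 = splitmix64(k ^ (atom * 0x2545F4914F6CDD1DULL + lane));
  return 3.4641016151377544 * (u01(h1) - 0.5);
}

// ---------------------------------------------------------------------------
struct Params {
  double eps, sig, mass, rmax, K, ktheta, gamma, dt, Th, Tc;
  double rc2;      // WCA cutoff squared
  double clamp_r;  // force clamp radius (<=0 disables)
  double max_disp; // per-step displacement limit (<=0 disables)
};

static inline double minimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// WCA force magnitude / r  (i.e. F(r)/r) at squared distance r2, plus clamp
static inline double wca_fdivr(double r2, const Params& p, bool clamped) {
  double s2 = p.sig * p.sig / r2;
  double s6 = s2 * s2 * s2;
  double f = 24.0 * p.eps * s6 * (2.0 * s6 - 1.0) / r2; // F(r)/r
  if (clamped && p.clamp_r > 0 && r2 < p.clamp_r * p.clamp_r) {
    // constant-magnitude continuation below clamp_r
    double rc2c = p.clamp_r * p.clamp_r;
    double c2 = p.sig * p.sig / rc2c;
    double c6 = c2 * c2 * c2;
    double fc = 24.0 * p.eps * c6 * (2.0 * c6 - 1.0) / p.clamp_r; // F(clamp_r)
    f = fc / std::sqrt(r2);
  }
  return f;
}

// ---------------------------------------------------------------------------
// Neighbour list (half list), built via cell binning or brute force.
// ---------------------------------------------------------------------------
struct NeighList {
  std::vector<int> first, second;
  std::vector<double> ref; // positions at build time (wrapped)
  double rlist;

  void build(const std::vector<double>& x, int n, const double* box,
             double rl) {
    rlist = rl;
    first.clear();
    second.clear();
    ref.assign(x.begin(), x.begin() + 3 * n);
    double rl2 = rl * rl;
    int ncx = (int)std::floor(box[0] / rl);
    int ncy = (int)std::floor(box[1] / rl);
    int ncz = (int)std::floor(box[2] / rl);
    // never allocate far more cells than atoms (dilute systems)
    int cap = (int)std::ceil(std::cbrt((double)n)) + 1;
    if (ncx > cap) ncx = cap;
    if (ncy > cap) ncy = cap;
    if (ncz > cap) ncz = cap;
    if (ncx >= 3 && ncy >= 3 && ncz >= 3 && n > 64) {
      int ncells = ncx * ncy * ncz;
      std::vector<int> head(ncells, -1), next(n, -1);
      for (int i = 0; i < n; ++i) {
        int cx = (int)(x[3 * i] / box[0] * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
        int cy = (int)(x[3 * i + 1] / box[1] * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
        int cz = (int)(x[3 * i + 2] / box[2] * ncz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
        int c = (cz * ncy + cy) * ncx + cx;
        next[i] = head[c];
        head[c] = i;
      }
      for (int cz = 0; cz < ncz; ++cz)
        for (int cy = 0; cy < ncy; ++cy)
          for (int cx = 0; cx < ncx; ++cx) {
            int c = (cz * ncy + cy) * ncx + cx;
            for (int i = head[c]; i >= 0; i = next[i]) {
              // same cell
              for (int j = next[i]; j >= 0; j = next[j]) {
                double dx = minimg(x[3 * i] - x[3 * j], box[0]);
                double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
                double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
                if (dx * dx + dy * dy + dz * dz < rl2) {
                  first.push_back(i);
                  second.push_back(j);
                }
              }
              // half the neighbour cells
              for (int dcz = 0; dcz <= 1; ++dcz)
                for (int dcy = (dcz == 0 ? 0 : -1); dcy <= 1; ++dcy)
                  for (int dcx = (dcz == 0 && dcy == 0 ? 1 : -1); dcx <= 1; ++dcx) {
                    int c2x = (cx + dcx + ncx) % ncx;
                    int c2y = (cy + dcy + ncy) % ncy;
                    int c2z = (cz + dcz + ncz) % ncz;
                    int c2 = (c2z * ncy + c2y) * ncx + c2x;
                    if (c2 == c) continue;
                    for (int j = head[c2]; j >= 0; j = next[j]) {
                      double dx = minimg(x[3 * i] - x[3 * j], box[0]);
                      double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
                      double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
                      if (dx * dx + dy * dy + dz * dz < rl2) {
                        first.push_back(i);
                        second.push_back(j);
                      }
                    }
                  }
            }
          }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = minimg(x[3 * i] - x[3 * j], box[0]);
          double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
          double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
          if (dx * dx + dy * dy + dz * dz < rl2) {
            first.push_back(i);
            second.push_back(j);
          }
        }
    }
  }

  bool stale(const std::vector<double>& x, int n, const double* box,
             double skin) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = minimg(x[i] - ref[i], box[0]);
      double dy = minimg(x[i + 1] - ref[i + 1], box[1]);
      double dz = minimg(x[i + 2] - ref[i + 2], box[2]);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// conservative forces; returns index of first overstretched bond or -1
static int forces(const std::vector<double>& x, int n, const double* box,
                  const IntegerMatrix& bonds, const IntegerMatrix& angles,
                  const Params& p, const NeighList& nl, bool clamped,
                  std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  // pairs
  size_t np = nl.first.size();
  for (size_t k = 0; k < np; ++k) {
    int i = nl.first[k], j = nl.second[k];
    double dx = minimg(x[3 * i] - x[3 * j], box[0]);
    double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < p.rc2) {
      double fr = wca_fdivr(r2, p, clamped);
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  }
  // FENE bonds
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = minimg(x[3 * i] - x[3 * j], box[0]);
    double dy = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    double rm2 = p.rmax * p.rmax;
    if (r2 >= rm2) return b;
    double fr = -p.K / (1.0 - r2 / rm2); // F(r)/r, attractive
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
  }
  // cosine bending  U = k_theta (1 + cos theta)
  int na = angles.nrow();
  for (int a = 0; a < na; ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double ax = minimg(x[3 * i] - x[3 * j], box[0]);
    double ay = minimg(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double az = minimg(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double bx = minimg(x[3 * k] - x[3 * j], box[0]);
    double by = minimg(x[3 * k + 1] - x[3 * j + 1], box[1]);
    double bz = minimg(x[3 * k + 2] - x[3 * j + 2], box[2]);
    double ra2 = ax * ax + ay * ay + az * az;
    double rb2 = bx * bx + by * by + bz * bz;
    double ra = std::sqrt(ra2), rb = std::sqrt(rb2);
    double c = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    // F_i = -k d(cos)/d a_vec, etc.
    double fix = -p.ktheta * (bx / (ra * rb) - c * ax / ra2);
    double fiy = -p.ktheta * (by / (ra * rb) - c * ay / ra2);
    double fiz = -p.ktheta * (bz / (ra * rb) - c * az / ra2);
    double fkx = -p.ktheta * (ax / (ra * rb) - c * bx / rb2);
    double fky = -p.ktheta * (ay / (ra * rb) - c * by / rb2);
    double fkz = -p.ktheta * (az / (ra * rb) - c * bz / rb2);
    f[3 * i] += fix; f[3 * i + 1] += fiy; f[3 * i + 2] += fiz;
    f[3 * k] += fkx; f[3 * k + 1] += fky; f[3 * k + 2] += fkz;
    f[3 * j] -= fix + fkx; f[3 * j + 1] -= fiy + fky; f[3 * j + 2] -= fiz + fkz;
  }
  return -1;
}

// [[Rcpp::export(name = ".cpp_md_run")]]
List cpp_md_run(NumericMatrix pos, IntegerMatrix img, NumericMatrix vel,
                NumericVector box_, IntegerMatrix bonds, IntegerMatrix angles,
                IntegerVector hot, List par, int nsteps, int stride,
                double seed_d, double step_offset_d, double clamp_r,
                double max_disp, double skin) {
  int n = pos.nrow();
  Params p;
  p.eps = par["epsilon"]; p.sig = par["sigma"]; p.mass = par["mass"];
  p.rmax = par["r_max"]; p.K = par["K"]; p.ktheta = par["k_theta"];
  p.gamma = par["gamma"]; p.dt = par["dt"];
  p.Th = par["T_h"]; p.Tc = par["T_c"];
  double rc = std::pow(2.0, 1.0 / 6.0) * p.sig;
  p.rc2 = rc * rc;
  bool clamped = clamp_r > 0;
  p.clamp_r = clamped ? clamp_r : -1.0;
  p.max_disp = max_disp;
  uint64_t seed = (uint64_t)seed_d;
  uint64_t off = (uint64_t)step_offset_d;
  double box[3] = { box_[0], box_[1], box_[2] };

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  std::vector<int> im(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
      im[3 * i + d] = img(i, d);
    }

  // per-atom thermostat noise prefactors sqrt(2 m gamma kB T / dt)
  std::vector<double> pref(n);
  for (int i = 0; i < n; ++i) {
    double T = hot[i] ? p.Th : p.Tc;
    pref[i] = std::sqrt(2.0 * p.mass * p.gamma * T / p.dt);
  }

  double rlist = rc + skin;
  NeighList nl;
  nl.build(x, n, box, rlist);

  int bad = forces(x, n, box, bonds, angles, p, nl, clamped, f);
  if (bad < 0) {
    // add friction + noise at step "off" using initial velocities
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        f[3 * i + d] += -p.gamma * p.mass * v[3 * i + d] +
                        pref[i] * ukick_at(seed, off, (uint64_t)i, (uint64_t)d);
  }

  int nframes = (stride > 0) ? nsteps / stride : 0;
  NumericVector fpos, fvel;
  if (nframes > 0) {
    fpos = NumericVector((R_xlen_t)nframes * n * 3);
    fvel = NumericVector((R_xlen_t)nframes * n * 3);
  }
  int frame = 0;
  int status_bond = bad;
  int steps_done = 0;

  if (bad < 0) for (int s = 0; s < nsteps; ++s) {
    double hdtm = 0.5 * p.dt / p.mass;
    for (int i = 0; i < 3 * n; ++i) v[i] += hdtm * f[i];
    // position update (with optional displacement limit)
    for (int i = 0; i < n; ++i) {
      double dx = p.dt * v[3 * i], dy = p.dt * v[3 * i + 1], dz = p.dt * v[3 * i + 2];
      if (p.max_disp > 0) {
        double dr = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dr > p.max_disp) {
          double sc = p.max_disp / dr;
          dx *= sc; dy *= sc; dz *= sc;
          v[3 * i] *= sc; v[3 * i + 1] *= sc; v[3 * i + 2] *= sc;
        }
      }
      x[3 * i] += dx; x[3 * i + 1] += dy; x[3 * i + 2] += dz;
      for (int d = 0; d < 3; ++d) {
        if (x[3 * i + d] >= box[d]) { x[3 * i + d] -= box[d]; im[3 * i + d] += 1; }
        else if (x[3 * i + d] < 0) { x[3 * i + d] += box[d]; im[3 * i + d] -= 1; }
      }
    }
    if (nl.stale(x, n, box, skin)) nl.build(x, n, box, rlist);
    status_bond = forces(x, n, box, bonds, angles, p, nl, clamped, f);
    if (status_bond >= 0) break;
    uint64_t gstep = off + (uint64_t)s + 1;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        f[3 * i + d] += -p.gamma * p.mass * v[3 * i + d] +
                        pref[i] * ukick_at(seed, gstep, (uint64_t)i, (uint64_t)d);
    for (int i = 0; i < 3 * n; ++i) v[i] += hdtm * f[i];
    steps_done = s + 1;
    if (stride > 0 && (s + 1) % stride == 0 && frame < nframes) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          // store unwrapped positions
          fpos[(R_xlen_t)frame * n * 3 + (R_xlen_t)i * 3 + d] =
            x[3 * i + d] + box[d] * im[3 * i + d];
          fvel[(R_xlen_t)frame * n * 3 + (R_xlen_t)i * 3 + d] = v[3 * i + d];
        }
      ++frame;
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix opos(n, 3), ovel(n, 3);
  IntegerMatrix oimg(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      opos(i, d) = x[3 * i + d];
      ovel(i, d) = v[3 * i + d];
      oimg(i, d) = im[3 * i + d];
    }
  return List::create(
    _["pos"] = opos, _["img"] = oimg, _["vel"] = ovel,
    _["frames_pos"] = fpos, _["frames_vel"] = fvel, _["n_frames"] = frame,
    _["steps_done"] = steps_done, _["overstretched_bond"] = status_bond + 1);
}

// Diagnostic: global minimum non-bonded pair distance (minimum image).
// [[Rcpp::export(name = ".cpp_min_pair_dist")]]
double cpp_min_pair_dist(NumericMatrix pos, NumericVector box_,
                         IntegerMatrix bonds) {
  int n = pos.nrow();
  double box[3] = { box_[0], box_[1], box_[2] };
  std::vector<std::vector<int> > bonded(n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    bonded[bonds(b, 0)].push_back(bonds(b, 1));
    bonded[bonds(b, 1)].push_back(bonds(b, 0));
  }
  double best = 1e300;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool skip = false;
      for (size_t k = 0; k < bonded[i].size(); ++k)
        if (bonded[i][k] == j) { skip = true; break; }
      if (skip) continue;
      double dx = minimg(pos(i, 0) - pos(j, 0), box[0]);
      double dy = minimg(pos(i, 1) - pos(j, 1), box[1]);
      double dz = minimg(pos(i, 2) - pos(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
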