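// DPD engine: cell-list pair forces (conservative / dissipative / random),
// harmonic bonds, soft wall potential, hard reflecting slit boundaries,
// Groot-Warren modified velocity-Verlet integration.
//
// Reduced units throughout: r_c = kT = m0 = 1.  Species are coded
// A = 0, B = 1, S = 2, W = 3.  Box kinds: 0 = bulk (periodic x,y,z,
// coordinates in [0, L)), 1 = slit (reflecting planes at x = +-D/2,
// frozen wall beads outside them, periodic y,z).

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Deterministic, platform-independent RNG (splitmix64-seeded xoshiro256+).
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // zero-mean unit-variance uniform variate on [-sqrt(3), sqrt(3)]
  double theta() { return (2.0 * unif() - 1.0) * 1.7320508075688772; }
  // standard normal (Box-Muller; used only for velocity seeding)
  double gauss() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

struct Box {
  int kind;              // 0 bulk, 1 slit
  double Lx, Ly, Lz;     // Lx = D for slits
  double x_c, a_wall;    // slit wall potential
  double xlo, xhi;       // spatial extent in x covered by the cell grid
};

inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
  return d;
}

struct System {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> species;
  std::vector<char> frozen;
  std::vector<int> mobile;    // indices of mobile beads
  // bonds
  std::vector<int> bi, bj;
  double K, r0;
  // interactions
  double a[4][4];
  double gamma, sigma;
  Box box;
  long overlap_count = 0;
};

struct CellList {
  int ncx, ncy, ncz;
  double cwx, cwy, cwz;
  std::vector<int> head, nxt;
  bool brute = false;

  void build(const System& S) {
    const Box& b = S.box;
    double spanx = b.xhi - b.xlo;
    ncx = std::max(1, (int)std::floor(spanx));
    ncy = std::max(1, (int)std::floor(b.Ly));
    ncz = std::max(1, (int)std::floor(b.Lz));
    // periodic dims need >= 3 cells for a unique half-stencil sweep
    brute = (ncy < 3 || ncz < 3 || (b.kind == 0 && ncx < 3));
    if (brute) return;
    cwx = spanx / ncx; cwy = b.Ly / ncy; cwz = b.Lz / ncz;
    head.assign((size_t)ncx * ncy * ncz, -1);
    nxt.assign(S.n, -1);
    for (int i = 0; i < S.n; ++i) {
      int cx = (int)((S.x[i] - b.xlo) / cwx);
      int cy = (int)(S.y[i] / cwy);
      int cz = (int)(S.z[i] / cwz);
      if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
      if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
      if (cz < 0) cz = 0; if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// accumulate all pair terms for the (i, j) pair
inline void pair_force(System& S, int i, int j, bool with_pair_thermo,
                       Rng* rng, double inv_sqrt_dt) {
  if (S.frozen[i] && S.frozen[j]) return;
  double dx = S.x[i] - S.x[j];
  double dy = S.y[i] - S.y[j];
  double dz = S.z[i] - S.z[j];
  if (S.box.kind == 0) dx = min_image(dx, S.box.Lx);
  dy = min_image(dy, S.box.Ly);
  dz = min_image(dz, S.box.Lz);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= 1.0) {
    // a random draw is still consumed only for interacting pairs, so the
    // stream is a deterministic function of geometry; nothing to do here
    return;
  }
  double r = std::sqrt(r2);
  if (r < 1e-12) { S.overlap_count++; return; }  // direction undefined
  double ex = dx / r, ey = dy / r, ez = dz / r;
  double w = 1.0 - r;  // w_R(r); w_D = w_R^2
  double aij = S.a[S.species[i]][S.species[j]];
  double f = aij * w;  // conservative magnitude along +e (repulsive on i)
  if (with_pair_thermo) {
    double dvx = S.vx[i] - S.vx[j];
    double dvy = S.vy[i] - S.vy[j];
    double dvz = S.vz[i] - S.vz[j];
    double vdote = dvx * ex + dvy * ey + dvz * ez;
    f += -S.gamma * w * w * vdote;
    f += S.sigma * w * rng->theta() * inv_sqrt_dt;
  }
  S.fx[i] += f * ex; S.fy[i] += f * ey; S.fz[i] += f * ez;
  S.fx[j] -= f * ex; S.fy[j] -= f * ey; S.fz[j] -= f * ez;
}

void compute_forces(System& S, CellList& cl, bool with_pair_thermo,
                    bool with_bonds, bool with_wall, Rng* rng, double dt) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  cl.build(S);
  if (cl.brute) {
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j)
        pair_force(S, i, j, with_pair_thermo, rng, inv_sqrt_dt);
  } else {
    // half stencil: self cell (j > i) plus 13 forward neighbours
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    bool perx = (S.box.kind == 0);
    for (int cz = 0; cz < cl.ncz; ++cz)
      for (int cy = 0; cy < cl.ncy; ++cy)
        for (int cx = 0; cx < cl.ncx; ++cx) {
          int c = (cz * cl.ncy + cy) * cl.ncx + cx;
          for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
            for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
              pair_force(S, i, j, with_pair_thermo, rng, inv_sqrt_dt);
          for (int k = 0; k < 13; ++k) {
            int nx = cx + off[k][0], ny = cy + off[k][1], nz = cz + off[k][2];
            if (perx) nx = (nx + cl.ncx) % cl.ncx;
            else if (nx < 0 || nx >= cl.ncx) continue;
            ny = (ny + cl.ncy) % cl.ncy;
            nz = (nz + cl.ncz) % cl.ncz;
            int c2 = (nz * cl.ncy + ny) * cl.ncx + nx;
            for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j])
                pair_force(S, i, j, with_pair_thermo, rng, inv_sqrt_dt);
          }
        }
  }

  if (with_bonds) {
    for (size_t b = 0; b < S.bi.size(); ++b) {
      int i = S.bi[b], j = S.bj[b];
      double dx = S.x[i] - S.x[j];
      double dy = S.y[i] - S.y[j];
      double dz = S.z[i] - S.z[j];
      if (S.box.kind == 0) dx = min_image(dx, S.box.Lx);
      dy = min_image(dy, S.box.Ly);
      dz = min_image(dz, S.box.Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;  // zero extension force at coincidence (r0 = 0)
      // U = (K/2)(r - r0)^2  ->  F_i = -K (r - r0) e_ij
      double f = -S.K * (r - S.r0) / r;
      S.fx[i] += f * dx; S.fy[i] += f * dy; S.fz[i] += f * dz;
      S.fx[j] -= f * dx; S.fy[j] -= f * dy; S.fz[j] -= f * dz;
    }
  }

  if (with_wall && S.box.kind == 1) {
    double half = 0.5 * S.box.Lx;
    for (int idx : S.mobile) {
      double d = half - std::fabs(S.x[idx]);  // distance to nearest plane
      if (d < S.box.x_c && d >= 0.0) {
        double mag = S.box.a_wall * (1.0 - d / S.box.x_c);
        // directed into the slit (away from the nearest plane)
        S.fx[idx] += (S.x[idx] > 0 ? -mag : mag);
      }
    }
  }
}

System make_system(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                   LogicalVector frozen, IntegerVector bond_i,
                   IntegerVector bond_j, double K, double r0,
                   NumericMatrix a, double gamma, double sigma, List box) {
  System S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  S.species.resize(S.n); S.frozen.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.species[i] = species[i];
    S.frozen[i] = frozen[i] ? 1 : 0;
    if (!S.frozen[i]) S.mobile.push_back(i);
  }
  S.bi.assign(bond_i.begin(), bond_i.end());
  S.bj.assign(bond_j.begin(), bond_j.end());
  S.K = K; S.r0 = r0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) S.a[i][j] = a(i, j);
  S.gamma = gamma; S.sigma = sigma;
  S.box.kind = as<int>(box["kind"]);
  S.box.Lx = as<double>(box["Lx"]);
  S.box.Ly = as<double>(box["Ly"]);
  S.box.Lz = as<double>(box["Lz"]);
  S.box.x_c = box.containsElementNamed("x_c") ? as<double>(box["x_c"]) : 0.0;
  S.box.a_wall = box.containsElementNamed("a_wall") ? as<double>(box["a_wall"]) : 0.0;
  if (S.box.kind == 0) { S.box.xlo = 0.0; S.box.xhi = S.box.Lx; }
  else { S.box.xlo = -0.5 * S.box.Lx - 1.0; S.box.xhi = 0.5 * S.box.Lx + 1.0; }
  return S;
}

double instantaneous_kT(const System& S) {
  int nm = (int)S.mobile.size();
  if (nm < 2) return 0.0;
  double ke2 = 0.0;
  for (int i : S.mobile)
    ke2 += S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
  return ke2 / (3.0 * nm - 3.0);
}

} // namespace

// [[Rcpp::export]]
List cpp_dpd_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 LogicalVector frozen, IntegerVector bond_i,
                 IntegerVector bond_j, double K, double r0, NumericMatrix a,
                 double gamma, double sigma, List box, double dt,
                 double lambda, int pre_steps, int steps, int sample_period,
                 int log_period, double seed) {
  System S = make_system(pos, vel, species, frozen, bond_i, bond_j, K, r0,
                         a, gamma, sigma, box);
  CellList cl;
  Rng rng((uint64_t)seed);

  int total = pre_steps + steps;
  int nframes = (sample_period > 0) ? steps / sample_period : 0;
  List frames(nframes);
  int nlog = (log_period > 0) ? total / log_period + 1 : 1;
  NumericMatrix log(nlog, 5);  // step, kT, px, py, pz
  int fidx = 0, lidx = 0;

  compute_forces(S, cl, true, true, true, &rng, dt);

  auto log_state = [&](int step) {
    if (lidx >= nlog) return;
    double px = 0, py = 0, pz = 0;
    for (int i : S.mobile) { px += S.vx[i]; py += S.vy[i]; pz += S.vz[i]; }
    log(lidx, 0) = step; log(lidx, 1) = instantaneous_kT(S);
    log(lidx, 2) = px; log(lidx, 3) = py; log(lidx, 4) = pz;
    ++lidx;
  };
  log_state(0);

  for (int step = 1; step <= total; ++step) {
    // position update + lambda velocity prediction
    for (int i : S.mobile) {
      S.x[i] += dt * S.vx[i] + 0.5 * dt * dt * S.fx[i];
      S.y[i] += dt * S.vy[i] + 0.5 * dt * dt * S.fy[i];
      S.z[i] += dt * S.vz[i] + 0.5 * dt * dt * S.fz[i];
      if (!std::isfinite(S.x[i]) || !std::isfinite(S.y[i]) ||
          !std::isfinite(S.z[i]))
        stop("non-finite coordinate at step %d, bead %d", step, i + 1);
    }
    // stash old force and old velocity, predict velocity
    std::vector<double> ofx = S.fx, ofy = S.fy, ofz = S.fz;
    std::vector<double> ovx = S.vx, ovy = S.vy, ovz = S.vz;
    for (int i : S.mobile) {
      S.vx[i] += lambda * dt * S.fx[i];
      S.vy[i] += lambda * dt * S.fy[i];
      S.vz[i] += lambda * dt * S.fz[i];
    }
    // boundaries: wrap / reflect; reflection also flips the stored old
    // normal velocity so the corrector is applied in the reflected frame
    if (S.box.kind == 1) {
      double half = 0.5 * S.box.Lx;
      for (int i : S.mobile) {
        for (int guard = 0; guard < 8 && std::fabs(S.x[i]) > half; ++guard) {
          if (S.x[i] > half) S.x[i] = 2 * half - S.x[i];
          else S.x[i] = -2 * half - S.x[i];
          S.vx[i] = -S.vx[i];
          ovx[i] = -ovx[i];
          ofx[i] = -ofx[i];
        }
        S.y[i] -= S.box.Ly * std::floor(S.y[i] / S.box.Ly);
        S.z[i] -= S.box.Lz * std::floor(S.z[i] / S.box.Lz);
      }
    } else {
      for (int i : S.mobile) {
        S.x[i] -= S.box.Lx * std::floor(S.x[i] / S.box.Lx);
        S.y[i] -= S.box.Ly * std::floor(S.y[i] / S.box.Ly);
        S.z[i] -= S.box.Lz * std::floor(S.z[i] / S.box.Lz);
      }
    }
    compute_forces(S, cl, true, true, true, &rng, dt);
    // corrector
    for (int i : S.mobile) {
      S.vx[i] = ovx[i] + 0.5 * dt * (ofx[i] + S.fx[i]);
      S.vy[i] = ovy[i] + 0.5 * dt * (ofy[i] + S.fy[i]);
      S.vz[i] = ovz[i] + 0.5 * dt * (ofz[i] + S.fz[i]);
    }
    if (log_period > 0 && step % log_period == 0) log_state(step);
    if (step > pre_steps && sample_period > 0 &&
        (step - pre_steps) % sample_period == 0 && fidx < nframes) {
      NumericMatrix p(S.n, 3), v(S.n, 3);
      for (int i = 0; i < S.n; ++i) {
        p(i, 0) = S.x[i]; p(i, 1) = S.y[i]; p(i, 2) = S.z[i];
        v(i, 0) = S.vx[i]; v(i, 1) = S.vy[i]; v(i, 2) = S.vz[i];
      }
      frames[fidx++] = List::create(_["pos"] = p, _["vel"] = v,
                                    _["step"] = step);
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["frames"] = frames,
                      _["log"] = log(Range(0, std::max(0, lidx - 1)), _),
                      _["overlaps"] = (double)S.overlap_count);
}

// Single force evaluation, used to cross-check the engine against a plain
// R reference implementation.  Random contributions are excluded so the
// result is deterministic.
// [[Rcpp::export]]
NumericMatrix cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                                 IntegerVector species, LogicalVector frozen,
                                 IntegerVector bond_i, IntegerVector bond_j,
                                 double K, double r0, NumericMatrix a,
                                 double gamma, List box,
                                 bool with_dissipative, bool with_bonds,
                                 bool with_wall) {
  System S = make_system(pos, vel, species, frozen, bond_i, bond_j, K, r0,
                         a, gamma, /*sigma=*/0.0, box);
  CellList cl;
  Rng rng(1);
  if (!with_dissipative) S.gamma = 0.0;
  compute_forces(S, cl, true, with_bonds, with_wall, &rng, 1.0);
  NumericMatrix f(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    f(i, 0) = S.fx[i]; f(i, 1) = S.fy[i]; f(i, 2) = S.fz[i];
  }
  return f;
}

// Count B-B contact pairs (r < rc) between distinct chains.
// Returns a 3-column matrix: chain_i, chain_j (chain_i < chain_j), count.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, IntegerVector chain,
                                NumericVector boxlen, LogicalVector periodic,
                                double rc) {
  int n = pos.nrow();
  double rc2 = rc * rc;
  std::map<std::pair<int, int>, int> counts;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j]) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (periodic[0]) dx = min_image(dx, boxlen[0]);
      if (periodic[1]) dy = min_image(dy, boxlen[1]);
      if (periodic[2]) dz = min_image(dz, boxlen[2]);
      if (dx * dx + dy * dy + dz * dz < rc2) {
        int ci = chain[i], cj = chain[j];
        if (ci > cj) std::swap(ci, cj);
        counts[{ci, cj}]++;
      }
    }
  }
  IntegerMatrix out(counts.size(), 3);
  int k = 0;
  for (auto& kv : counts) {
    out(k, 0) = kv.first.first;
    out(k, 1) = kv.first.second;
    out(k, 2) = kv.second;
    ++k;
  }
  return out;
}

// Unwrap a connected point cloud across periodic boundaries: BFS over the
// adjacency graph (minimum-image distance < cutoff), placing each newly
// reached point at its minimum image relative to its BFS parent.  Returns
// the unwrapped coordinates plus a flag marking components whose extent
// exceeds half a periodic box length (ambiguous unwrap).
// [[Rcpp::export]]
List cpp_unwrap(NumericMatrix pos, NumericVector boxlen,
                LogicalVector periodic, double cutoff) {
  int n = pos.nrow();
  NumericMatrix out(n, 3);
  std::vector<char> seen(n, 0);
  double c2 = cutoff * cutoff;
  std::vector<int> queue;
  int ncomp = 0;
  for (int start = 0; start < n; ++start) {
    if (seen[start]) continue;
    ++ncomp;
    seen[start] = 1;
    out(start, 0) = pos(start, 0);
    out(start, 1) = pos(start, 1);
    out(start, 2) = pos(start, 2);
    queue.clear();
    queue.push_back(start);
    size_t qi = 0;
    while (qi < queue.size()) {
      int i = queue[qi++];
      for (int j = 0; j < n; ++j) {
        if (seen[j]) continue;
        double dx = pos(j, 0) - pos(i, 0);
        double dy = pos(j, 1) - pos(i, 1);
        double dz = pos(j, 2) - pos(i, 2);
        if (periodic[0]) dx = min_image(dx, boxlen[0]);
        if (periodic[1]) dy = min_image(dy, boxlen[1]);
        if (periodic[2]) dz = min_image(dz, boxlen[2]);
        if (dx * dx + dy * dy + dz * dz < c2) {
          seen[j] = 1;
          out(j, 0) = out(i, 0) + dx;
          out(j, 1) = out(i, 1) + dy;
          out(j, 2) = out(i, 2) + dz;
          queue.push_back(j);
        }
      }
    }
  }
  bool ambiguous = false;
  for (int d = 0; d < 3; ++d) {
    if (!periodic[d]) continue;
    double lo = out(0, d), hi = out(0, d);
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, out(i, d));
      hi = std::max(hi, out(i, d));
    }
    if (hi - lo > 0.5 * boxlen[d]) ambiguous = true;
  }
  return List::create(_["pos"] = out, _["n_components"] = ncomp,
                      _["ambiguous"] = ambiguous);
}
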