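// Metropolis Monte Carlo for the hard-sphere Kratky-Porod bead chain.
//
// Chain: N beads, fixed bond length = bead diameter d, bending energy
// U/kBT = -g * sum_i cos(theta_i) over the N-2 interior bond angles.
// Moves: pivot, crank-shaft, and generalized MOS (inversion, reflection,
// interchange); all preserve every bond length by construction.  Hard-sphere
// overlap (|r_i - r_j| < d for |i-j| >= 2) rejects a proposal outright;
// otherwise the usual Metropolis criterion on the bending energy applies.
// Overlap detection uses hashed linked cell lists with cell edge d.
//
// Energy bookkeeping: every move either transforms contiguous blocks rigidly
// or permutes window-interior angles among themselves, so the energy change
// reduces to the few junction angles each move computes explicitly.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// externals from knots.cpp
typedef std::array<double, 3> V3;
std::array<long long, 3> mc_analyze_hook(const std::vector<V3>& r, Xoshiro& rng);

namespace {

struct CellGrid {
  double cell;
  uint32_t mask;
  std::vector<int> head;   // bucket -> first bead (-1 empty)
  std::vector<int> nxt;    // bead -> next bead in bucket
  std::vector<int> bucket_of;

  void init(int n, double cell_size) {
    cell = cell_size;
    int H = 4;
    while (H < 4 * n) H <<= 1;
    mask = (uint32_t)(H - 1);
    head.assign(H, -1);
    nxt.assign(n, -1);
    bucket_of.assign(n, -1);
  }
  inline uint32_t hash_cell(int64_t ix, int64_t iy, int64_t iz) const {
    uint64_t h = (uint64_t)ix * 0x9E3779B185EBCA87ULL ^
                 (uint64_t)iy * 0xC2B2AE3D27D4EB4FULL ^
                 (uint64_t)iz * 0x165667B19E3779F9ULL;
    h ^= h >> 29;
    return (uint32_t)h & mask;
  }
  inline uint32_t bucket(double px, double py, double pz) const {
    return hash_cell((int64_t)std::floor(px / cell),
                     (int64_t)std::floor(py / cell),
                     (int64_t)std::floor(pz / cell));
  }
  void insert(int i, double px, double py, double pz) {
    uint32_t b = bucket(px, py, pz);
    nxt[i] = head[b];
    head[b] = i;
    bucket_of[i] = (int)b;
  }
  void remove(int i) {
    int b = bucket_of[i];
    int cur = head[b];
    if (cur == i) { head[b] = nxt[i]; return; }
    while (cur >= 0) {
      if (nxt[cur] == i) { nxt[cur] = nxt[i]; return; }
      cur = nxt[cur];
    }
  }
};

struct Sampler {
  int N;
  double g, d, d2tol;
  bool ideal;
  std::vector<double> x, y, z;     // current coordinates
  std::vector<double> px, py, pz;  // proposal arrays, kept synced with x,y,z
  std::vector<char> moved;
  CellGrid grid;
  Xoshiro rng;
  double U;
  long long att[5] = {0, 0, 0, 0, 0}, acc[5] = {0, 0, 0, 0, 0};

  Sampler(const NumericMatrix& start, double g_, double d_, bool ideal_,
          uint64_t seed)
      : N(start.nrow()), g(g_), d(d_), ideal(ideal_), rng(seed) {
    x.resize(N); y.resize(N); z.resize(N);
    for (int i = 0; i < N; ++i) {
      x[i] = start(i, 0); y[i] = start(i, 1); z[i] = start(i, 2);
    }
    px = x; py = y; pz = z;
    moved.assign(N, 0);
    d2tol = d * d * (1.0 - 1e-9);
    if (!ideal) {
      grid.init(N, d);
      for (int i = 0; i < N; ++i) grid.insert(i, x[i], y[i], z[i]);
    }
    U = total_energy();
  }

  inline double cos_angle(int i, const std::vector<double>& X,
                          const std::vector<double>& Y,
                          const std::vector<double>& Z) const {
    double ax = X[i] - X[i - 1], ay = Y[i] - Y[i - 1], az = Z[i] - Z[i - 1];
    double bx = X[i + 1] - X[i], by = Y[i + 1] - Y[i], bz = Z[i + 1] - Z[i];
    double nab = std::sqrt((ax * ax + ay * ay + az * az) *
                           (bx * bx + by * by + bz * bz));
    return (ax * bx + ay * by + az * bz) / nab;
  }
  double total_energy() const {
    double s = 0.0;
    for (int i = 1; i < N - 1; ++i) s += cos_angle(i, x, y, z);
    return -g * s;
  }

  // energy difference over an explicit list of candidate angle indices
  double delta_U(std::vector<int>& cand) {
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    double s = 0.0;
    for (int i : cand) {
      if (i < 1 || i > N - 2) continue;
      s += cos_angle(i, px, py, pz) - cos_angle(i, x, y, z);
    }
    return -g * s;
  }

  // hard-sphere test of moved beads at proposal positions; rigid_internal
  // skips moved-vs-moved pairs (their mutual distances are unchanged)
  bool overlap(const std::vector<int>& idx, bool rigid_internal) {
    for (int i : idx) {
      int64_t ix = (int64_t)std::floor(px[i] / grid.cell);
      int64_t iy = (int64_t)std::floor(py[i] / grid.cell);
      int64_t iz = (int64_t)std::floor(pz[i] / grid.cell);
      for (int64_t cx = ix - 1; cx <= ix + 1; ++cx)
        for (int64_t cy = iy - 1; cy <= iy + 1; ++cy)
          for (int64_t cz = iz - 1; cz <= iz + 1; ++cz) {
            int j = grid.head[grid.hash_cell(cx, cy, cz)];
            for (; j >= 0; j = grid.nxt[j]) {
              if (moved[j] || std::abs(i - j) < 2) continue;
              double dx = px[i] - x[j], dy = py[i] - y[j], dz = pz[i] - z[j];
              if (dx * dx + dy * dy + dz * dz < d2tol) return true;
            }
          }
    }
    if (!rigid_internal) {
      for (size_t a = 0; a < idx.size(); ++a)
        for (size_t b = a + 1; b < idx.size(); ++b) {
          int i = idx[a], j = idx[b];
          if (std::abs(i - j) < 2) continue;
          double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
          if (dx * dx + dy * dy + dz * dz < d2tol) return true;
        }
    }
    return false;
  }

  void reset_proposal(const std::vector<int>& idx) {
    for (int i : idx) {
      px[i] = x[i]; py[i] = y[i]; pz[i] = z[i];
      moved[i] = 0;
    }
  }

  bool decide(const std::vector<int>& idx, std::vector<int>& cand_angles,
              bool rigid_internal, int mtype) {
    ++att[mtype];
    double dU = delta_U(cand_angles);
    if (dU > 0 && rng.unif() >= std::exp(-dU)) {
      reset_proposal(idx);
      return false;
    }
    if (!ideal) {
      for (int i : idx) moved[i] = 1;
      bool bad = overlap(idx, rigid_internal);
      if (bad) { reset_proposal(idx); return false; }
      for (int i : idx) grid.remove(i);
    }
    for (int i : idx) {
      x[i] = px[i]; y[i] = py[i]; z[i] = pz[i];
      moved[i] = 0;
    }
    if (!ideal)
      for (int i : idx) grid.insert(i, x[i], y[i], z[i]);
    U += dU;
    ++acc[mtype];
    return true;
  }

  static void rotation_matrix(const double* axis, double ang, double R[3][3]) {
    double c = std::cos(ang), s = std::sin(ang), t = 1 - c;
    double ux = axis[0], uy = axis[1], uz = axis[2];
    R[0][0] = c + ux * ux * t; R[0][1] = ux * uy * t - uz * s; R[0][2] = ux * uz * t + uy * s;
    R[1][0] = uy * ux * t + uz * s; R[1][1] = c + uy * uy * t; R[1][2] = uy * uz * t - ux * s;
    R[2][0] = uz * ux * t - uy * s; R[2][1] = uz * uy * t + ux * s; R[2][2] = c + uz * uz * t;
  }

  inline void apply_rot(int i, const double R[3][3], double ox, double oy,
                        double oz) {
    double vx = x[i] - ox, vy = y[i] - oy, vz = z[i] - oz;
    px[i] = ox + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
    py[i] = oy + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
    pz[i] = oz + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
  }

  // rigid rotation of the shorter side about an internal bead
  void pivot() {
    int p = 1 + rng.unif_int(N - 2);
    bool tail = (N - 1 - p) <= p;
    double axis[3];
    rng.unit_vector(axis);
    double ang = rng.unif() * M_PI;
    if (ang == 0.0) ang = M_PI;
    double R[3][3];
    rotation_matrix(axis, ang, R);
    int a = tail ? p + 1 : 0, b = tail ? N - 1 : p - 1;
    std::vector<int> idx;
    idx.reserve(b - a + 1);
    // order beads outward from the pivot so an overlap (typically near the
    // hinge) aborts the scan early
    if (tail)
      for (int i = a; i <= b; ++i) { apply_rot(i, R, x[p], y[p], z[p]); idx.push_back(i); }
    else
      for (int i = b; i >= a; --i) { apply_rot(i, R, x[p], y[p], z[p]); idx.push_back(i); }
    std::vector<int> ang_cand{p};  // only the angle at the pivot bead changes
    decide(idx, ang_cand, true, 0);
  }

  void crankshaft(int max_window) {
    if (N < 4) return;
    int wmax = std::min(max_window, N - 2);
    int w = 2 + rng.unif_int(wmax - 1);  // j - i in [2, wmax]
    int i = rng.unif_int(N - w);
    int j = i + w;
    double ax = x[j] - x[i], ay = y[j] - y[i], az = z[j] - z[i];
    double nn = std::sqrt(ax * ax + ay * ay + az * az);
    if (nn < 1e-12) return;
    double axis[3] = {ax / nn, ay / nn, az / nn};
    double ang = rng.unif() * 2.0 * M_PI;
    double R[3][3];
    rotation_matrix(axis, ang, R);
    std::vector<int> idx;
    idx.reserve(w - 1);
    for (int k = i + 1; k < j; ++k) {
      apply_rot(k, R, x[i], y[i], z[i]);
      idx.push_back(k);
    }
    std::vector<int> cand{i, i + 1, j - 1, j};
    decide(idx, cand, true, 1);
  }

  // MOS inversion: reverse the window's bond order, equivalently point
  // reflection of the interior through the junction midpoint; interior
  // angles permute among themselves so only the junction angles enter dU
  void mos_inversion(int max_window) {
    if (N < 4) return;
    int wmax = std::min(max_window, N - 1);
    int w = 2 + rng.unif_int(wmax - 1);  // bonds in window
    int i = rng.unif_int(N - w);
    int j = i + w;
    double sx = x[i] + x[j], sy = y[i] + y[j], sz = z[i] + z[j];
    std::vector<int> idx;
    idx.reserve(w - 1);
    for (int k = i + 1; k < j; ++k) {
      int m = i + j - k;
      px[k] = sx - x[m]; py[k] = sy - y[m]; pz[k] = sz - z[m];
      idx.push_back(k);
    }
    if (idx.empty()) return;
    std::vector<int> cand{i, j};
    decide(idx, cand, true, 2);
  }

  // MOS reflection: reflect the window interior through the plane normal to
  // the junction chord through its midpoint, then reverse the order; both
  // junction beads are fixed and the map is an isometry
  void mos_reflection(int max_window) {
    if (N < 4) return;
    int wmax = std::min(max_window, N - 1);
    int w = 2 + rng.unif_int(wmax - 1);
    int i = rng.unif_int(N - w);
    int j = i + w;
    double ax = x[j] - x[i], ay = y[j] - y[i], az = z[j] - z[i];
    double nn2 = ax * ax + ay * ay + az * az;
    if (nn2 < 1e-24) return;
    double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]),
           mz = 0.5 * (z[i] + z[j]);
    std::vector<int> idx;
    idx.reserve(w - 1);
    for (int k = i + 1; k < j; ++k) {
      int m = i + j - k;
      double vx = x[m] - mx, vy = y[m] - my, vz = z[m] - mz;
      double h = 2.0 * (vx * ax + vy * ay + vz * az) / nn2;
      px[k] = mx + vx - h * ax;
      py[k] = my + vy - h * ay;
      pz[k] = mz + vz - h * az;
      idx.push_back(k);
    }
    if (idx.empty()) return;
    std::vector<int> cand{i, j};
    decide(idx, cand, true, 3);
  }

  // MOS interchange: swap two disjoint equal-length bond windows; window
  // interiors and the stretch between them move rigidly, and window-interior
  // angles swap pairwise, leaving only the four junction angles in dU
  void mos_interchange(int max_window) {
    if (N < 6) return;
    int lmax = std::min(max_window / 2, (N - 1) / 2 - 1);
    if (lmax < 1) return;
    int L = 1 + rng.unif_int(lmax);
    int amax = N - 1 - 2 * L;  // a in [0, amax)
    if (amax < 1) return;
    int a = rng.unif_int(amax);
    int bmax = std::min(a + L + 2 * max_window, N - 1 - L);
    int b = a + L + rng.unif_int(bmax - (a + L) + 1);
    double s1x = x[a + L] - x[a], s1y = y[a + L] - y[a], s1z = z[a + L] - z[a];
    double s2x = x[b + L] - x[b], s2y = y[b + L] - y[b], s2z = z[b + L] - z[b];
    double tx = s2x - s1x, ty = s2y - s1y, tz = s2z - s1z;
    if (tx * tx + ty * ty + tz * tz < 1e-24) return;
    // window 1 beads take window-2 bonds
    double cx = x[a], cy = y[a], cz = z[a];
    for (int k = 0; k < L; ++k) {
      cx += x[b + k + 1] - x[b + k];
      cy += y[b + k + 1] - y[b + k];
      cz += z[b + k + 1] - z[b + k];
      int bead = a + k + 1;
      if (bead <= b + L - 1) { px[bead] = cx; py[bead] = cy; pz[bead] = cz; }
    }
    // middle stretch translates rigidly
    for (int bead = a + L + 1; bead <= b; ++bead) {
      px[bead] = x[bead] + tx; py[bead] = y[bead] + ty; pz[bead] = z[bead] + tz;
    }
    // window 2 beads take window-1 bonds, from the shifted bead b
    cx = x[b] + tx; cy = y[b] + ty; cz = z[b] + tz;
    for (int k = 0; k < L - 1; ++k) {
      cx += x[a + k + 1] - x[a + k];
      cy += y[a + k + 1] - y[a + k];
      cz += z[a + k + 1] - z[a + k];
      px[b + k + 1] = cx; py[b + k + 1] = cy; pz[b + k + 1] = cz;
    }
    std::vector<int> idx;
    idx.reserve(b + L - a - 1);
    for (int bead = a + 1; bead <= b + L - 1; ++bead) idx.push_back(bead);
    std::vector<int> cand{a, a + L, b, b + L};
    decide(idx, cand, false, 4);
  }

  void step(const double* cump, int max_window) {
    double u = rng.unif();
    if (u < cump[0]) pivot();
    else if (u < cump[1]) crankshaft(max_window);
    else if (u < cump[2]) mos_inversion(max_window);
    else if (u < cump[3]) mos_reflection(max_window);
    else mos_interchange(max_window);
  }
};

}  // namespace

// probs: c(pivot, crankshaft, mos_inversion, mos_reflection, mos_interchange)
// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix start, double g, double d, int n_samples,
                int sampling_interval, int burn_in, NumericVector probs,
                int seed, bool ideal, bool return_frames, bool analyze_knots,
                int max_window = 32) {
  if (start.nrow() < 3) stop("chain needs at least 3 beads");
  if (probs.size() != 5) stop("move mix needs 5 probabilities");
  double cum = 0.0, cump[5];
  for (int i = 0; i < 5; ++i) { cum += probs[i]; cump[i] = cum; }
  if (std::fabs(cum - 1.0) > 1e-8) stop("move probabilities must sum to 1");

  Sampler s(start, g, d, ideal, (uint64_t)seed);
  Xoshiro knot_rng(((uint64_t)seed) ^ 0xabcdef1234567890ULL);
  int N = s.N;
  long long sweep_moves = N;

  for (long long i = 0; i < (long long)burn_in * sweep_moves; ++i)
    s.step(cump, max_window);

  List frames(return_frames ? n_samples : 0);
  NumericVector det1(analyze_knots ? n_samples : 0),
      det2(analyze_knots ? n_samples : 0);
  NumericVector energy(n_samples);

  for (int samp = 0; samp < n_samples; ++samp) {
    for (long long i = 0; i < (long long)sampling_interval * sweep_moves; ++i)
      s.step(cump, max_window);
    s.U = s.total_energy();  // refresh against float drift
    energy[samp] = s.U;
    if (return_frames) {
      NumericMatrix m(N, 3);
      for (int i = 0; i < N; ++i) {
        m(i, 0) = s.x[i]; m(i, 1) = s.y[i]; m(i, 2) = s.z[i];
      }
      frames[samp] = m;
    }
    if (analyze_knots) {
      std::vector<V3> r(N);
      for (int i = 0; i < N; ++i) r[i] = V3{s.x[i], s.y[i], s.z[i]};
      std::array<long long, 3> res = mc_analyze_hook(r, knot_rng);
      det1[samp] = (double)res[0];
      det2[samp] = (double)res[1];
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(N, 3);
  for (int i = 0; i < N; ++i) {
    fin(i, 0) = s.x[i]; fin(i, 1) = s.y[i]; fin(i, 2) = s.z[i];
  }
  NumericVector attv(5), accv(5);
  for (int i = 0; i < 5; ++i) {
    attv[i] = (double)s.att[i];
    accv[i] = (double)s.acc[i];
  }
  return List::create(_["frames"] = frames, _["det1"] = det1,
                      _["det2"] = det2, _["energy"] = energy,
                      _["final"] = fin, _["attempted"] = attv,
                      _["accepted"] = accv);
}
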