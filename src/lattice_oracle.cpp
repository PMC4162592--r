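// Brute-force reference enumerator for self-avoiding virtual-bond walks on
// the diamond lattice.  Written independently of lattice_enum.cpp: plain
// depth-first recursion over the four step directions, per-coordinate
// feasibility bounds, no symmetry reductions.  Used only by tests and
// table validation as the oracle the production enumerator is compared
// against.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace saw_oracle {

static const int STEP[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};

struct Walk {
  int n;
  bool to_target;
  int tgt[3];
  int fixed_step, fixed_k;
  std::vector<int> vx, vy, vz;      // vertices 0..n
  std::vector<signed char> vis;     // dense cube, own indexing
  int span, width;
  std::vector<std::array<int, 4>> mm;
  double total;

  long cube(int x, int y, int z) const {
    return (x + span) + (long)width * ((y + span) + (long)width * (z + span));
  }
};

static bool neighbours(const Walk &w, int a, int b) {
  int d0 = w.vx[b] - w.vx[a], d1 = w.vy[b] - w.vy[a], d2 = w.vz[b] - w.vz[a];
  if (d0 * d0 != 1 || d1 * d1 != 1 || d2 * d2 != 1) return false;
  bool even = (w.vx[a] % 2) == 0;
  int s = d0 * d1 * d2;
  return even ? s > 0 : s < 0;
}

// a constraint is verified once all four of its vertices exist; before
// that it is hopeless if no anchor/partner combination can still be
// brought within one lattice bond
static bool mm_hopeless(const Walk &w, int placed) {
  for (const auto &c : w.mm) {
    int last = std::max(std::max(c[0], c[1]), std::max(c[2], c[3]));
    if (last < placed) continue;
    if (last == placed) {
      bool ok = false;
      for (int i : {c[0], c[1]})
        for (int j : {c[2], c[3]})
          if (neighbours(w, i, j)) ok = true;
      if (!ok) return true;
      continue;
    }
    bool maybe = false;
    for (int side = 0; side < 2 && !maybe; ++side) {
      for (int t = 0; t < 2 && !maybe; ++t) {
        int u = side == 0 ? c[t] : c[2 + t];
        for (int o = 0; o < 2 && !maybe; ++o) {
          int j = side == 0 ? c[2 + o] : c[o];
          int lo = std::min(u, j), hi = std::max(u, j);
          if (lo > placed) { maybe = true; break; }
          if (hi <= placed) {
            if (neighbours(w, lo, hi)) maybe = true;
            continue;
          }
          int left = hi - placed;
          int e0 = std::abs(w.vx[placed] - w.vx[lo]);
          int e1 = std::abs(w.vy[placed] - w.vy[lo]);
          int e2 = std::abs(w.vz[placed] - w.vz[lo]);
          int far = std::max(e0, std::max(e1, e2));
          if (far <= left + 1) maybe = true;
        }
      }
    }
    if (!maybe) return true;
  }
  return false;
}

static void extend(Walk &w, int placed) {
  if (placed == w.n) {
    if (w.to_target &&
        (w.vx[w.n] != w.tgt[0] || w.vy[w.n] != w.tgt[1] || w.vz[w.n] != w.tgt[2]))
      return;
    w.total += 1.0;
    return;
  }
  int next = placed + 1;
  bool even = (w.vx[placed] % 2) == 0;
  for (int k = 0; k < 4; ++k) {
    if (w.fixed_step == next && w.fixed_k != k) continue;
    int nx, ny, nz;
    if (even) {
      nx = w.vx[placed] + STEP[k][0];
      ny = w.vy[placed] + STEP[k][1];
      nz = w.vz[placed] + STEP[k][2];
    } else {
      nx = w.vx[placed] - STEP[k][0];
      ny = w.vy[placed] - STEP[k][1];
      nz = w.vz[placed] - STEP[k][2];
    }
    if (w.to_target) {
      int rem = w.n - next;
      int g0 = std::abs(nx - w.tgt[0]);
      int g1 = std::abs(ny - w.tgt[1]);
      int g2 = std::abs(nz - w.tgt[2]);
      if (g0 > rem || g1 > rem || g2 > rem) continue;
      if (((g0 + rem) % 2) != 0) continue;
      if (((g1 + rem) % 2) != 0) continue;
      if (((g2 + rem) % 2) != 0) continue;
    }
    long ci = w.cube(nx, ny, nz);
    if (w.vis[ci]) continue;
    w.vx[next] = nx; w.vy[next] = ny; w.vz[next] = nz;
    if (!w.mm.empty() && mm_hopeless(w, next)) continue;
    w.vis[ci] = 1;
    extend(w, next);
    w.vis[ci] = 0;
  }
}

}  // namespace saw_oracle

// [[Rcpp::export]]
double vf_saw_count_oracle_cpp(int nsteps, bool closed,
                               IntegerVector target,
                               IntegerMatrix blocked,
                               IntegerMatrix mmpairs,
                               IntegerVector fixed_step) {
  using saw_oracle::Walk;
  if (nsteps == 0) return 1.0;
  Walk w;
  w.n = nsteps;
  w.to_target = closed;
  if (closed) { w.tgt[0] = target[0]; w.tgt[1] = target[1]; w.tgt[2] = target[2]; }
  w.fixed_step = fixed_step.size() == 2 ? fixed_step[0] : -1;
  w.fixed_k = fixed_step.size() == 2 ? fixed_step[1] : -1;
  w.span = nsteps + 2;
  w.width = 2 * w.span + 1;
  w.vx.assign(nsteps + 1, 0);
  w.vy.assign(nsteps + 1, 0);
  w.vz.assign(nsteps + 1, 0);
  w.vis.assign((size_t)w.width * w.width * w.width, 0);
  w.vis[w.cube(0, 0, 0)] = 1;
  for (int b = 0; b < blocked.nrow(); ++b)
    w.vis[w.cube(blocked(b, 0), blocked(b, 1), blocked(b, 2))] = 1;
  for (int m = 0; m < mmpairs.nrow(); ++m)
    w.mm.push_back({mmpairs(m, 0), mmpairs(m, 1), mmpairs(m, 2), mmpairs(m, 3)});
  w.total = 0.0;
  saw_oracle::extend(w, 0);
  return w.total;
}
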