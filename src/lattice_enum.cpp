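// Production self-avoiding-walk enumerator on the diamond lattice.
//
// The virtual-bond chain lives on the diamond (tetrahedral) lattice encoded
// as the subset of Z^3 reachable from the origin under the parity rule:
// from a vertex with even x the four neighbors are p + D[k], from odd x
// p - D[k], with D = {(1,1,1),(1,-1,-1),(-1,1,-1),(-1,-1,1)}.
//
// Counts are exact. The DFS is iterative with an explicit stack and a
// dense visited grid addressed by precomputed per-parity flat offsets; it
// prunes on (a) max-coordinate distance + parity to the closure target and
// (b) reachability of pending mismatch-adjacency constraints. Free-chain
// counts exploit the point-group symmetry of the lattice (the 12
// equivalence classes of the first two steps), which is valid only for
// fully unconstrained walks. Counts are returned as doubles (they stay
// far below 2^53).
//
// An independently written brute-force enumerator (lattice_oracle.cpp)
// provides the cross-check used by the test suite.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int DX[4] = {1, 1, -1, -1};
static const int DY[4] = {1, -1, 1, -1};
static const int DZ[4] = {1, -1, -1, 1};

static inline bool is_adjacent(int ax, int ay, int az, int bx, int by, int bz) {
  int dx = bx - ax, dy = by - ay, dz = bz - az;
  if (dx != 1 && dx != -1) return false;
  if (dy != 1 && dy != -1) return false;
  if (dz != 1 && dz != -1) return false;
  int prod = dx * dy * dz;
  // from even-x vertex the allowed step set D has component product +1
  return ((ax & 1) == 0) ? (prod == 1) : (prod == -1);
}

struct Constraint {
  int a1, a2, b1, b2;
  int trigger;
};

struct Enumerator {
  int nsteps;
  bool closed;
  int tx, ty, tz;
  int fixed_idx, fixed_dir;
  std::vector<Constraint> cons;
  int half, dim;
  std::vector<unsigned char> occ;
  long off[2][4];  // flat-index offsets per parity (0: even x) and direction
  std::vector<int> wx, wy, wz;
  std::vector<long> widx;
  double count;

  Enumerator(int n)
      : half(n + 2), dim(2 * (n + 2) + 1),
        occ((size_t)(2 * (n + 2) + 1) * (2 * (n + 2) + 1) * (2 * (n + 2) + 1), 0),
        wx(n + 1), wy(n + 1), wz(n + 1), widx(n + 1), count(0.0) {
    for (int k = 0; k < 4; ++k) {
      off[0][k] = ((long)DX[k] * dim + DY[k]) * dim + DZ[k];
      off[1][k] = -off[0][k];
    }
  }
  inline long idx(int x, int y, int z) const {
    return ((long)(x + half) * dim + (y + half)) * dim + (z + half);
  }

  inline bool target_prune(int x, int y, int z, int rem) const {
    int dx = x > tx ? x - tx : tx - x;
    int dy = y > ty ? y - ty : ty - y;
    int dz = z > tz ? z - tz : tz - z;
    int mx = dx > dy ? dx : dy; if (dz > mx) mx = dz;
    if (mx > rem) return true;
    if ((dx ^ rem) & 1) return true;
    return false;
  }

  inline bool constraint_prune(int vidx, int x, int y, int z) const {
    for (size_t c = 0; c < cons.size(); ++c) {
      const Constraint &cn = cons[c];
      if (cn.trigger <= vidx) continue;
      bool feasible = false;
      const int as[2] = {cn.a1, cn.a2};
      const int bs[2] = {cn.b1, cn.b2};
      for (int ia = 0; ia < 2 && !feasible; ++ia) {
        for (int ib = 0; ib < 2 && !feasible; ++ib) {
          int u = as[ia], b = bs[ib];
          if (u > b) { int t = u; u = b; b = t; }
          if (u > vidx) { feasible = true; continue; }
          if (b <= vidx) {
            if (is_adjacent(wx[u], wy[u], wz[u], wx[b], wy[b], wz[b]))
              feasible = true;
            continue;
          }
          int dx = x > wx[u] ? x - wx[u] : wx[u] - x;
          int dy = y > wy[u] ? y - wy[u] : wy[u] - y;
          int dz = z > wz[u] ? z - wz[u] : wz[u] - z;
          int mx = dx > dy ? dx : dy; if (dz > mx) mx = dz;
          if (mx <= (b - vidx) + 1) feasible = true;
        }
      }
      if (!feasible) return true;
    }
    return false;
  }

  inline bool constraints_ok_at(int vidx) const {
    for (size_t c = 0; c < cons.size(); ++c) {
      const Constraint &cn = cons[c];
      if (cn.trigger != vidx) continue;
      bool sat =
        is_adjacent(wx[cn.a1], wy[cn.a1], wz[cn.a1], wx[cn.b1], wy[cn.b1], wz[cn.b1]) ||
        is_adjacent(wx[cn.a1], wy[cn.a1], wz[cn.a1], wx[cn.b2], wy[cn.b2], wz[cn.b2]) ||
        is_adjacent(wx[cn.a2], wy[cn.a2], wz[cn.a2], wx[cn.b1], wy[cn.b1], wz[cn.b1]) ||
        is_adjacent(wx[cn.a2], wy[cn.a2], wz[cn.a2], wx[cn.b2], wy[cn.b2], wz[cn.b2]);
      if (!sat) return false;
    }
    return true;
  }

  // tight inner loop for fully unconstrained free chains: flat indices only
  void run_open_fast(int start_depth, double mult) {
    std::vector<int> next_dir(nsteps + 1, 0);
    int d = start_depth;
    next_dir[d] = 0;
    long nodes_left_to_full = 0; (void)nodes_left_to_full;
    while (d >= start_depth) {
      if (d == nsteps) {
        count += mult;
        occ[widx[d]] = 0;
        --d;
        continue;
      }
      bool descended = false;
      int par = (wx[d] & 1);
      while (next_dir[d] < 4) {
        int k = next_dir[d]++;
        long ni = widx[d] + off[par][k];
        if (occ[ni]) continue;
        int step = d + 1;
        int sgn = par == 0 ? 1 : -1;
        wx[step] = wx[d] + sgn * DX[k];
        wy[step] = wy[d] + sgn * DY[k];
        wz[step] = wz[d] + sgn * DZ[k];
        widx[step] = ni;
        occ[ni] = 1;
        next_dir[step] = 0;
        d = step;
        descended = true;
        break;
      }
      if (!descended) {
        occ[widx[d]] = 0;
        --d;
      }
    }
    // restore start vertex occupancy for the caller
    occ[widx[start_depth]] = 1;
  }

  void run_general() {
    std::vector<int> next_dir(nsteps + 1, 0);
    int d = 0;
    while (d >= 0) {
      if (d == nsteps) {
        bool ok = !closed ||
          (wx[d] == tx && wy[d] == ty && wz[d] == tz);
        if (ok) count += 1.0;
        occ[widx[d]] = 0;
        --d;
        continue;
      }
      int step = d + 1;
      bool descended = false;
      int par = (wx[d] & 1);
      int sgn = par == 0 ? 1 : -1;
      while (next_dir[d] < 4) {
        int k = next_dir[d]++;
        if (fixed_idx == step && k != fixed_dir) continue;
        long ni = widx[d] + off[par][k];
        if (occ[ni]) continue;
        int nx = wx[d] + sgn * DX[k];
        int ny = wy[d] + sgn * DY[k];
        int nz = wz[d] + sgn * DZ[k];
        if (closed && target_prune(nx, ny, nz, nsteps - step)) continue;
        wx[step] = nx; wy[step] = ny; wz[step] = nz;
        widx[step] = ni;
        if (!cons.empty()) {
          if (!constraints_ok_at(step)) continue;
          if (constraint_prune(step, nx, ny, nz)) continue;
        }
        occ[ni] = 1;
        next_dir[step] = 0;
        d = step;
        descended = true;
        break;
      }
      if (!descended && d >= 0 && next_dir[d] >= 4) {
        occ[widx[d]] = 0;
        --d;
      }
    }
  }
};

// [[Rcpp::export]]
double vf_saw_count_cpp(int nsteps, bool closed,
                        IntegerVector target,
                        IntegerMatrix blocked,
                        IntegerMatrix mmpairs,
                        IntegerVector fixed_step) {
  if (nsteps == 0) return 1.0;
  if (nsteps < 0) stop("nsteps must be >= 0");
  Enumerator en(nsteps);
  en.nsteps = nsteps;
  en.closed = closed;
  if (closed) {
    en.tx = target[0]; en.ty = target[1]; en.tz = target[2];
  } else {
    en.tx = en.ty = en.tz = 0;
  }
  for (int b = 0; b < blocked.nrow(); ++b)
    en.occ[en.idx(blocked(b, 0), blocked(b, 1), blocked(b, 2))] = 1;
  for (int m = 0; m < mmpairs.nrow(); ++m) {
    Constraint cn;
    cn.a1 = mmpairs(m, 0); cn.a2 = mmpairs(m, 1);
    cn.b1 = mmpairs(m, 2); cn.b2 = mmpairs(m, 3);
    cn.trigger = std::max(std::max(cn.a1, cn.a2), std::max(cn.b1, cn.b2));
    if (cn.trigger > nsteps) stop("mismatch constraint index beyond walk length");
    en.cons.push_back(cn);
  }
  if (fixed_step.size() == 2) {
    en.fixed_idx = fixed_step[0];
    en.fixed_dir = fixed_step[1];
  } else {
    en.fixed_idx = -1; en.fixed_dir = -1;
  }
  en.wx[0] = 0; en.wy[0] = 0; en.wz[0] = 0;
  en.widx[0] = en.idx(0, 0, 0);
  en.occ[en.widx[0]] = 1;

  bool unconstrained_open = !closed && blocked.nrow() == 0 &&
    mmpairs.nrow() == 0 && fixed_step.size() != 2;
  if (unconstrained_open && nsteps >= 2) {
    // fix the first two steps (origin -> D[0] -> -D[1]); the lattice point
    // group acts transitively on the 12 two-step non-reversing paths
    en.wx[1] = 1; en.wy[1] = 1; en.wz[1] = 1;
    en.widx[1] = en.idx(1, 1, 1);
    en.occ[en.widx[1]] = 1;
    en.wx[2] = 0; en.wy[2] = 2; en.wz[2] = 2;
    en.widx[2] = en.idx(0, 2, 2);
    en.occ[en.widx[2]] = 1;
    en.run_open_fast(2, 12.0);
  } else if (unconstrained_open) {
    en.run_open_fast(0, 1.0);
  } else {
    en.run_general();
  }
  return en.count;
}
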