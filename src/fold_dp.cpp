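// Partition function over helix-based RNA secondary structures.
//
// Grammar of the nested ensemble (identical to the one the exhaustive
// R-level oracle enumerates):
//   * pairs: Watson-Crick + wobble; every pair belongs to a maximal run
//     (helix) of >= 2 consecutive pairs; hairpin loops >= 3 nt;
//   * loops closed by the inner pair of a helix are scored as hairpin /
//     internal / bulge loops (with Boltzmann-summed intra-loop single
//     mismatch variants) or as a multiloop (entropy of the total unpaired
//     length + a per-branch penalty);
//   * the exterior strand carries no penalty;
//   * internal loops are capped at 30 unpaired nt total.
// Pseudoknotted structures are bare H-type two-helix geometries (all other
// nucleotides unpaired), enumerated explicitly and weighted with the
// pseudoknot loop-entropy tables.
//
// Base-pair probabilities come from the matching outside recursion; the
// multiloop entropy depends on the total unpaired length, so multiloop
// states track that length as an explicit DP dimension.
//
// All loop entropies arrive from R in units of R (dimensionless), all
// stack-type energies as exp(-dG/RT) factors, so this file only assembles
// weights.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct FoldCtx {
  int N;
  std::vector<int> s;          // 1..N, codes 0..3 (A C G U)
  std::vector<int> pt;         // pair type matrix (N+2)^2, 0 = not pairable
  double eSG[7][7];            // exp(-stackG/RT), [outer pt][inner pt]
  double emmH[7][4][4];        // exp(-mismatch_hairpin/RT)
  double emmI[7][4][4];
  bool mm_ok[4][4];
  std::vector<double> S_hp;    // 0..N
  std::vector<double> S_int;   // 31x31 row-major [a*31+b]
  double a_int, c_int;         // fallback for internal loops > 30 total
  std::vector<double> S_hpmm;  // (cap+1)^3, [L][u][v]
  std::vector<double> S_intmm; // (cap+1)^4, [L1][L2][u][v]
  int mmcap;
  std::vector<double> eSml;    // exp(S_ml(u)), 0..N
  double beta;                 // exp(-c_b/RT) per branch
  std::vector<double> S_pk;    // (N+1) x n_pk_h row-major [L][hidx], hidx = h-2
  int pk_hmax;
  std::vector<double> S_junc;  // 0..N
  int min_hairpin, max_internal;
  double RT;

  inline int PT(int i, int j) const { return pt[(size_t)i * (N + 2) + j]; }

  inline double s_int_any(int a, int b) const {
    if (a + b == 0) return 0.0;
    if (a <= 30 && b <= 30) return S_int[(size_t)a * 31 + b];
    return a_int - c_int * std::log((double)(a + b));
  }

  // hairpin loop weight closed by (p,q): plain + single-mismatch variants
  double wh(int p, int q) const {
    int L = q - p - 1;
    if (L < min_hairpin) return 0.0;
    double w = (L <= N) ? std::exp(S_hp[L]) : 0.0;
    if (L >= 5) {
      for (int u = 1; u + 4 <= L; ++u) {
        int su = s[p + u];
        for (int v = u + 4; v <= L; ++v) {
          if (!mm_ok[su][s[p + v]]) continue;
          double S;
          if (L <= mmcap) {
            S = S_hpmm[((size_t)L * (mmcap + 1) + u) * (mmcap + 1) + v];
          } else {
            S = S_hp[v - u - 1] + s_int_any(u - 1, L - v);
          }
          if (!std::isfinite(S)) continue;
          double fac = std::exp(S);
          if (u == 1 && v == L)
            fac *= emmH[PT(p, q)][s[p + 1]][s[q - 1]];
          w += fac;
        }
      }
    }
    return w;
  }

  // internal/bulge loop weight between closing pair (p,q) and inner helix
  // outer pair (pp,qq); cross-strand single-mismatch variants
  double wint(int p, int q, int pp, int qq) const {
    int L1 = pp - p - 1, L2 = q - qq - 1;
    double base = s_int_any(L1, L2);
    double w = std::isfinite(base) ? std::exp(base) : 0.0;
    if (L1 >= 1 && L2 >= 1) {
      int cap1 = mmcap + 1;
      bool small = (L1 + L2) <= mmcap;
      for (int u = 1; u <= L1; ++u) {
        int su = s[p + u];
        for (int v = 1; v <= L2; ++v) {
          if (!mm_ok[su][s[qq + v]]) continue;
          double S;
          if (small) {
            S = S_intmm[(((size_t)L1 * cap1 + L2) * cap1 + u) * cap1 + v];
          } else {
            S = s_int_any(u - 1, L2 - v) + s_int_any(L1 - u, v - 1);
          }
          if (!std::isfinite(S)) continue;
          double fac = std::exp(S);
          if (u == 1 && v == L2)
            fac *= emmI[PT(p, q)][s[p + 1]][s[q - 1]];
          if (u == L1 && v == 1)
            fac *= emmI[PT(qq, pp)][s[qq + 1]][s[pp - 1]];
          w += fac;
        }
      }
    }
    return w;
  }
};

struct PkHelix {
  int i, j, h;
  double w;  // stack weight product
};

}  // namespace

// [[Rcpp::export]]
List vf_fold_cpp(IntegerVector seq_enc, double RT,
                 NumericMatrix eSG_in, NumericVector emmH_in, NumericVector emmI_in,
                 IntegerMatrix mm_ok_in,
                 NumericVector S_hp_in, NumericMatrix S_int_in,
                 double a_int, double c_int,
                 NumericVector S_hpmm_in, NumericVector S_intmm_in, int mmcap,
                 NumericVector S_ml_in, double c_b,
                 NumericMatrix S_pk_in, NumericVector S_junc_in,
                 int pk_mode, int min_hairpin, int max_internal,
                 bool want_bpp) {
  FoldCtx C;
  int N = seq_enc.size();
  C.N = N; C.RT = RT;
  C.min_hairpin = min_hairpin; C.max_internal = max_internal;
  C.mmcap = mmcap;
  C.a_int = a_int; C.c_int = c_int;
  C.s.assign(N + 2, -1);
  for (int i = 1; i <= N; ++i) C.s[i] = seq_enc[i - 1];

  // pair types: 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA (A=0,C=1,G=2,U=3)
  static const int PAIRCODE[4][4] = {
    {0, 0, 0, 5}, {0, 0, 1, 0}, {0, 2, 0, 3}, {6, 0, 4, 0}};
  C.pt.assign((size_t)(N + 2) * (N + 2), 0);
  for (int i = 1; i <= N; ++i)
    for (int j = 1; j <= N; ++j)
      if (i != j) C.pt[(size_t)i * (N + 2) + j] = PAIRCODE[C.s[i]][C.s[j]];

  for (int a = 0; a < 7; ++a)
    for (int b = 0; b < 7; ++b)
      C.eSG[a][b] = (a >= 1 && b >= 1) ? std::exp(-eSG_in(a - 1, b - 1) / RT) : 0.0;
  for (int p = 1; p <= 6; ++p)
    for (int x = 0; x < 4; ++x)
      for (int y = 0; y < 4; ++y) {
        C.emmH[p][x][y] = std::exp(-emmH_in[(p - 1) + 6 * (x + 4 * y)] / RT);
        C.emmI[p][x][y] = std::exp(-emmI_in[(p - 1) + 6 * (x + 4 * y)] / RT);
      }
  for (int x = 0; x < 4; ++x)
    for (int y = 0; y < 4; ++y)
      C.mm_ok[x][y] = mm_ok_in(x, y) != 0;
  C.S_hp.assign(S_hp_in.begin(), S_hp_in.end());
  C.S_int.assign(S_int_in.begin(), S_int_in.end());  // column-major! fix below
  // NumericMatrix is column-major; copy into row-major [a*31+b]
  for (int a = 0; a < 31; ++a)
    for (int b = 0; b < 31; ++b)
      C.S_int[(size_t)a * 31 + b] = S_int_in(a, b);
  C.S_hpmm.assign(S_hpmm_in.begin(), S_hpmm_in.end());
  C.S_intmm.assign(S_intmm_in.begin(), S_intmm_in.end());
  C.eSml.resize(N + 1);
  for (int u = 0; u <= N; ++u) C.eSml[u] = std::exp(S_ml_in[u]);
  C.beta = std::exp(-c_b / RT);
  C.pk_hmax = S_pk_in.ncol();
  C.S_pk.resize((size_t)(N + 1) * std::max(1, C.pk_hmax));
  for (int L = 0; L <= N; ++L)
    for (int hh = 0; hh < C.pk_hmax; ++hh)
      C.S_pk[(size_t)L * C.pk_hmax + hh] = S_pk_in(L, hh);
  C.S_junc.assign(S_junc_in.begin(), S_junc_in.end());

  const int W = N + 2;
  auto id2 = [W](int i, int j) { return (size_t)i * W + j; };
  auto id3 = [W](int x, int y, int u) { return ((size_t)x * W + y) * W + u; };

  std::vector<double> ZH((size_t)W * W, 0.0), ZL((size_t)W * W, 0.0);
  std::vector<double> T3((size_t)W * W * W, 0.0), M23((size_t)W * W * W, 0.0);

  const double beta = C.beta;

  // ---------------- inside ----------------
  for (int d = 0; d <= N - 1; ++d) {
    // helices and their closing loops, span d
    for (int i = 1; i + d <= N; ++i) {
      int j = i + d;
      if (d >= 4 && C.PT(i, j)) {
        // loop weight ZL for (i,j) as a closing (inner-of-helix) pair
        int p = i, q = j;
        double zl = 0.0;
        if (q - p - 1 >= C.min_hairpin) {
          zl = C.wh(p, q);
          // internal / bulge
          int Lmax = std::min(C.max_internal, q - p - 8);
          for (int L1 = 0; L1 <= Lmax; ++L1) {
            int pp = p + 1 + L1;
            for (int L2 = (L1 == 0 ? 1 : 0); L1 + L2 <= Lmax; ++L2) {
              int qq = q - 1 - L2;
              if (qq - pp < 6) break;
              double zh = ZH[id2(pp, qq)];
              if (zh > 0.0) zl += C.wint(p, q, pp, qq) * zh;
            }
          }
          // multiloop
          if (q - p - 1 >= 12) {
            double zm = 0.0;
            for (int u = 0; u <= q - p - 1; ++u) {
              double m2 = M23[id3(p + 1, q - 1, u)];
              if (m2 > 0.0) zm += C.eSml[u] * m2;
            }
            zl += beta * zm;
          }
        }
        ZL[id2(p, q)] = zl;
        // helix sums starting at (i,j)
        double w = 1.0, zh = 0.0;
        int ptprev = C.PT(i, j);
        for (int h = 2; ; ++h) {
          int ii = i + h - 1, jj = j - h + 1;
          if (jj - ii - 1 < C.min_hairpin) break;
          int ptin = C.PT(ii, jj);
          if (!ptin) break;
          w *= C.eSG[ptprev][ptin];
          ptprev = ptin;
          zh += w * ZL[id2(ii, jj)];
        }
        ZH[id2(i, j)] = zh;
      }
    }
    // multiloop segment states, span d
    for (int x = 1; x + d <= N; ++x) {
      int y = x + d;
      int umax = d + 1;
      for (int u = 0; u <= umax; ++u) {
        double t = 0.0, m2 = 0.0;
        if (u >= 1 && x < y) {
          t = T3[id3(x + 1, y, u - 1)];
          m2 = M23[id3(x + 1, y, u - 1)];
        } else if (u >= 1 && x == y && u == 1) {
          t = 0.0; m2 = 0.0;  // single unpaired nt cannot hold a helix
        }
        for (int e = x + 6; e <= y; ++e) {
          double zh = ZH[id2(x, e)];
          if (zh <= 0.0) continue;
          double tail = (e < y) ? T3[id3(e + 1, y, u)] : 0.0;
          t += zh * beta * ((u == y - e ? 1.0 : 0.0) + tail);
          m2 += zh * beta * tail;
        }
        T3[id3(x, y, u)] = t;
        M23[id3(x, y, u)] = m2;
      }
    }
  }

  // exterior segment partition functions
  std::vector<double> G2((size_t)W * W, 0.0);
  auto gfun = [&](int a, int b) -> double {
    if (a > b) return 1.0;
    return G2[id2(a, b)];
  };
  for (int b = 1; b <= N; ++b) {
    for (int a = b; a >= 1; --a) {
      double g = gfun(a + 1, b);
      for (int e = a + 6; e <= b; ++e) {
        double zh = ZH[id2(a, e)];
        if (zh > 0.0) g += zh * gfun(e + 1, b);
      }
      G2[id2(a, b)] = g;
    }
  }
  double Qn = gfun(1, N);

  // ---------------- pseudoknots: bare H-type two-helix structures --------
  double Qpk = 0.0;
  std::vector<double> bppnum;
  if (want_bpp) bppnum.assign((size_t)W * W, 0.0);
  std::vector<PkHelix> pl;
  if (pk_mode > 0) {
    for (int i = 1; i <= N; ++i)
      for (int j = i + 3; j <= N; ++j) {
        if (!C.PT(i, j)) continue;
        double w = 1.0;
        int ptprev = C.PT(i, j);
        for (int h = 2; ; ++h) {
          int ii = i + h - 1, jj = j - h + 1;
          if (jj - ii < 1) break;
          int ptin = C.PT(ii, jj);
          if (!ptin) break;
          w *= C.eSG[ptprev][ptin];
          ptprev = ptin;
          PkHelix ph; ph.i = i; ph.j = j; ph.h = h; ph.w = w;
          pl.push_back(ph);
        }
      }
    for (size_t a = 0; a < pl.size(); ++a) {
      const PkHelix &A = pl[a];
      int a1e = A.i + A.h - 1, a2s = A.j - A.h + 1;
      for (size_t b = 0; b < pl.size(); ++b) {
        const PkHelix &B = pl[b];
        int b1s = B.i, b1e = B.i + B.h - 1, b2s = B.j - B.h + 1;
        int L1 = b1s - a1e - 1;
        int j2 = a2s - b1e - 1;
        int L3 = b2s - A.j - 1;
        if (L1 < 1 || j2 < 0 || L3 < 1) continue;
        if (B.j - B.h + 1 <= A.j) continue;  // strand order: a2 before b2
        if (pk_mode == 1 && j2 > 1) continue;
        int hA = std::min(A.h, C.pk_hmax + 1) - 2;  // column index, clamped
        int hB = std::min(B.h, C.pk_hmax + 1) - 2;
        double S = C.S_pk[(size_t)L1 * C.pk_hmax + hB] + C.S_junc[j2] +
                   C.S_pk[(size_t)L3 * C.pk_hmax + hA];
        if (!std::isfinite(S)) continue;
        double w = A.w * B.w * std::exp(S);
        Qpk += w;
        if (want_bpp) {
          for (int t = 0; t < A.h; ++t) bppnum[id2(A.i + t, A.j - t)] += w;
          for (int t = 0; t < B.h; ++t) bppnum[id2(B.i + t, B.j - t)] += w;
        }
      }
    }
  }

  double Q = Qn + Qpk;

  // ---------------- outside ----------------
  if (want_bpp) {
    std::vector<double> OH((size_t)W * W, 0.0), OL((size_t)W * W, 0.0);
    std::vector<double> OT3((size_t)W * W * W, 0.0), OM23((size_t)W * W * W, 0.0);
    for (int i = 1; i <= N; ++i)
      for (int j = i + 6; j <= N; ++j)
        if (ZH[id2(i, j)] > 0.0)
          OH[id2(i, j)] = gfun(1, i - 1) * gfun(j + 1, N);

    for (int d = N - 1; d >= 0; --d) {
      // segment states first
      for (int x = 1; x + d <= N; ++x) {
        int y = x + d;
        int umax = d + 1;
        for (int u = 0; u <= umax; ++u) {
          double om = OM23[id3(x, y, u)];
          double ot = OT3[id3(x, y, u)];
          if (om > 0.0) {
            if (u >= 1 && x < y) OM23[id3(x + 1, y, u - 1)] += om;
            for (int e = x + 6; e <= y; ++e) {
              double zh = ZH[id2(x, e)];
              if (zh <= 0.0) continue;
              double tail = (e < y) ? T3[id3(e + 1, y, u)] : 0.0;
              OH[id2(x, e)] += beta * om * tail;
              if (e < y) OT3[id3(e + 1, y, u)] += beta * om * zh;
            }
          }
          if (ot > 0.0) {
            if (u >= 1 && x < y) OT3[id3(x + 1, y, u - 1)] += ot;
            for (int e = x + 6; e <= y; ++e) {
              double zh = ZH[id2(x, e)];
              if (zh <= 0.0) continue;
              double tail = (e < y) ? T3[id3(e + 1, y, u)] : 0.0;
              OH[id2(x, e)] += beta * ot * ((u == y - e ? 1.0 : 0.0) + tail);
              if (e < y) OT3[id3(e + 1, y, u)] += beta * ot * zh;
            }
          }
        }
      }
      // helices span d: distribute into placements and loop outsides
      for (int i = 1; i + d <= N; ++i) {
        int j = i + d;
        if (d < 4 || !C.PT(i, j)) continue;
        double oh = OH[id2(i, j)];
        if (oh > 0.0 && ZH[id2(i, j)] > 0.0) {
          double w = 1.0;
          int ptprev = C.PT(i, j);
          for (int h = 2; ; ++h) {
            int ii = i + h - 1, jj = j - h + 1;
            if (jj - ii - 1 < C.min_hairpin) break;
            int ptin = C.PT(ii, jj);
            if (!ptin) break;
            w *= C.eSG[ptprev][ptin];
            ptprev = ptin;
            double zl = ZL[id2(ii, jj)];
            if (zl > 0.0) {
              double num = oh * w * zl;
              for (int t = 0; t < h; ++t) bppnum[id2(i + t, j - t)] += num;
              OL[id2(ii, jj)] += oh * w;
            }
          }
        }
        // consume OL at this span
        double ol = OL[id2(i, j)];
        if (ol > 0.0) {
          int p = i, q = j;
          int Lmax = std::min(C.max_internal, q - p - 8);
          for (int L1 = 0; L1 <= Lmax; ++L1) {
            int pp = p + 1 + L1;
            for (int L2 = (L1 == 0 ? 1 : 0); L1 + L2 <= Lmax; ++L2) {
              int qq = q - 1 - L2;
              if (qq - pp < 6) break;
              if (ZH[id2(pp, qq)] > 0.0)
                OH[id2(pp, qq)] += ol * C.wint(p, q, pp, qq);
            }
          }
          if (q - p - 1 >= 12) {
            for (int u = 0; u <= q - p - 1; ++u)
              OM23[id3(p + 1, q - 1, u)] += ol * beta * C.eSml[u];
          }
        }
      }
    }
  }

  NumericMatrix bpp(N, N);
  if (want_bpp) {
    for (int i = 1; i <= N; ++i)
      for (int j = i + 1; j <= N; ++j) {
        double p = bppnum[id2(i, j)] / Q;
        bpp(i - 1, j - 1) = p;
        bpp(j - 1, i - 1) = p;
      }
  }

  return List::create(_["Q"] = Q, _["lnQ"] = std::log(Q),
                      _["Qn"] = Qn, _["Qpk"] = Qpk,
                      _["bpp"] = bpp);
}
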