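// Dynamic-programming kernels for miRNA:target duplex alignment.
//
// Both kernels align a miRNA (5'->3') against a target window read 3'->5'
// (i.e. the window is reversed before the call), so that column k pairs
// miRNA position i with the window base opposite it.  Base coding:
// A=0, C=1, G=2, U=3.
//
// dp_score_align  : minimum-penalty global alignment (mismatch / G:U wobble /
//                   asymmetric bulge moves), lexicographic tie-break on
//                   (penalty, number of gap columns), backtrack placing gaps
//                   at their 5'-most equivalent position.
// dp_energy_align : minimum nearest-neighbor free-energy structure over the
//                   same alignment space (paired columns are WC or G:U;
//                   everything else is loop or free end).

#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// pair type: CG=0 GC=1 GU=2 UG=3 AU=4 UA=5, -1 if not a pair
static inline int pt(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}
static inline bool is_wc(int p) { return p == 0 || p == 1 || p == 4 || p == 5; }

// [[Rcpp::export(name = ".dp_score_align")]]
List dp_score_align(IntegerVector mi, IntegerVector tg,
                    double mismatch, double wobble, double bulge_nt,
                    int max_bulge, bool require1011) {
  const int L = mi.size(), W = tg.size(), mb = max_bulge;
  const int S = 2 * mb + 1;
  const bool req = require1011 && L >= 11;
  // state 0: last column consumed both strands (or start)
  // 1..mb: miRNA-bulge run of that length; mb+1..2mb: target-bulge run
  std::vector<double> D((size_t)(L + 1) * (W + 1) * S, INF);
  std::vector<int>    G((size_t)(L + 1) * (W + 1) * S, INT_MAX);
  auto idx = [&](int i, int j, int s) {
    return ((size_t)i * (W + 1) + j) * S + s;
  };
  D[idx(0, 0, 0)] = 0.0;
  G[idx(0, 0, 0)] = 0;

  auto relax = [&](int i, int j, int s, double sc, int gp) {
    size_t k = idx(i, j, s);
    if (sc < D[k] || (sc == D[k] && gp < G[k])) { D[k] = sc; G[k] = gp; }
  };

  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j <= W; ++j) {
      for (int s = 0; s < S; ++s) {
        double d = D[idx(i, j, s)];
        if (d == INF) continue;
        int g = G[idx(i, j, s)];
        // consume one base of each strand (WC pair, wobble, or mismatch)
        if (i < L && j < W) {
          int p = pt(mi[i], tg[j]);
          double c = (p < 0) ? mismatch : (is_wc(p) ? 0.0 : wobble);
          bool mm_at_anchor = req && p < 0 && (i + 1 == 10 || i + 1 == 11);
          if (!mm_at_anchor) relax(i + 1, j + 1, 0, d + c, g);
        }
        // bulged miRNA base (consumes miRNA only)
        if (i < L && !(req && (i + 1 == 10 || i + 1 == 11))) {
          int run = (s >= 1 && s <= mb) ? s : 0;
          if (run < mb) relax(i + 1, j, run + 1, d + bulge_nt, g + 1);
        }
        // bulged target base (consumes target only)
        if (j < W && !(req && i == 10)) {
          int run = (s > mb) ? s - mb : 0;
          if (run < mb) relax(i, j + 1, mb + run + 1, d + bulge_nt, g + 1);
        }
      }
    }
  }

  // pick final state: best (score, gaps); ties resolved scanning the pair
  // state first so that gaps land at their 5'-most equivalent placement
  // (the convention used to draw the miR396:GRF bulge between positions 7-8)
  int sbest = -1; double best = INF; int bestg = INT_MAX;
  for (int s = 0; s < S; ++s) {
    double d = D[idx(L, W, s)];
    if (d < best || (d == best && G[idx(L, W, s)] < bestg)) {
      best = d; bestg = G[idx(L, W, s)]; sbest = s;
    }
  }
  if (sbest < 0 || best == INF)
    return List::create(_["feasible"] = false, _["score"] = R_PosInf,
                        _["gaps"] = NA_INTEGER,
                        _["moves"] = IntegerVector(0));

  // backtrack; moves recovered 3'->5' then reversed
  std::vector<int> rmoves;
  int i = L, j = W, s = sbest;
  while (i > 0 || j > 0) {
    double d = D[idx(i, j, s)];
    int g = G[idx(i, j, s)];
    bool stepped = false;
    if (s == 0) { // last move consumed both strands
      int p = pt(mi[i - 1], tg[j - 1]);
      double c = (p < 0) ? mismatch : (is_wc(p) ? 0.0 : wobble);
      bool legal = !(req && p < 0 && (i == 10 || i == 11));
      if (legal) {
        for (int sp = 0; sp < S && !stepped; ++sp) {
          size_t k = idx(i - 1, j - 1, sp);
          if (D[k] + c == d && G[k] == g) {
            rmoves.push_back(0); i--; j--; s = sp; stepped = true;
          }
        }
      }
    } else if (s <= mb) { // miRNA bulge run
      bool legal = !(req && (i == 10 || i == 11));
      if (legal) {
        if (s == 1) {
          for (int sp = 0; sp < S && !stepped; ++sp) {
            if (sp >= 1 && sp <= mb) continue; // run start: prior not m-bulge
            size_t k = idx(i - 1, j, sp);
            if (D[k] + bulge_nt == d && G[k] + 1 == g) {
              rmoves.push_back(1); i--; s = sp; stepped = true;
            }
          }
        } else {
          size_t k = idx(i - 1, j, s - 1);
          if (D[k] + bulge_nt == d && G[k] + 1 == g) {
            rmoves.push_back(1); i--; s = s - 1; stepped = true;
          }
        }
      }
    } else { // target bulge run
      int run = s - mb;
      bool legal = !(req && i == 10);
      if (legal) {
        if (run == 1) {
          for (int sp = 0; sp < S && !stepped; ++sp) {
            if (sp > mb) continue; // run start: prior not t-bulge
            size_t k = idx(i, j - 1, sp);
            if (D[k] + bulge_nt == d && G[k] + 1 == g) {
              rmoves.push_back(2); j--; s = sp; stepped = true;
            }
          }
        } else {
          size_t k = idx(i, j - 1, s - 1);
          if (D[k] + bulge_nt == d && G[k] + 1 == g) {
            rmoves.push_back(2); j--; s = s - 1; stepped = true;
          }
        }
      }
    }
    if (!stepped) stop("internal error: duplex score backtrack failed");
  }
  IntegerVector moves(rmoves.rbegin(), rmoves.rend());
  return List::create(_["feasible"] = true, _["score"] = best,
                      _["gaps"] = bestg, _["moves"] = moves);
}

// stack free energy between consecutive pairs p1 (5'-ward on the miRNA) and
// p2; the table is indexed [first pair][reversed second pair]
static inline int revp(int p) {
  static const int r[6] = {1, 0, 3, 2, 5, 4};
  return r[p];
}

static inline double loop_len_e(int n, const NumericVector& tab, double lxc) {
  if (n <= (int)tab.size()) return tab[n - 1];
  return tab[tab.size() - 1] + lxc * std::log((double)n / (double)tab.size());
}

// [[Rcpp::export(name = ".dp_energy_align")]]
List dp_energy_align(IntegerVector mi, IntegerVector tg,
                     NumericMatrix stack, NumericVector bulge_tab,
                     NumericVector internal_tab, double terminal_au,
                     double initiation, double lxc,
                     int max_bulge, bool require1011) {
  const int L = mi.size(), W = tg.size(), mb = max_bulge;
  const bool req = require1011 && L >= 11;
  std::vector<double> E((size_t)(L + 1) * (W + 1), INF);
  std::vector<int> Pi((size_t)(L + 1) * (W + 1), 0), Pj(Pi);
  auto idx = [&](int i, int j) { return (size_t)i * (W + 1) + j; };
  auto tau = [&](int p) { return p < 2 ? 0.0 : terminal_au; }; // CG/GC closing pairs are free

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= W; ++j) {
      int p = pt(mi[i - 1], tg[j - 1]);
      if (p < 0) continue;
      double best = INF; int bpi = 0, bpj = 0;
      // open the duplex at this pair (5' overhangs are free ends)
      if (std::abs((i - 1) - (j - 1)) <= mb && !(req && i > 10)) {
        double cand = initiation + tau(p);
        if (cand < best) { best = cand; bpi = 0; bpj = 0; }
      }
      for (int pi2 = 1; pi2 < i; ++pi2) {
        if (req && pi2 <= 9 && i >= 11) continue;      // would skip pos 10
        for (int pj2 = 1; pj2 < j; ++pj2) {
          size_t k = idx(pi2, pj2);
          if (E[k] == INF) continue;
          int a = i - pi2 - 1, b = j - pj2 - 1;
          if (std::abs(a - b) > mb) continue;
          if (req && pi2 == 10 && !(i == 11 && a == 0 && b == 0)) continue;
          int pp = pt(mi[pi2 - 1], tg[pj2 - 1]);
          double cost;
          if (a == 0 && b == 0) {
            cost = stack(pp, revp(p));
          } else if (a + b == 1) { // single-nt bulge keeps the stack
            cost = stack(pp, revp(p)) + loop_len_e(1, bulge_tab, lxc);
          } else if (b == 0) {
            cost = loop_len_e(a, bulge_tab, lxc);
          } else if (a == 0) {
            cost = loop_len_e(b, bulge_tab, lxc);
          } else {
            cost = loop_len_e(a + b, internal_tab, lxc);
          }
          double cand = E[k] + cost;
          if (cand < best) { best = cand; bpi = pi2; bpj = pj2; }
        }
      }
      E[idx(i, j)] = best; Pi[idx(i, j)] = bpi; Pj[idx(i, j)] = bpj;
    }
  }

  double best = INF; int li = 0, lj = 0;
  for (int i = 1; i <= L; ++i) {
    if (req && i < 11) continue;
    for (int j = 1; j <= W; ++j) {
      size_t k = idx(i, j);
      if (E[k] == INF) continue;
      if (std::abs((L - i) - (W - j)) > mb) continue;
      double cand = E[k] + tau(pt(mi[i - 1], tg[j - 1]));
      if (cand < best) { best = cand; li = i; lj = j; }
    }
  }
  if (best == INF)
    return List::create(_["feasible"] = false, _["energy"] = R_PosInf,
                        _["pair_i"] = IntegerVector(0),
                        _["pair_j"] = IntegerVector(0));
  std::vector<int> vi, vj;
  int i = li, j = lj;
  while (i > 0 && j > 0) {
    vi.push_back(i); vj.push_back(j);
    size_t k = idx(i, j);
    int ni = Pi[k], nj = Pj[k];
    i = ni; j = nj;
  }
  IntegerVector pair_i(vi.rbegin(), vi.rend());
  IntegerVector pair_j(vj.rbegin(), vj.rend());
  return List::create(_["feasible"] = true, _["energy"] = best,
                      _["pair_i"] = pair_i, _["pair_j"] = pair_j);
}
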