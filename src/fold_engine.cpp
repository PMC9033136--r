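#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Nucleotide encoding used throughout: 0 = A, 1 = C, 2 = G, 3 = U.
// pairE is a 4x4 matrix of pairing energies; 0 marks a non-pairing
// combination, negative values a pairing one (GC/AU/GU by default).

static const double INF = std::numeric_limits<double>::infinity();

// Minimum-energy nested secondary structure (Nussinov-style DP with a
// nearest-neighbour stacking bonus).  Three tables:
//   W(i,j)  best energy of subsequence [i, j]
//   V(i,j)  best energy of [i, j] given that i pairs with j
//   Wx(i,j) best energy of [i, j] with i NOT paired to j
// V(i,j) = e(i,j) + min(V(i+1,j-1) + stack, Wx(i+1,j-1))
// W(i,j) = min(Wx(i,j), V(i,j))
// Wx(i,j) = min(W(i+1,j), min_k<j V(i,k) + W(k+1,j))
// Hairpin loops must enclose more than min_loop unpaired positions
// (j - i > min_loop for a pair (i,j)).
// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector s, NumericMatrix pairE, double stack,
                  int min_loop) {
  int n = s.size();
  List out;
  if (n == 0) {
    out["pairs"] = IntegerMatrix(0, 2);
    out["energy"] = 0.0;
    return out;
  }
  std::vector<double> W((size_t)n * n, 0.0), V((size_t)n * n, INF),
      Wx((size_t)n * n, 0.0);
#define IDX(i, j) ((size_t)(i) * n + (j))
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V
      double e = pairE(s[i], s[j]);
      if (e < 0 && (j - i) > min_loop) {
        double interior;
        // interior span [i+1, j-1] is non-empty whenever j - i >= 2
        double v_in = V[IDX(i + 1, j - 1)];
        double wx_in = Wx[IDX(i + 1, j - 1)];
        interior = std::min(v_in == INF ? INF : v_in + stack, wx_in);
        V[IDX(i, j)] = e + interior;
      }
      // Wx: i unpaired, or i paired to some k < j
      double best = W[IDX(i + 1, j)];
      for (int k = i + min_loop + 1; k < j; ++k) {
        double v = V[IDX(i, k)];
        if (v == INF) continue;
        double cand = v + ((k + 1 <= j) ? W[IDX(k + 1, j)] : 0.0);
        if (cand < best) best = cand;
      }
      Wx[IDX(i, j)] = best;
      double w = best;
      if (V[IDX(i, j)] < w) w = V[IDX(i, j)];
      W[IDX(i, j)] = w;
    }
  }
  // traceback; deterministic: smallest i first, then smallest j
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::array<int, 3> > stk;  // (i, j, which) which: 0=W,1=V,2=Wx
  stk.push_back({0, n - 1, 0});
  const double EPS = 1e-9;
  while (!stk.empty()) {
    std::array<int, 3> fr = stk.back();
    stk.pop_back();
    int i = fr[0], j = fr[1], which = fr[2];
    if (i >= j) continue;
    if (which == 0) {  // W
      if (V[IDX(i, j)] <= W[IDX(i, j)] + EPS &&
          V[IDX(i, j)] <= Wx[IDX(i, j)] + EPS) {
        stk.push_back({i, j, 1});
      } else {
        stk.push_back({i, j, 2});
      }
    } else if (which == 1) {  // V: (i,j) paired
      pairs.push_back(std::make_pair(i, j));
      if (j - 1 > i + 1) {
        double v_in = V[IDX(i + 1, j - 1)];
        double target = V[IDX(i, j)] - pairE(s[i], s[j]);
        if (v_in != INF && std::abs(v_in + stack - target) < EPS) {
          stk.push_back({i + 1, j - 1, 1});
        } else {
          stk.push_back({i + 1, j - 1, 2});
        }
      }
    } else {  // Wx
      double target = Wx[IDX(i, j)];
      bool done = false;
      for (int k = i + min_loop + 1; k < j; ++k) {
        double v = V[IDX(i, k)];
        if (v == INF) continue;
        if (std::abs(v + W[IDX(k + 1, j)] - target) < EPS) {
          stk.push_back({i, k, 1});
          stk.push_back({k + 1, j, 0});
          done = true;
          break;
        }
      }
      if (!done) stk.push_back({i + 1, j, 0});
    }
  }
#undef IDX
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  out["pairs"] = pm;
  out["energy"] = W[(size_t)0 * n + (n - 1)];
  return out;
}

// Best intermolecular duplex between strands a and b (no intramolecular
// pairs).  Antiparallel alignment: successive pairs move 3' on a and 5'
// on b.  Energy = duplex_init + sum of pair energies + stack bonus for
// each directly adjacent pair of pairs; an interruption (bulge or
// internal loop) costs the bulge penalty per unpaired nucleotide it
// loops out, and breaks stacking.  A duplex with non-negative total
// energy is reported as no duplex (energy 0).
// [[Rcpp::export(name = ".duplex_cpp")]]
List duplex_cpp(IntegerVector a, IntegerVector b, NumericMatrix pairE,
                double stack, double bulge_pen, double init) {
  int n = a.size(), m = b.size();
  List out;
  // D(i,j): best energy of a duplex whose 3'-most pair (on a) is a[i]:b[j]
  // M(i,j): min over i' <= i, j' >= j of D(i',j') + bulge_pen per base
  //         skipped relative to (i, j)
  std::vector<double> D((size_t)n * m, INF), M((size_t)n * m, INF);
#define IDX(i, j) ((size_t)(i) * m + (j))
  double best = INF;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      double e = pairE(a[i], b[j]);
      if (e < 0) {
        double prev = 0.0;
        if (i > 0 && j < m - 1) {
          double st = D[IDX(i - 1, j + 1)];
          double opt = (st == INF) ? INF : st + stack;
          double bu = M[IDX(i - 1, j + 1)];
          if (bu != INF && bu < opt) opt = bu;
          if (opt < prev) prev = opt;
        }
        D[IDX(i, j)] = e + prev;
        if (D[IDX(i, j)] < best) {
          best = D[IDX(i, j)];
          bi = i;
          bj = j;
        }
      }
      double mm = D[IDX(i, j)];
      if (i > 0 && M[IDX(i - 1, j)] + bulge_pen < mm)
        mm = M[IDX(i - 1, j)] + bulge_pen;
      if (j < m - 1 && M[IDX(i, j + 1)] + bulge_pen < mm)
        mm = M[IDX(i, j + 1)] + bulge_pen;
      M[IDX(i, j)] = mm;
    }
  }
  if (best == INF || init + best >= 0) {
    out["pairs"] = IntegerMatrix(0, 2);
    out["energy"] = 0.0;
    return out;
  }
  // traceback from (bi, bj)
  const double EPS = 1e-9;
  std::vector<std::pair<int, int> > pairs;
  int i = bi, j = bj;
  while (i >= 0 && j <= m - 1) {
    pairs.push_back(std::make_pair(i, j));
    double rem = D[IDX(i, j)] - pairE(a[i], b[j]);
    if (std::abs(rem) < EPS) break;
    if (i > 0 && j < m - 1) {
      double st = D[IDX(i - 1, j + 1)];
      if (st != INF && std::abs(st + stack - rem) < EPS) {
        --i;
        ++j;
        continue;
      }
      // bulge/internal loop: find predecessor pair deterministically,
      // largest i' then smallest j' (closest to the junction)
      bool found = false;
      for (int pi = i - 1; pi >= 0 && !found; --pi) {
        for (int pj = j + 1; pj <= m - 1 && !found; ++pj) {
          double d = D[IDX(pi, pj)];
          double gap = (double)((i - 1 - pi) + (pj - j - 1));
          if (d != INF && std::abs(d + bulge_pen * gap - rem) < EPS) {
            i = pi;
            j = pj;
            found = true;
          }
        }
      }
      if (!found) break;
    } else {
      break;
    }
  }
#undef IDX
  IntegerMatrix pm(pairs.size(), 2);
  // emit pairs in 5'->3' order on a
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[pairs.size() - 1 - r].first;
    pm(r, 1) = pairs[pairs.size() - 1 - r].second;
  }
  out["pairs"] = pm;
  out["energy"] = init + best;
  return out;
}
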