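// Error-correction alignment core.
//
// Cells are indexed by (node j, candidate corrected position c).  After
// overlap deletion the per-peak position intervals [m_i - lower_i,
// m_i + upper_i] are pairwise disjoint, so the concatenation of all
// candidate positions is a strictly increasing array and every integer
// position is examined exactly once.  A transition from node j' to node j
// with sub-path mass M moves from position c - M to position c; because the
// position arrays are sorted, each (j, M) pair is processed with a single
// two-pointer sweep instead of per-cell binary searches.
//
// Scores: T(cell) = maximum number of matched triples in a chain ending at
// that cell; every cell starts at 1 (a single matched peak is an alignment
// of size 1).  In diagonal (local, banded) mode only cells inside the band
// are active, chains must start at the user-supplied (start_peak,
// start_node) cell, and unreached cells stay 0.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List align_core_cpp(IntegerVector peak_mass,   // scaled mass per peak, ascending, y0 first
                    IntegerVector lo,          // lower corrected-position bound per peak
                    IntegerVector hi,          // upper bound; intervals pairwise disjoint
                    IntegerVector sub_src,     // sub-path source node j' (0-based)
                    IntegerVector sub_dst,     // sub-path target node j (1..n)
                    IntegerVector sub_mass,    // sub-path scaled mass
                    int n_pos,                 // number of residue positions n
                    bool diagonal,
                    int start_node, int start_peak, double band,
                    IntegerVector black_prefix) {
  const int P = peak_mass.size();
  const int n = n_pos;

  // per-peak offsets into the global position array
  std::vector<int> off(P + 1, 0);
  for (int i = 0; i < P; ++i) {
    if (hi[i] < lo[i]) stop("empty tolerance interval for peak %d", i);
    if (i > 0 && lo[i] <= hi[i - 1])
      stop("tolerance intervals not disjoint at peak %d", i);
    off[i + 1] = off[i] + (hi[i] - lo[i] + 1);
  }
  const int K = off[P];
  std::vector<int> pos_val(K), pos_peak(K);
  for (int i = 0; i < P; ++i)
    for (int c = lo[i], t = off[i]; c <= hi[i]; ++c, ++t) {
      pos_val[t] = c;
      pos_peak[t] = i;
    }

  // group sub-paths by destination node
  const int S = sub_src.size();
  std::vector<std::vector<std::pair<int,int>>> grp(n + 1);
  for (int e = 0; e < S; ++e) {
    if (sub_dst[e] < 1 || sub_dst[e] > n) stop("sub-path dst out of range");
    if (sub_src[e] < 0 || sub_src[e] >= sub_dst[e]) stop("sub-path src out of range");
    grp[sub_dst[e]].push_back(std::make_pair(sub_src[e], sub_mass[e]));
  }

  // cell validity in diagonal mode
  std::vector<char> valid;
  if (diagonal) {
    valid.assign((size_t)(n + 1) * K, 0);
    for (int j = 0; j <= n; ++j)
      for (int t = 0; t < K; ++t) {
        const int p = pos_peak[t];
        if (p == start_peak && j == start_node) {
          valid[(size_t)j * K + t] = 1;
        } else if (p > start_peak && j > start_node) {
          const double drift =
            (double)(peak_mass[p] - peak_mass[start_peak]) -
            (double)(black_prefix[j] - black_prefix[start_node]);
          if (drift <= band && drift >= -band) valid[(size_t)j * K + t] = 1;
        }
      }
  }

  std::vector<int> T((size_t)(n + 1) * K, 0);
  for (int j = 0; j <= n; ++j) {
    int *Tj = &T[(size_t)j * K];
    const char *vj = diagonal ? &valid[(size_t)j * K] : nullptr;
    if (!diagonal) {
      for (int t = 0; t < K; ++t) Tj[t] = 1;
    } else {
      for (int t = 0; t < K; ++t)
        Tj[t] = (pos_peak[t] == start_peak && j == start_node) ? 1 : 0;
    }
    for (size_t g = 0; g < grp[j].size(); ++g) {
      const int jp = grp[j][g].first;
      const int M = grp[j][g].second;
      const int *Ts = &T[(size_t)jp * K];
      int p = 0;
      for (int t = 0; t < K; ++t) {
        if (diagonal && !vj[t]) continue;
        const int target = pos_val[t] - M;
        while (p < K && pos_val[p] < target) ++p;
        if (p < K && pos_val[p] == target && Ts[p] >= 1) {
          const int cand = Ts[p] + 1;
          if (cand > Tj[t]) Tj[t] = cand;
        }
      }
    }
  }

  // best cell, lexicographically smallest (peak, node, k) on ties
  int best = 0, bi = -1, bj = -1, bt = -1;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j <= n; ++j)
      for (int t = off[i]; t < off[i + 1]; ++t) {
        const int v = T[(size_t)j * K + t];
        if (v > best) { best = v; bi = i; bj = j; bt = t; }
      }

  IntegerVector a_node(best), a_peak(best), a_k(best), a_pos(best);
  if (best > 0) {
    int cj = bj, ct = bt, v = best;
    for (int step = best - 1; step >= 0; --step) {
      a_node[step] = cj;
      a_peak[step] = pos_peak[ct];
      a_pos[step] = pos_val[ct];
      a_k[step] = pos_val[ct] - peak_mass[pos_peak[ct]];
      if (step == 0) break;
      // predecessor with value v-1; lexicographically smallest (i', j', k')
      int ni = -1, nj = -1, nt = -1;
      for (size_t g = 0; g < grp[cj].size(); ++g) {
        const int jp = grp[cj][g].first;
        const int M = grp[cj][g].second;
        const int target = pos_val[ct] - M;
        // binary search in pos_val
        int a = 0, b = K - 1, idx = -1;
        while (a <= b) {
          const int mid = (a + b) / 2;
          if (pos_val[mid] == target) { idx = mid; break; }
          if (pos_val[mid] < target) a = mid + 1; else b = mid - 1;
        }
        if (idx < 0) continue;
        if (T[(size_t)jp * K + idx] != v - 1) continue;
        const int ip = pos_peak[idx];
        const int kp = pos_val[idx] - peak_mass[ip];
        if (ni < 0 || ip < ni || (ip == ni && (jp < nj ||
            (jp == nj && kp < (pos_val[nt] - peak_mass[pos_peak[nt]]))))) {
          ni = ip; nj = jp; nt = idx;
        }
      }
      if (ni < 0) stop("traceback failed: no predecessor found");
      cj = nj; ct = nt; --v;
    }
  }

  return List::create(_["score"] = best,
                      _["node"] = a_node, _["peak"] = a_peak,
                      _["k"] = a_k, _["pos"] = a_pos);
}
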