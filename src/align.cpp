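#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U/T by the R callers.

// Global alignment of tag vs reference counting substitutions and gap
// columns separately. The tag is assignable iff an edit-optimal
// alignment (minimal substitutions + gap columns, i.e. Levenshtein
// distance) has subs <= max_mm and gap columns <= max_gap; a suboptimal
// alignment that happens to fit the bounds does not count, mirroring
// how an aligner reports its best alignment before filters apply.
// Returns (edits, subs, gaps) of the qualifying optimal alignment, or
// (-1,-1,-1).
// [[Rcpp::export]]
IntegerVector align_bounded_cpp(IntegerVector a, IntegerVector b,
                                int max_mm, int max_gap) {
  const int n = a.size(), m = b.size();
  const int G = max_gap + 1;
  const int INF = 1000000;
  // f[g][i][j]: min substitutions aligning a[0..i) with b[0..j) using g gaps
  std::vector<int> f((size_t)G * (n + 1) * (m + 1), INF);
  auto idx = [&](int g, int i, int j) {
    return ((size_t)g * (n + 1) + i) * (m + 1) + j;
  };
  f[idx(0, 0, 0)] = 0;
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        int cur = f[idx(g, i, j)];
        if (cur >= INF) continue;
        if (i < n && j < m) {
          int c = cur + (a[i] == b[j] ? 0 : 1);
          if (c < f[idx(g, i + 1, j + 1)]) f[idx(g, i + 1, j + 1)] = c;
        }
        if (g + 1 < G) {
          if (i < n && cur < f[idx(g + 1, i + 1, j)])
            f[idx(g + 1, i + 1, j)] = cur;
          if (j < m && cur < f[idx(g + 1, i, j + 1)])
            f[idx(g + 1, i, j + 1)] = cur;
        }
      }
    }
  }
  // unrestricted Levenshtein distance (unit costs) for the optimality
  // requirement
  std::vector<int> prev(m + 1), curr(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    curr[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      curr[j] = std::min(sub, std::min(prev[j], curr[j - 1]) + 1);
    }
    std::swap(prev, curr);
  }
  int lev = prev[m];
  int best_mm = -1, best_gap = -1;
  for (int g = 0; g < G; ++g) {
    int mm = f[idx(g, n, m)];
    if (mm <= max_mm && mm + g == lev) {
      best_mm = mm;
      best_gap = g;
      break; // fewest gaps among qualifying optimal alignments
    }
  }
  if (best_mm < 0) return IntegerVector::create(-1, -1, -1);
  return IntegerVector::create(lev, best_mm, best_gap);
}

// Penalty of pairing miRNA base mi against the reverse-complemented site
// base rj: 0 = Watson-Crick match, 1 = G:U wobble, 2 = mismatch.
static inline int pair_kind(int mi, int rj) {
  if (mi == rj) return 0;
  if ((mi == 2 && rj == 0) || (mi == 3 && rj == 1)) return 1; // G:U
  return 2;
}

// Banded global alignment of a miRNA against every window (length within
// +-band of the miRNA) of a reverse-complemented transcript, under plant
// target-site penalties: match 0, G:U p_gu, mismatch p_mm, indel p_gap,
// all doubled at miRNA core positions [core_lo, core_hi] (1-based).
// Returns every window whose minimal penalty is <= cutoff.
// Coordinates are on the reverse-complemented transcript, 1-based.
// [[Rcpp::export]]
DataFrame scan_windows_cpp(IntegerVector m, IntegerVector r,
                           double p_gu, double p_mm, double p_gap,
                           int core_lo, int core_hi,
                           double cutoff, int band) {
  const int L = m.size(), n = r.size();
  const double INF = 1e9;
  std::vector<int> starts, ends;
  std::vector<double> pens;
  // weight multiplier for miRNA position i (1-based)
  auto mult = [&](int i) {
    return (i >= core_lo && i <= core_hi) ? 2.0 : 1.0;
  };
  const int W = 2 * band + 1;        // columns tracked per row (offset band)
  std::vector<double> prev(W), cur(W);
  for (int a = 1; a <= n; ++a) {     // window start on rc transcript
    // row 0: offsets correspond to consumed site length j - (a-1)
    // prev[k] = penalty with 0 miRNA positions and (k - band) site bases:
    // leading site-only columns are gaps in the miRNA.
    bool alive = false;
    for (int k = 0; k < W; ++k) {
      int off = k - band; // site consumed minus miRNA consumed
      if (off < 0) { prev[k] = INF; continue; }
      // off leading gaps in miRNA before position 1: doubled iff pos 1 core
      prev[k] = off * p_gap * mult(1);
      if (prev[k] <= cutoff) alive = true;
    }
    for (int i = 1; i <= L && alive; ++i) {
      alive = false;
      for (int k = 0; k < W; ++k) {
        int off = k - band;
        int j = a - 1 + i + off; // site position consumed so far
        double best = INF;
        if (j >= a - 1 && j <= n) {
          // diagonal: consume m[i] and r[j]
          if (j >= a) {
            double d = prev[k];
            if (d < INF) {
              int kind = pair_kind(m[i - 1], r[j - 1]);
              double c = kind == 0 ? 0.0 : (kind == 1 ? p_gu : p_mm);
              best = d + c * mult(i);
            }
          }
          // gap in site: consume m[i] only (offset decreases)
          if (k + 1 < W && prev[k + 1] < INF) {
            double c = prev[k + 1] + p_gap * mult(i);
            if (c < best) best = c;
          }
          // gap in miRNA: consume r[j] only (same row, offset increases)
          if (k - 1 >= 0 && j >= a && cur[k - 1] < INF) {
            double gm = (i < L) ? mult(i + 1) : 1.0;
            double c = cur[k - 1] + p_gap * gm;
            if (c < best) best = c;
          }
        }
        cur[k] = (best <= cutoff) ? best : INF;
        if (cur[k] < INF) alive = true;
      }
      std::swap(prev, cur);
    }
    if (!alive) continue;
    for (int k = 0; k < W; ++k) {
      if (prev[k] >= INF) continue;
      int off = k - band;
      int b = a - 1 + L + off; // window end
      if (b < a || b > n) continue;
      starts.push_back(a);
      ends.push_back(b);
      pens.push_back(prev[k]);
    }
  }
  return DataFrame::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                           _["penalty"] = wrap(pens));
}
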