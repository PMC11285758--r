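#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Low-probability subsequence scanner core.
//
// codes: residue codes 0..19 in alphabetical amino-acid order
//        ("ACDEFGHIKLMNPQRSTVWY"); -1 marks 'X' (unknown residue).
// bg:    background frequency for each of the 20 residues (sums to 1).
// t:     p-value threshold; m/M: min/max window length in residues.
//
// For every window [i, j) with m <= j-i <= M that contains no X, candidate
// residue sets of size 1..5 are grown greedily from the window's most
// frequent residues (ties broken by alphabetical order). Each set is scored
// by the binomial upper tail P(X >= c) with c = count of set residues,
// n = window length, p = summed background frequency. Windows whose best
// score is <= t are retained, then selected greedily by ascending p-value
// (ties: longer window, then smaller start), discarding overlaps.

struct Win {
  int start, end;
  double p;
  int k;
  int set[5];
};

static bool win_order(const Win &a, const Win &b) {
  if (a.p != b.p) return a.p < b.p;
  int la = a.end - a.start, lb = b.end - b.start;
  if (la != lb) return la > lb;
  return a.start < b.start;
}

// [[Rcpp::export]]
List scan_core_cpp(IntegerVector codes, NumericVector bg, double t, int m,
                   int M) {
  const int L = codes.size();
  std::vector<Win> cand;
  for (int i = 0; i < L; ++i) {
    int counts[20] = {0};
    int jmax = std::min(L, i + M);
    for (int j = i; j < jmax; ++j) {
      int c = codes[j];
      if (c < 0) break;  // every longer window from i would contain the X
      counts[c]++;
      int len = j - i + 1;
      if (len < m) continue;
      bool used[20] = {false};
      int ccum = 0;
      double pcum = 0.0;
      double best_p = 2.0;
      int best_k = 0;
      int cur[5], best[5];
      for (int k = 0; k < 5; ++k) {
        int bi = -1, bc = 0;
        for (int r = 0; r < 20; ++r)
          if (!used[r] && counts[r] > bc) {
            bc = counts[r];
            bi = r;
          }
        if (bi < 0) break;  // no further residue present in the window
        used[bi] = true;
        cur[k] = bi;
        ccum += bc;
        pcum += bg[bi];
        double pv;
        if (pcum >= 1.0) {
          pv = 1.0;
        } else if (t < 0.4 && (double)ccum <= (double)len * pcum) {
          // c <= floor(n*p) implies P(X >= c) >= 1/2 (binomial median bound),
          // so the window cannot pass a threshold below 0.4; skip the tail.
          pv = 1.0;
        } else {
          pv = R::pbinom(ccum - 1, (double)len, pcum, 0, 0);
        }
        if (pv < best_p) {
          best_p = pv;
          best_k = k + 1;
          for (int q = 0; q <= k; ++q) best[q] = cur[q];
        }
      }
      if (best_p <= t) {
        Win w;
        w.start = i;
        w.end = j + 1;
        w.p = best_p;
        w.k = best_k;
        for (int q = 0; q < best_k; ++q) w.set[q] = best[q];
        cand.push_back(w);
      }
    }
  }
  std::stable_sort(cand.begin(), cand.end(), win_order);
  std::vector<char> occ(L, 0);
  std::vector<int> sel;
  for (size_t w = 0; w < cand.size(); ++w) {
    bool free_ = true;
    for (int x = cand[w].start; x < cand[w].end; ++x)
      if (occ[x]) {
        free_ = false;
        break;
      }
    if (!free_) continue;
    for (int x = cand[w].start; x < cand[w].end; ++x) occ[x] = 1;
    sel.push_back((int)w);
  }
  std::sort(sel.begin(), sel.end(),
            [&](int a, int b) { return cand[a].start < cand[b].start; });
  const int n = (int)sel.size();
  IntegerVector s(n), e(n);
  NumericVector p(n);
  CharacterVector sig(n);
  const char *AA = "ACDEFGHIKLMNPQRSTVWY";
  for (int q = 0; q < n; ++q) {
    const Win &w = cand[sel[q]];
    s[q] = w.start;
    e[q] = w.end;
    p[q] = w.p;
    std::vector<char> ss;
    for (int z = 0; z < w.k; ++z) ss.push_back(AA[w.set[z]]);
    std::sort(ss.begin(), ss.end());
    sig[q] = std::string(ss.begin(), ss.end());
  }
  return List::create(_["start0"] = s, _["end0"] = e, _["pvalue"] = p,
                      _["signature"] = sig);
}
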