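#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Unit-cost Levenshtein distance over integer symbol vectors.
// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(IntegerVector a, IntegerVector b) {
  const int la = a.size(), lb = b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Smith-Waterman local alignment over symbols: match +1, mismatch -1, gap -1.
// Returns 1-based inclusive spans of the best local alignment in each input
// (0s when the best alignment is empty). Ties broken by leftmost start in b,
// then shortest span, then leftmost start in a.
// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(IntegerVector a, IntegerVector b) {
  const int la = a.size(), lb = b.size();
  // H: (la+1) x (lb+1); start positions propagated along the traceback.
  std::vector<std::vector<int> > H(la + 1, std::vector<int>(lb + 1, 0));
  std::vector<std::vector<int> > si(la + 1, std::vector<int>(lb + 1, 0));
  std::vector<std::vector<int> > sj(la + 1, std::vector<int>(lb + 1, 0));
  int best = 0, bi = 0, bj = 0, b_si = 0, b_sj = 0;
  long best_span = 0;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int diag = H[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      int up = H[i - 1][j] - 1;
      int left = H[i][j - 1] - 1;
      int val = std::max(0, std::max(diag, std::max(up, left)));
      H[i][j] = val;
      if (val == 0) { si[i][j] = i; sj[i][j] = j; continue; }
      // preference: diagonal, then up, then left (deterministic)
      if (val == diag) {
        si[i][j] = (H[i - 1][j - 1] == 0) ? i - 1 : si[i - 1][j - 1];
        sj[i][j] = (H[i - 1][j - 1] == 0) ? j - 1 : sj[i - 1][j - 1];
      } else if (val == up) {
        si[i][j] = si[i - 1][j]; sj[i][j] = sj[i - 1][j];
      } else {
        si[i][j] = si[i][j - 1]; sj[i][j] = sj[i][j - 1];
      }
      if (val > 0) {
        long span = (long)(i - si[i][j]) + (long)(j - sj[i][j]);
        bool take = false;
        if (val > best) take = true;
        else if (val == best && best > 0) {
          if (sj[i][j] < b_sj) take = true;
          else if (sj[i][j] == b_sj) {
            if (span < best_span) take = true;
            else if (span == best_span && si[i][j] < b_si) take = true;
          }
        }
        if (take) {
          best = val; bi = i; bj = j;
          b_si = si[i][j]; b_sj = sj[i][j]; best_span = span;
        }
      }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  return List::create(_["score"] = best,
                      _["a_start"] = b_si + 1, _["a_end"] = bi,
                      _["b_start"] = b_sj + 1, _["b_end"] = bj);
}

// Needleman-Wunsch global score with the same +1/-1/-1 scheme (oracle helper).
static int nw_score(const std::vector<int>& a, const std::vector<int>& b) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = -j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = -i;
    for (int j = 1; j <= lb; ++j) {
      int diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      cur[j] = std::max(diag, std::max(prev[j] - 1, cur[j - 1] - 1));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Exhaustive local alignment oracle: best global alignment score over all
// substring pairs (including empty, score 0).
// [[Rcpp::export(name = ".exhaustive_local_cpp")]]
int exhaustive_local_cpp(IntegerVector a, IntegerVector b) {
  const int la = a.size(), lb = b.size();
  int best = 0;
  for (int i1 = 0; i1 < la; ++i1) {
    for (int i2 = i1; i2 < la; ++i2) {
      std::vector<int> sa(a.begin() + i1, a.begin() + i2 + 1);
      for (int j1 = 0; j1 < lb; ++j1) {
        for (int j2 = j1; j2 < lb; ++j2) {
          std::vector<int> sb(b.begin() + j1, b.begin() + j2 + 1);
          best = std::max(best, nw_score(sa, sb));
        }
      }
    }
  }
  return best;
}

// Exact median permutation under summed Levenshtein distance: enumerates all
// permutations of `symbols` (lexicographic order; first minimum kept, so ties
// resolve to the lexicographically smallest).
// [[Rcpp::export(name = ".exact_median_cpp")]]
List exact_median_cpp(List perms, IntegerVector symbols) {
  std::vector<std::vector<int> > ps;
  for (int k = 0; k < perms.size(); ++k) {
    IntegerVector v = perms[k];
    ps.push_back(std::vector<int>(v.begin(), v.end()));
  }
  std::vector<int> cand(symbols.begin(), symbols.end());
  std::sort(cand.begin(), cand.end());
  std::vector<int> bestp = cand;
  long best = -1;
  const int m = (int)cand.size();
  std::vector<int> prev(64), cur(64);
  do {
    long tot = 0;
    for (size_t k = 0; k < ps.size(); ++k) {
      const std::vector<int>& g = ps[k];
      const int lb = (int)g.size();
      for (int j = 0; j <= lb; ++j) prev[j] = j;
      for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        for (int j = 1; j <= lb; ++j) {
          int sub = prev[j - 1] + (cand[i - 1] == g[j - 1] ? 0 : 1);
          cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
      }
      tot += prev[lb];
      if (best >= 0 && tot >= best) break;  // prune: cannot improve
    }
    if (best < 0 || tot < best) { best = tot; bestp = cand; }
  } while (std::next_permutation(cand.begin(), cand.end()));
  return List::create(_["ordering"] = IntegerVector(bestp.begin(), bestp.end()),
                      _["cost"] = (double)best);
}
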