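#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Residue pair score. 'N' is an ambiguity code: it never scores as a match,
// not even against another 'N'.
static inline int pair_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

static inline bool pair_is_match(char x, char y) {
  return x != 'N' && y != 'N' && x == y;
}

//' @title Smith-Waterman local alignment (linear gap model)
//' @description Internal C++ kernel. Finds a maximal-scoring local alignment
//'   of two residue strings under match/mismatch scores and a single linear
//'   per-column gap penalty. Deterministic and symmetric in its match count:
//'   among co-optimal alignments the one with the most matched residue pairs
//'   is chosen (the match count of an optimal alignment set is invariant
//'   under swapping the inputs), then the lowest end coordinate in \code{a},
//'   then in \code{b}; the traceback prefers diagonal over up (gap in b)
//'   over left moves among ties.
//' @noRd
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap) {
  const int n = (int) a.size(), m = (int) b.size();
  // full matrices: queries and windows are <= a few kb, so n*m ints are cheap
  // H: best local score ending at (i, j); M: max matches among score-optimal
  // local alignments ending at (i, j)
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> M((size_t)(n + 1) * (m + 1), 0);

  int best = 0, best_m = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int *Hp = H.data() + (size_t)(i - 1) * (m + 1);
    int *Hi = H.data() + (size_t) i * (m + 1);
    const int *Mp = M.data() + (size_t)(i - 1) * (m + 1);
    int *Mi = M.data() + (size_t) i * (m + 1);
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool is_m = pair_is_match(ai, b[j - 1]);
      int diag = Hp[j - 1] + (is_m ? match : mismatch);
      int up   = Hp[j] + gap;   // consume a[i-1], gap in b
      int left = Hi[j - 1] + gap;   // consume b[j-1], gap in a
      int h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      Hi[j] = h;
      int mm = 0;
      if (h > 0) {
        mm = -1;
        if (diag == h) mm = Mp[j - 1] + (is_m ? 1 : 0);
        if (up == h && Mp[j] > mm) mm = Mp[j];
        if (left == h && Mi[j - 1] > mm) mm = Mi[j - 1];
      }
      Mi[j] = mm;
      // keep the earliest (lowest-i, then lowest-j) end among co-optimal
      // cells with the maximal match count
      if (h > best || (h == best && h > 0 && mm > best_m)) {
        best = h; best_m = mm; bi = i; bj = j;
      }
    }
  }

  std::string a_aln, b_aln;
  int matches = 0, mismatches = 0, gaps = 0;
  int i = bi, j = bj;
  if (best > 0) {
    auto at = [m](int r, int c) { return (size_t) r * (m + 1) + c; };
    while (i > 0 && j > 0 && H[at(i, j)] > 0) {
      int h = H[at(i, j)], mm = M[at(i, j)];
      const bool is_m = pair_is_match(a[i - 1], b[j - 1]);
      int diag = H[at(i - 1, j - 1)] + (is_m ? match : mismatch);
      if (diag == h && M[at(i - 1, j - 1)] + (is_m ? 1 : 0) == mm) {
        if (is_m) ++matches; else ++mismatches;
        a_aln.push_back(a[i - 1]); b_aln.push_back(b[j - 1]);
        --i; --j;
      } else if (H[at(i - 1, j)] + gap == h && M[at(i - 1, j)] == mm) {
        a_aln.push_back(a[i - 1]); b_aln.push_back('-');
        ++gaps; --i;
      } else {
        a_aln.push_back('-'); b_aln.push_back(b[j - 1]);
        ++gaps; --j;
      }
    }
    std::reverse(a_aln.begin(), a_aln.end());
    std::reverse(b_aln.begin(), b_aln.end());
  } else {
    bi = bj = i = j = 0;  // empty alignment
  }

  return List::create(
    _["score"] = best, _["matches"] = matches,
    _["mismatches"] = mismatches, _["gaps"] = gaps,
    _["a_start"] = i, _["a_end"] = bi,
    _["b_start"] = j, _["b_end"] = bj,
    _["a_aln"] = a_aln, _["b_aln"] = b_aln);
}

//' @title Longest exact common substring of two residue strings
//' @description Internal C++ kernel used by the mock search backend to model
//'   word-size-dependent discoverability. 'N' never matches. Returns the
//'   length and 0-based start coordinates of the maximal shared block; ties
//'   resolve to the block ending earliest in \code{a}, then in \code{b}.
//' @noRd
// [[Rcpp::export(name = ".lcs_cpp")]]
List lcs_cpp(std::string a, std::string b) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, bi = 0, bj = 0;  // bi, bj: 0-based block ends (exclusive)
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (pair_is_match(a[i - 1], b[j - 1])) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) { best = cur[j]; bi = i; bj = j; }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return List::create(
    _["length"] = best,
    _["a_start"] = bi - best, _["b_start"] = bj - best);
}
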