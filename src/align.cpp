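#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Dynamic-programming aligners used by the assembly, clustering and
// contaminant-filter stages.  All use a linear gap penalty; scores are
// integers (match/mismatch/gap configurable from R).

static inline int score_pair(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch; // N never counts as a match
  return (x == y) ? match : mismatch;
}

// Overlap alignment of a suffix of `a` against a prefix of `b`.
// Leading bases of `a` and trailing bases of `b` are free; additionally the
// trailing bases of `a` are free so that a left read sequenced through the
// right read's end (adapter read-through) still finds the genuine overlap.
// Returns the traceback path so the caller can build a consensus.
// [[Rcpp::export]]
List overlap_align_cpp(std::string a, std::string b,
                       int match = 1, int mismatch = -2, int gap = -3) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  for (int j = 1; j <= m; ++j) H[0][j] = H[0][j - 1] + gap;
  for (int i = 1; i <= n; ++i) {
    H[i][0] = 0; // free skip of a's prefix
    for (int j = 1; j <= m; ++j) {
      int diag = H[i - 1][j - 1] + score_pair(a[i - 1], b[j - 1], match, mismatch);
      int up   = H[i - 1][j] + gap;
      int left = H[i][j - 1] + gap;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H[i][j] = best;
    }
  }
  // best end: anywhere on the last row (rest of b free) or the last column
  // (rest of a free)
  int ibest = n, jbest = 0, sbest = H[n][0];
  for (int j = 1; j <= m; ++j)
    if (H[n][j] > sbest) { sbest = H[n][j]; ibest = n; jbest = j; }
  for (int i = 1; i <= n; ++i)
    if (H[i][m] > sbest) { sbest = H[i][m]; ibest = i; jbest = m; }

  // traceback until j == 0
  std::vector<int> ai, bi;
  int i = ibest, j = jbest, matches = 0, aln_len = 0;
  while (j > 0) {
    if (i > 0 && H[i][j] == H[i - 1][j - 1] +
          score_pair(a[i - 1], b[j - 1], match, mismatch)) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      ai.push_back(i); bi.push_back(j);
      --i; --j; ++aln_len;
    } else if (i > 0 && H[i][j] == H[i - 1][j] + gap) {
      ai.push_back(i); bi.push_back(0);
      --i; ++aln_len;
    } else {
      ai.push_back(0); bi.push_back(j);
      --j; ++aln_len;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a_start"] = i,          // 0-based start of overlap in a
                      _["a_end"] = ibest,        // 0-based exclusive end in a
                      _["b_end"] = jbest,        // 0-based exclusive end in b
                      _["score"] = sbest,
                      _["matches"] = matches,
                      _["aln_len"] = aln_len,
                      _["ai"] = wrap(ai),        // 1-based positions, 0 = gap
                      _["bi"] = wrap(bi));
}

// Semi-global alignment: `s` (the shorter sequence) aligned globally,
// end gaps on `l` free.  Identity = matches / aln_len over the aligned span.
// [[Rcpp::export]]
List glocal_align_cpp(std::string s, std::string l,
                      int match = 1, int mismatch = -2, int gap = -3) {
  int n = s.size(), m = l.size();
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) H[i][0] = H[i - 1][0] + gap;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int diag = H[i - 1][j - 1] + score_pair(s[i - 1], l[j - 1], match, mismatch);
      int up   = H[i - 1][j] + gap;
      int left = H[i][j - 1] + gap;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H[i][j] = best;
    }
  int jbest = 0, sbest = H[n][0];
  for (int j = 1; j <= m; ++j) if (H[n][j] > sbest) { sbest = H[n][j]; jbest = j; }
  int i = n, j = jbest, matches = 0, aln_len = 0;
  while (i > 0) {
    if (j > 0 && H[i][j] == H[i - 1][j - 1] +
          score_pair(s[i - 1], l[j - 1], match, mismatch)) {
      if (s[i - 1] == l[j - 1] && s[i - 1] != 'N') ++matches;
      --i; --j; ++aln_len;
    } else if (H[i][j] == H[i - 1][j] + gap) {
      --i; ++aln_len;
    } else {
      --j; ++aln_len;
    }
  }
  return List::create(_["score"] = sbest,
                      _["matches"] = matches,
                      _["aln_len"] = aln_len,
                      _["l_start"] = j,
                      _["l_end"] = jbest);
}

// Smith-Waterman local alignment; returns the best local alignment's score,
// match count and length (enough to apply length/identity thresholds).
// [[Rcpp::export]]
List local_align_cpp(std::string a, std::string b,
                     int match = 1, int mismatch = -2, int gap = -3) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  int sbest = 0, ibest = 0, jbest = 0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int diag = H[i - 1][j - 1] + score_pair(a[i - 1], b[j - 1], match, mismatch);
      int up   = H[i - 1][j] + gap;
      int left = H[i][j - 1] + gap;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      if (best < 0) best = 0;
      H[i][j] = best;
      if (best > sbest) { sbest = best; ibest = i; jbest = j; }
    }
  int i = ibest, j = jbest, matches = 0, aln_len = 0;
  while (i > 0 && j > 0 && H[i][j] > 0) {
    if (H[i][j] == H[i - 1][j - 1] +
          score_pair(a[i - 1], b[j - 1], match, mismatch)) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      --i; --j; ++aln_len;
    } else if (H[i][j] == H[i - 1][j] + gap) {
      --i; ++aln_len;
    } else {
      --j; ++aln_len;
    }
  }
  return List::create(_["score"] = sbest,
                      _["matches"] = matches,
                      _["aln_len"] = aln_len,
                      _["a_start"] = i, _["a_end"] = ibest,
                      _["b_start"] = j, _["b_end"] = jbest);
}
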