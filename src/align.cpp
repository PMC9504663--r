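#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

// Shared scoring: unit match/mismatch with a linear gap cost. Comparison is
// case-insensitive so soft-masked (lowercase) residues still align; 'N' (an
// assembly gap / hard-masked base) never scores as a match. Sequences are
// normalised once per call: uppercase, with N mapped to 0 on one side and
// 1 on the other so N never equals anything (including another N).
static std::vector<char> norm_seq(const std::string &s, char n_code) {
  std::vector<char> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c >= 'a' && c <= 'z') c -= 32;
    if (c == 'N') c = n_code;
    out[i] = c;
  }
  return out;
}

static inline bool base_match(char a, char b) { return a == b; }

// Global (Needleman-Wunsch) alignment of a vs b.
// Returns score, number of matched columns and total aligned columns
// (including gap columns) of one optimal alignment.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  const size_t n = a.size(), m = b.size();
  const std::vector<char> an = norm_seq(a, 0), bn = norm_seq(b, 1);
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> T((n + 1) * (m + 1));
  for (size_t i = 0; i <= n; ++i) T[i * (m + 1)] = 1;  // 1 = up (gap in b)
  for (size_t j = 0; j <= m; ++j) { prev[j] = gap * j; T[j] = 2; }
  T[0] = 0;
  for (size_t i = 1; i <= n; ++i) {
    const char ai = an[i - 1];
    unsigned char *Ti = &T[i * (m + 1)];
    cur[0] = gap * i;
    for (size_t j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (base_match(ai, bn[j - 1]) ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; unsigned char t = 0;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      cur[j] = best; Ti[j] = t;
    }
    std::swap(prev, cur);
  }
  size_t i = n, j = m; int matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char t = T[i * (m + 1) + j];
    ++cols;
    if (t == 0) { if (base_match(an[i - 1], bn[j - 1])) ++matches; --i; --j; }
    else if (t == 1) { --i; }
    else { --j; }
  }
  return List::create(_["score"] = prev[m], _["matches"] = matches,
                      _["aln_length"] = cols);
}

// Local (Smith-Waterman) alignment: best-scoring local alignment of query a
// within subject b. Coordinates are 0-based half-open on each input string.
// Flat row-major DP with a byte traceback matrix keeps the inner loop tight.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  const size_t n = a.size(), m = b.size();
  const std::vector<char> an = norm_seq(a, 0), bn = norm_seq(b, 1);
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<unsigned char> T((n + 1) * (m + 1), 3); // 3 = stop (score 0)
  double best = 0.0; size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= n; ++i) {
    const char ai = an[i - 1];
    unsigned char *Ti = &T[i * (m + 1)];
    cur[0] = 0.0;
    for (size_t j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (base_match(ai, bn[j - 1]) ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double v = d; unsigned char t = 0;
      if (u > v) { v = u; t = 1; }
      if (l > v) { v = l; t = 2; }
      if (v <= 0.0) { v = 0.0; t = 3; }
      cur[j] = v; Ti[j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  size_t i = bi, j = bj; int matches = 0, cols = 0;
  while (i > 0 && j > 0 && T[i * (m + 1) + j] != 3) {
    unsigned char t = T[i * (m + 1) + j];
    ++cols;
    if (t == 0) { if (base_match(an[i - 1], bn[j - 1])) ++matches; --i; --j; }
    else if (t == 1) { --i; }
    else { --j; }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["aln_length"] = cols,
                      _["qstart"] = (int)i, _["qend"] = (int)bi,
                      _["sstart"] = (int)j, _["send"] = (int)bj);
}

// Longest strictly increasing subsequence length (patience-sorting style
// O(n log n)); used by the minimal-removal order-concordance metric.
// [[Rcpp::export]]
int lis_length_cpp(IntegerVector x) {
  std::vector<int> tails;
  for (int k = 0; k < x.size(); ++k) {
    int v = x[k];
    std::vector<int>::iterator it =
        std::lower_bound(tails.begin(), tails.end(), v);
    if (it == tails.end()) tails.push_back(v); else *it = v;
  }
  return static_cast<int>(tails.size());
}
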