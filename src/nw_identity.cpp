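#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty, returning the
// fraction of identical columns among aligned columns, with terminal gap
// columns excluded from the denominator and internal gap columns counted as
// mismatches. Scoring: match = 1, mismatch = 0, gap = -1. Ties in the
// traceback are resolved diagonal > up > left, which is immaterial to the
// optimal score but makes the reported identity deterministic.

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b,
                       double match = 1.0, double mismatch = 0.0,
                       double gap = -1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // rolling score rows + full traceback (0 = diag, 1 = up, 2 = left)
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> P((size_t)(n + 1) * (m + 1));
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; P[j] = 2; }
  for (int i = 1; i <= n; ++i) P[(size_t)i * (m + 1)] = 1;

  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    const char ai = a[i - 1];
    uint8_t *Pi = &P[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      if (d >= u && d >= l)      { cur[j] = d; Pi[j] = 0; }
      else if (u >= l)           { cur[j] = u; Pi[j] = 1; }
      else                       { cur[j] = l; Pi[j] = 2; }
    }
    std::swap(prev, cur);
  }

  // traceback into column classes: 0 match, 1 mismatch, 2 gap
  std::vector<uint8_t> cols;
  cols.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t p = P[(size_t)i * (m + 1) + j];
    if (p == 0)      { cols.push_back(a[i - 1] == b[j - 1] ? 0 : 1); --i; --j; }
    else if (p == 1) { cols.push_back(2); --i; }
    else             { cols.push_back(2); --j; }
  }
  // trim terminal gap runs at both ends (cols is reversed; ends are ends)
  int lo = 0, hi = (int)cols.size() - 1;
  while (lo <= hi && cols[hi] == 2) --hi; // alignment start
  while (lo <= hi && cols[lo] == 2) ++lo; // alignment end
  int denom = hi - lo + 1, matches = 0;
  if (denom <= 0) return 0.0;
  for (int k = lo; k <= hi; ++k) if (cols[k] == 0) ++matches;
  return (double)matches / (double)denom;
}
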