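#include <Rcpp.h>
#include <cstring>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Unit-cost Levenshtein distance, full dynamic programme, two rolling rows.
static int lev_full(const char *a, int n, const char *b, int m) {
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded Levenshtein bounded by t. Returns the exact distance when it is
// <= t, otherwise -1 ("over threshold"). Three-stage contract:
//   1) length-difference pre-check (a lower bound on the distance);
//   2) DP restricted to the band of width 2t+1 around the main diagonal;
//   3) early exit when every cell in the current row's band exceeds t
//      (cell values along a diagonal never decrease, so no later cell in
//      the band can drop back to <= t).
static int lev_bounded(const char *a, int n, const char *b, int m, int t) {
  if (t < 0) return -1;
  if (n > m) { std::swap(a, b); std::swap(n, m); }
  if (m - n > t) return -1;
  if (n == 0) return m <= t ? m : -1;
  // Row i covers columns j in [i - t, i + t] intersected with [0, m].
  const int W = 2 * t + 1;
  std::vector<int> prev(W + 2), cur(W + 2);
  const int BIG = t + 1;
  for (int k = 0; k < W + 2; ++k) prev[k] = BIG;
  // Row 0: D[0, j] = j for j <= t.
  for (int j = 0; j <= t && j <= m; ++j) prev[j - 0 + t] = j;  // index j - i + t
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - t), hi = std::min(m, i + t);
    bool alive = false;
    for (int k = 0; k < W + 2; ++k) cur[k] = BIG;
    for (int j = lo; j <= hi; ++j) {
      int k = j - i + t;  // band-local column index
      int best = BIG;
      if (j > 0) {
        int diag = prev[k];  // D[i-1, j-1] sits at same band index in prev row
        int sub = diag + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (sub < best) best = sub;
      } else {
        best = i <= t ? i : BIG;  // D[i, 0] = i
      }
      int up = (k + 1 <= W + 1) ? prev[k + 1] : BIG;  // D[i-1, j]
      if (up + 1 < best) best = up + 1;
      if (k - 1 >= 0) {
        int left = cur[k - 1];  // D[i, j-1]
        if (left + 1 < best) best = left + 1;
      }
      if (best > BIG) best = BIG;
      cur[k] = best;
      if (best <= t) alive = true;
    }
    if (!alive) return -1;
    std::swap(prev, cur);
  }
  int d = prev[m - n + t];
  return d <= t ? d : -1;
}

// [[Rcpp::export(name = ".lev_full_vec")]]
IntegerVector lev_full_vec(CharacterVector s1, CharacterVector s2) {
  R_xlen_t n = std::max(s1.size(), s2.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(s1, s1.size() == 1 ? 0 : i));
    const char *b = CHAR(STRING_ELT(s2, s2.size() == 1 ? 0 : i));
    out[i] = lev_full(a, (int)std::strlen(a), b, (int)std::strlen(b));
  }
  return out;
}

// Bounded variant; NA marks "distance exceeds the bound". t may be a
// scalar or one bound per pair; negative/NA bounds yield NA.
// [[Rcpp::export(name = ".lev_bounded_vec")]]
IntegerVector lev_bounded_vec(CharacterVector s1, CharacterVector s2,
                              IntegerVector t) {
  R_xlen_t n = std::max(std::max(s1.size(), s2.size()), t.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(s1, s1.size() == 1 ? 0 : i));
    const char *b = CHAR(STRING_ELT(s2, s2.size() == 1 ? 0 : i));
    int ti = t[t.size() == 1 ? 0 : i];
    if (ti == NA_INTEGER || ti < 0) { out[i] = NA_INTEGER; continue; }
    int d = lev_bounded(a, (int)std::strlen(a), b, (int)std::strlen(b), ti);
    out[i] = d < 0 ? NA_INTEGER : d;
  }
  return out;
}
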