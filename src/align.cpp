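#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Banded global alignment of two strings, unit scores (match +1, mismatch -1,
// gap -1), band limits |i - j| <= band. Returns the number of matched bases,
// the number of alignment columns and the score along one optimal path.
// Cells outside the band are unreachable; callers must pick `band` at least as
// large as the expected indel drift between the two sequences.
//
// Row-compressed DP: in row i, column j lives at offset j - i + band + 1; the
// arrays carry one sentinel cell on each side of the band so the inner loop
// is branch-light. Match and column counts ride along the winning transition.
// [[Rcpp::export]]
IntegerVector banded_align_cpp(std::string a, std::string b, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 1) band = 1;
  if (std::abs(n - m) > band)
    band = std::abs(n - m) + 8;  // band must reach the corner cell
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> sc(W + 2, NEG), scp(W + 2, NEG);
  std::vector<int> mt(W + 2, 0), mtp(W + 2, 0);
  std::vector<int> al(W + 2, 0), alp(W + 2, 0);
  // row i = 0: leading gaps in a
  for (int j = 0; j <= std::min(m, band); ++j) {
    scp[j + band + 1] = -j;
    alp[j + band + 1] = j;
  }
  const char* ca = a.c_str();
  const char* cb = b.c_str();
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    int* s = sc.data();
    int* q = mt.data();
    int* l = al.data();
    const int* ps = scp.data();
    const int* pq = mtp.data();
    const int* pl = alp.data();
    s[jlo - i + band] = NEG;  // left sentinel for this row
    const char ai = ca[i - 1];
    int j = jlo;
    if (j == 0) {  // no diagonal into column 0
      const int o = band - i + 1;
      int best = ps[o + 1] - 1;
      int bm = pq[o + 1], ba = pl[o + 1] + 1;
      if (best < NEG) best = NEG;
      s[o] = best; q[o] = bm; l[o] = ba;
      ++j;
    }
    for (; j <= jhi; ++j) {
      const int o = j - i + band + 1;
      const bool eq = ai == cb[j - 1];
      int best = ps[o] + (eq ? 1 : -1);
      int bm = pq[o] + (eq ? 1 : 0);
      int ba = pl[o] + 1;
      const int up = ps[o + 1] - 1;
      if (up > best) { best = up; bm = pq[o + 1]; ba = pl[o + 1] + 1; }
      const int lf = s[o - 1] - 1;
      if (lf > best) { best = lf; bm = q[o - 1]; ba = l[o - 1] + 1; }
      if (best < NEG) best = NEG;
      s[o] = best; q[o] = bm; l[o] = ba;
    }
    const int right = jhi - i + band + 2;
    if (right <= W + 1) s[right] = NEG;
    std::swap(sc, scp); std::swap(mt, mtp); std::swap(al, alp);
  }
  const int o = m - n + band + 1;
  if (o < 1 || o > W || scp[o] <= NEG + (n + m) + 8)
    return IntegerVector::create(0, 0, NEG);
  return IntegerVector::create(mtp[o], alp[o], scp[o]);
}

// Window minimizers over a numeric hash sequence: for every window of w
// consecutive hashes report the position (1-based) of the leftmost minimum.
// Returns the deduplicated, sorted position list. O(n) monotone deque.
// [[Rcpp::export]]
IntegerVector minimizer_positions_cpp(NumericVector h, int w) {
  const int n = h.size();
  if (n == 0) return IntegerVector(0);
  if (w < 1) w = 1;
  if (w > n) w = n;
  std::deque<int> dq;  // indices, increasing hash values
  std::vector<int> out;
  out.reserve(2 * n / w + 4);
  for (int i = 0; i < n; ++i) {
    while (!dq.empty() && h[dq.back()] > h[i]) dq.pop_back();
    dq.push_back(i);
    if (dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1) {
      // leftmost index achieving the window minimum
      int pos = dq.front();
      if (out.empty() || out.back() != pos + 1) out.push_back(pos + 1);
    }
  }
  return IntegerVector(out.begin(), out.end());
}
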