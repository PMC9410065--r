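#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global affine alignment machinery shared by the mitogenome comparison and
// the allelic-block verification. Scoring is fixed package-wide:
// match +1, mismatch -1, first gap column -2, each further gap column -1
// (a gap of length g costs -(g + 1)).
//
// Tie-break convention (identical in corridor and oracle routines so that
// tracebacks agree whenever the optimal path lies inside the corridor):
// source states are examined in the order M, X, Y and a later candidate
// replaces an earlier one only with a strictly greater score. X consumes a
// residue of `a` against a gap, Y consumes a residue of `b`.

namespace {

const int NEG = -1000000000;
const int S_MATCH = 1;
const int S_MISMATCH = -1;
const int G_OPEN = -2; // first gap column
const int G_EXT = -1;  // subsequent gap columns

// column codes in the traceback output
const int COL_MATCH = 0;
const int COL_MISMATCH = 1;
const int COL_GAP = 2;

} // namespace

// Corridor-band global affine alignment. lo/hi (length m+1) give inclusive
// column bounds for each row i = 0..m; bounds must be non-decreasing and
// contain (0,0) and (m,n). Returns score and per-column codes, or
// feasible = FALSE when no path fits inside the corridor.
// [[Rcpp::export]]
List nw_corridor_cpp(std::string a, std::string b,
                     IntegerVector lo_, IntegerVector hi_) {
  const int m = (int)a.size(), n = (int)b.size();
  if ((int)lo_.size() != m + 1 || (int)hi_.size() != m + 1)
    stop("corridor bounds must have length m + 1");
  std::vector<int> lo(m + 1), hi(m + 1);
  for (int i = 0; i <= m; ++i) {
    lo[i] = lo_[i];
    hi[i] = hi_[i];
    if (lo[i] < 0 || hi[i] > n || lo[i] > hi[i]) stop("invalid corridor bounds");
  }
  if (lo[0] != 0 || hi[m] != n) stop("corridor must contain both alignment corners");

  std::vector<long long> off(m + 1);
  long long total = 0;
  for (int i = 0; i <= m; ++i) {
    off[i] = total;
    total += hi[i] - lo[i] + 1;
  }
  std::vector<int> M(total, NEG), X(total, NEG), Y(total, NEG);
  std::vector<unsigned char> tM(total, 0), tX(total, 0), tY(total, 0);

  for (int i = 0; i <= m; ++i) {
    const bool prev_ok = i > 0;
    for (int j = lo[i]; j <= hi[i]; ++j) {
      const long long c = off[i] + (j - lo[i]);
      if (i == 0 && j == 0) {
        M[c] = 0;
        continue;
      }
      if (prev_ok && j > 0 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        const long long p = off[i - 1] + (j - 1 - lo[i - 1]);
        int best = M[p];
        unsigned char src = 0;
        if (X[p] > best) { best = X[p]; src = 1; }
        if (Y[p] > best) { best = Y[p]; src = 2; }
        if (best > NEG / 2) {
          M[c] = best + (a[i - 1] == b[j - 1] ? S_MATCH : S_MISMATCH);
          tM[c] = src;
        }
      }
      if (prev_ok && j >= lo[i - 1] && j <= hi[i - 1]) {
        const long long p = off[i - 1] + (j - lo[i - 1]);
        int best = NEG;
        unsigned char src = 0;
        if (M[p] > NEG / 2 && M[p] + G_OPEN > best) { best = M[p] + G_OPEN; src = 0; }
        if (X[p] > NEG / 2 && X[p] + G_EXT > best) { best = X[p] + G_EXT; src = 1; }
        if (Y[p] > NEG / 2 && Y[p] + G_OPEN > best) { best = Y[p] + G_OPEN; src = 2; }
        if (best > NEG / 2) { X[c] = best; tX[c] = src; }
      }
      if (j > lo[i]) {
        const long long p = c - 1;
        int best = NEG;
        unsigned char src = 0;
        if (M[p] > NEG / 2 && M[p] + G_OPEN > best) { best = M[p] + G_OPEN; src = 0; }
        if (X[p] > NEG / 2 && X[p] + G_OPEN > best) { best = X[p] + G_OPEN; src = 1; }
        if (Y[p] > NEG / 2 && Y[p] + G_EXT > best) { best = Y[p] + G_EXT; src = 2; }
        if (best > NEG / 2) { Y[c] = best; tY[c] = src; }
      }
    }
  }

  const long long e = off[m] + (n - lo[m]);
  int state = 0, score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  if (score < NEG / 2)
    return List::create(_["feasible"] = false);

  std::vector<int> cols;
  cols.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const long long c = off[i] + (j - lo[i]);
    if (state == 0) {
      cols.push_back(a[i - 1] == b[j - 1] ? COL_MATCH : COL_MISMATCH);
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      cols.push_back(COL_GAP);
      state = tX[c];
      --i;
    } else {
      cols.push_back(COL_GAP);
      state = tY[c];
      --j;
    }
  }
  std::reverse(cols.begin(), cols.end());
  return List::create(_["feasible"] = true, _["score"] = score,
                      _["columns"] = IntegerVector(cols.begin(), cols.end()));
}

// Reference implementation: naive unrestricted affine global DP over full
// rectangular matrices. Written independently of nw_corridor_cpp (shared
// constants only); serves as the in-package oracle for the corridor path.
// [[Rcpp::export]]
List nw_full_oracle_cpp(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  const long long w = (long long)(n + 1);
  std::vector<int> M((m + 1) * w, NEG), X((m + 1) * w, NEG), Y((m + 1) * w, NEG);
  std::vector<unsigned char> tM((m + 1) * w), tX((m + 1) * w), tY((m + 1) * w);
  M[0] = 0;
  for (int i = 0; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      if (i == 0 && j == 0) continue;
      const long long c = i * w + j;
      if (i > 0 && j > 0) {
        const long long p = (i - 1) * w + (j - 1);
        int best = M[p];
        unsigned char src = 0;
        if (X[p] > best) { best = X[p]; src = 1; }
        if (Y[p] > best) { best = Y[p]; src = 2; }
        if (best > NEG / 2) {
          M[c] = best + (a[i - 1] == b[j - 1] ? S_MATCH : S_MISMATCH);
          tM[c] = src;
        }
      }
      if (i > 0) {
        const long long p = (i - 1) * w + j;
        int best = NEG;
        unsigned char src = 0;
        if (M[p] > NEG / 2 && M[p] + G_OPEN > best) { best = M[p] + G_OPEN; src = 0; }
        if (X[p] > NEG / 2 && X[p] + G_EXT > best) { best = X[p] + G_EXT; src = 1; }
        if (Y[p] > NEG / 2 && Y[p] + G_OPEN > best) { best = Y[p] + G_OPEN; src = 2; }
        if (best > NEG / 2) { X[c] = best; tX[c] = src; }
      }
      if (j > 0) {
        const long long p = i * w + (j - 1);
        int best = NEG;
        unsigned char src = 0;
        if (M[p] > NEG / 2 && M[p] + G_OPEN > best) { best = M[p] + G_OPEN; src = 0; }
        if (X[p] > NEG / 2 && X[p] + G_OPEN > best) { best = X[p] + G_OPEN; src = 1; }
        if (Y[p] > NEG / 2 && Y[p] + G_EXT > best) { best = Y[p] + G_EXT; src = 2; }
        if (best > NEG / 2) { Y[c] = best; tY[c] = src; }
      }
    }
  }
  const long long e = (long long)m * w + n;
  int state = 0, score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  std::vector<int> cols;
  cols.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const long long c = (long long)i * w + j;
    if (state == 0) {
      cols.push_back(a[i - 1] == b[j - 1] ? COL_MATCH : COL_MISMATCH);
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      cols.push_back(COL_GAP);
      state = tX[c];
      --i;
    } else {
      cols.push_back(COL_GAP);
      state = tY[c];
      --j;
    }
  }
  std::reverse(cols.begin(), cols.end());
  return List::create(_["feasible"] = true, _["score"] = score,
                      _["columns"] = IntegerVector(cols.begin(), cols.end()));
}

// Booth's algorithm: 0-based index of the lexicographically least rotation.
// [[Rcpp::export]]
int min_rotation_cpp(std::string s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  std::string d = s + s;
  std::vector<int> f(2 * n, -1);
  int k = 0;
  for (int j = 1; j < 2 * n; ++j) {
    const char sj = d[j];
    int i = f[j - k - 1];
    while (i != -1 && sj != d[k + i + 1]) {
      if (sj < d[k + i + 1]) k = j - i - 1;
      i = f[i];
    }
    if (sj != d[k + i + 1]) {
      if (sj < d[k]) k = j;
      f[j - k] = -1;
    } else {
      f[j - k] = i + 1;
    }
  }
  return k % n;
}

// Longest strictly increasing subsequence; returns 1-based indices of one
// optimal subsequence (patience sorting, deterministic).
// [[Rcpp::export]]
IntegerVector lis_cpp(IntegerVector v) {
  const int n = v.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;       // value at end of best subsequence per length
  std::vector<int> tails_idx;   // index of that value
  std::vector<int> parent(n, -1);
  tails.reserve(n);
  tails_idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    const int x = v[i];
    // first position with tails[pos] >= x
    int loI = 0, hiI = (int)tails.size();
    while (loI < hiI) {
      const int mid = (loI + hiI) / 2;
      if (tails[mid] < x) loI = mid + 1; else hiI = mid;
    }
    if (loI == (int)tails.size()) {
      tails.push_back(x);
      tails_idx.push_back(i);
    } else {
      tails[loI] = x;
      tails_idx[loI] = i;
    }
    parent[i] = loI > 0 ? tails_idx[loI - 1] : -1;
  }
  int len = (int)tails.size();
  std::vector<int> out(len);
  int cur = tails_idx[len - 1];
  for (int p = len - 1; p >= 0; --p) {
    out[p] = cur + 1;
    cur = parent[cur];
  }
  return IntegerVector(out.begin(), out.end());
}
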