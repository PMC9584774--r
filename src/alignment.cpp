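// Edit-distance primitives used throughout the package.
//
// All routines use unit costs (match 0, mismatch/insertion/deletion 1) and
// treat 'N' as matching nothing, including another 'N'.  This matches the
// K-string indexing convention, where windows containing N are skipped.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static const int INF = 1 << 28;

static inline bool base_match(char a, char b) { return a == b && a != 'N'; }

// Banded Levenshtein distance (Ukkonen).  The returned value is exact iff it
// is <= band; callers widen the band until that holds.
static int banded_ed(const std::string &a, const std::string &b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  if (std::abs(n - m) > band) return INF;
  const int width = 2 * band + 1;
  std::vector<int> prev(width, INF), cur(width, INF);
  for (int k = 0; k < width; ++k) { // row i = 0: D[0][j] = j
    int j = k - band;
    prev[k] = (j >= 0 && j <= n) ? j : INF;
  }
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i + band;
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        if (prev[k] != INF)
          best = prev[k] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
        if (k + 1 < width && prev[k + 1] != INF)
          best = std::min(best, prev[k + 1] + 1); // delete a[i-1]
        if (k - 1 >= 0 && cur[k - 1] != INF)
          best = std::min(best, cur[k - 1] + 1); // insert b[j-1]
      }
      cur[k] = best;
    }
    std::swap(prev, cur);
  }
  const int k = n - m + band;
  return (k >= 0 && k < width) ? prev[k] : INF;
}

static int edit_distance_impl(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  const int maxb = std::max(m, n);
  int band = std::max(16, std::abs(n - m) + 1);
  for (;;) {
    int d = banded_ed(a, b, band);
    if (d <= band || band >= maxb) return d;
    band = std::min(band * 2, maxb);
  }
}

//' @noRd
// [[Rcpp::export]]
int edit_distance_cpp(std::string a, std::string b) {
  return edit_distance_impl(a, b);
}

// [[Rcpp::export]]
IntegerMatrix pairwise_edit_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = edit_distance_impl(s[i], s[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Global alignment with traceback, banded around the optimal distance.
// Preference order on ties: diagonal, then deletion (gap in b), then
// insertion (gap in a) -- fixed for determinism.
// [[Rcpp::export]]
List align_global_cpp(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  const int d = edit_distance_impl(a, b);
  int band = std::max(std::max(d + 1, std::abs(n - m) + 1), 8);
  band = std::min(band, std::max(m, n));
  const int width = 2 * band + 1;
  std::vector<int> prev(width, INF), cur(width, INF);
  std::vector<unsigned char> tb((size_t)(m + 1) * width, 0); // 1 diag, 2 up, 3 left
  for (int k = 0; k < width; ++k) {
    int j = k - band;
    if (j >= 0 && j <= n) {
      prev[k] = j;
      if (j > 0) tb[k] = 3;
    }
  }
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i + band;
      int best = INF;
      unsigned char move = 0;
      if (j == 0) {
        best = i;
        move = 2;
      } else {
        if (prev[k] != INF) {
          best = prev[k] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
          move = 1;
        }
        if (k + 1 < width && prev[k + 1] != INF && prev[k + 1] + 1 < best) {
          best = prev[k + 1] + 1;
          move = 2;
        }
        if (k - 1 >= 0 && cur[k - 1] != INF && cur[k - 1] + 1 < best) {
          best = cur[k - 1] + 1;
          move = 3;
        }
      }
      cur[k] = best;
      tb[(size_t)i * width + k] = move;
    }
    std::swap(prev, cur);
  }
  std::string ra, rb;
  ra.reserve(m + d);
  rb.reserve(n + d);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char move = tb[(size_t)i * width + (j - i + band)];
    if (move == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i;
      --j;
    } else if (move == 2) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["distance"] = d);
}

// Semi-global (infix) scan: find substrings of `text` aligning to the whole
// `query` with at most `max_edits` edits.  Forward pass computes, for every
// text position j, the best edit distance of query against an infix ending at
// j; candidate ends below the cutoff are kept after non-maximum suppression
// (no two kept ends closer than `suppress`), and a reverse pass per candidate
// recovers the start.  Ties on the end score keep the leftmost end; ties on
// the start keep the shortest infix.
// [[Rcpp::export]]
DataFrame semiglobal_scan_cpp(std::string query, std::string text,
                              int max_edits, double min_len_frac,
                              int suppress) {
  const int m = (int)query.size(), n = (int)text.size();
  std::vector<int> col(m + 1), ncol(m + 1), endscore(n + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;
  endscore[0] = m;
  for (int j = 1; j <= n; ++j) {
    ncol[0] = 0; // free leading text gap
    for (int i = 1; i <= m; ++i) {
      int v = col[i - 1] + (base_match(query[i - 1], text[j - 1]) ? 0 : 1);
      v = std::min(v, col[i] + 1);
      v = std::min(v, ncol[i - 1] + 1);
      ncol[i] = v;
    }
    std::swap(col, ncol);
    endscore[j] = col[m];
  }
  std::vector<int> cand;
  for (int j = 1; j <= n; ++j)
    if (endscore[j] <= max_edits) cand.push_back(j);
  std::sort(cand.begin(), cand.end(), [&](int x, int y) {
    if (endscore[x] != endscore[y]) return endscore[x] < endscore[y];
    return x < y;
  });
  std::vector<int> kept;
  for (int e : cand) {
    bool ok = true;
    for (int k : kept)
      if (std::abs(k - e) < suppress) { ok = false; break; }
    if (ok) kept.push_back(e);
  }
  const std::string rq(query.rbegin(), query.rend());
  std::vector<int> starts, ends, edits;
  for (int e : kept) {
    const int ws = std::max(0, e - m - max_edits - 2);
    const int L = e - ws;
    std::string rt = text.substr(ws, L);
    std::reverse(rt.begin(), rt.end());
    // F[k] = edit distance of full query vs text[(e-k)..e)
    std::vector<int> fcol(m + 1), fn(m + 1);
    for (int i = 0; i <= m; ++i) fcol[i] = i;
    int bestk = 0, bestv = fcol[m];
    for (int k = 1; k <= L; ++k) {
      fn[0] = k;
      for (int i = 1; i <= m; ++i) {
        int v = fcol[i - 1] + (base_match(rq[i - 1], rt[k - 1]) ? 0 : 1);
        v = std::min(v, fcol[i] + 1);
        v = std::min(v, fn[i - 1] + 1);
        fn[i] = v;
      }
      std::swap(fcol, fn);
      if (fcol[m] < bestv) {
        bestv = fcol[m];
        bestk = k;
      }
    }
    if (bestv <= max_edits && bestk >= (int)std::ceil(min_len_frac * m)) {
      starts.push_back(e - bestk); // 0-based
      ends.push_back(e);
      edits.push_back(bestv);
    }
  }
  std::vector<int> ord(starts.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return starts[x] < starts[y]; });
  IntegerVector s(ord.size()), e(ord.size()), d(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    s[i] = starts[ord[i]];
    e[i] = ends[ord[i]];
    d[i] = edits[ord[i]];
  }
  return DataFrame::create(_["start"] = s, _["end"] = e, _["edits"] = d);
}
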