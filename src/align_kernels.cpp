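#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost (Levenshtein) alignment kernels. Divergence between two
// sequences is defined as edit distance divided by the number of alignment
// columns; among cost-optimal alignments we take the one with the fewest
// columns (equivalently, the most matches), which makes the ratio
// deterministic. Cells carry (cost, cols) compared lexicographically.

struct Cell {
  int cost;
  int cols;
};

static inline bool lt(const Cell &a, const Cell &b) {
  return a.cost < b.cost || (a.cost == b.cost && a.cols < b.cols);
}

// Full DP over one pair; returns {edits, columns}.
static Cell edit_pair(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<Cell> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = {j, j};
  for (int i = 1; i <= m; ++i) {
    cur[0] = {i, i};
    for (int j = 1; j <= n; ++j) {
      Cell best = {prev[j - 1].cost + (a[i - 1] == b[j - 1] ? 0 : 1),
                   prev[j - 1].cols + 1};
      Cell up = {prev[j].cost + 1, prev[j].cols + 1};
      Cell left = {cur[j - 1].cost + 1, cur[j - 1].cols + 1};
      if (lt(up, best)) best = up;
      if (lt(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
IntegerMatrix edit_stats_cpp(std::string a, std::vector<std::string> b) {
  IntegerMatrix out(2, (int)b.size());
  for (int k = 0; k < (int)b.size(); ++k) {
    Cell c = edit_pair(a, b[k]);
    out(0, k) = c.cost;
    out(1, k) = c.cols;
  }
  return out;
}

// Banded divergence query: exact divergence when the edit distance is at
// most band k (chosen so that any pair with divergence < threshold stays in
// band); NA when the distance certainly exceeds the band, in which case the
// divergence is guaranteed to be >= threshold.
// k satisfies: ed < t * cols and cols <= max(la, lb) + ed  =>  ed < t*max/(1-t).
// [[Rcpp::export]]
NumericVector bounded_divergence_cpp(std::string a, std::vector<std::string> b,
                                     double threshold) {
  const int m = (int)a.size();
  NumericVector out((int)b.size());
  for (int q = 0; q < (int)b.size(); ++q) {
    const std::string &s = b[q];
    const int n = (int)s.size();
    int mx = m > n ? m : n;
    int k = (int)std::floor(threshold * mx / (1.0 - threshold)) + 1;
    if (std::abs(m - n) > k) {
      out[q] = NA_REAL;
      continue;
    }
    const Cell INF = {INT_MAX / 2, INT_MAX / 2};
    std::vector<Cell> prev(n + 1, INF), cur(n + 1, INF);
    for (int j = 0; j <= std::min(n, k); ++j) prev[j] = {j, j};
    for (int i = 1; i <= m; ++i) {
      int lo = std::max(1, i - k), hi = std::min(n, i + k);
      std::fill(cur.begin(), cur.end(), INF);
      if (i <= k) cur[0] = {i, i};
      for (int j = lo; j <= hi; ++j) {
        Cell best = INF;
        if (prev[j - 1].cost < INF.cost) {
          best = {prev[j - 1].cost + (a[i - 1] == s[j - 1] ? 0 : 1),
                  prev[j - 1].cols + 1};
        }
        if (prev[j].cost < INF.cost) {
          Cell up = {prev[j].cost + 1, prev[j].cols + 1};
          if (lt(up, best)) best = up;
        }
        if (cur[j - 1].cost < INF.cost) {
          Cell left = {cur[j - 1].cost + 1, cur[j - 1].cols + 1};
          if (lt(left, best)) best = left;
        }
        cur[j] = best;
      }
      std::swap(prev, cur);
    }
    if (prev[n].cost > k) {
      out[q] = NA_REAL;
    } else {
      out[q] = (double)prev[n].cost / (double)prev[n].cols;
    }
  }
  return out;
}

// Fit alignment: the pattern is aligned globally, the window locally (free
// start and end in the window). Used to refine seeded monomer candidates to
// exact boundaries. Start positions propagate through the DP; ties resolve
// to (min cost, min cols, leftmost start, leftmost end).
struct FCell {
  int cost;
  int cols;
  int start; // 0-based offset in window where the alignment begins
};

static inline bool flt(const FCell &a, const FCell &b) {
  if (a.cost != b.cost) return a.cost < b.cost;
  if (a.cols != b.cols) return a.cols < b.cols;
  return a.start < b.start;
}

// [[Rcpp::export]]
List fit_align_cpp(std::string pattern, std::vector<std::string> windows) {
  const int m = (int)pattern.size();
  const int nw = (int)windows.size();
  IntegerVector ed(nw), cols(nw), start(nw), end(nw);
  for (int q = 0; q < nw; ++q) {
    const std::string &w = windows[q];
    const int n = (int)w.size();
    std::vector<FCell> prev(n + 1), cur(n + 1);
    for (int j = 0; j <= n; ++j) prev[j] = {0, 0, j};
    for (int i = 1; i <= m; ++i) {
      cur[0] = {i, i, 0};
      for (int j = 1; j <= n; ++j) {
        FCell best = {prev[j - 1].cost + (pattern[i - 1] == w[j - 1] ? 0 : 1),
                      prev[j - 1].cols + 1, prev[j - 1].start};
        FCell up = {prev[j].cost + 1, prev[j].cols + 1, prev[j].start};
        FCell left = {cur[j - 1].cost + 1, cur[j - 1].cols + 1,
                      cur[j - 1].start};
        if (flt(up, best)) best = up;
        if (flt(left, best)) best = left;
        cur[j] = best;
      }
      std::swap(prev, cur);
    }
    FCell best = prev[0];
    int bj = 0;
    for (int j = 1; j <= n; ++j) {
      if (flt(prev[j], best)) {
        best = prev[j];
        bj = j;
      }
    }
    ed[q] = best.cost;
    cols[q] = best.cols;
    start[q] = best.start;
    end[q] = bj;
  }
  return List::create(_["ed"] = ed, _["cols"] = cols, _["start"] = start,
                      _["end"] = end);
}

// Projects a query sequence onto reference coordinates through a unit-cost
// global alignment (ties: diagonal > up > left, after (cost, cols)).
// Returns one character per reference position: the aligned query base, or
// '-' where the reference position is deleted in the query. Query
// insertions are dropped. Used for column-wise consensus voting.
// [[Rcpp::export]]
CharacterVector align_map_cpp(std::string ref, std::vector<std::string> qrys) {
  const int m = (int)ref.size();
  CharacterVector out((int)qrys.size());
  for (int q = 0; q < (int)qrys.size(); ++q) {
    const std::string &b = qrys[q];
    const int n = (int)b.size();
    // full DP with stored cells for traceback
    std::vector<std::vector<Cell>> dp(m + 1, std::vector<Cell>(n + 1));
    for (int j = 0; j <= n; ++j) dp[0][j] = {j, j};
    for (int i = 1; i <= m; ++i) {
      dp[i][0] = {i, i};
      for (int j = 1; j <= n; ++j) {
        Cell best = {dp[i - 1][j - 1].cost + (ref[i - 1] == b[j - 1] ? 0 : 1),
                     dp[i - 1][j - 1].cols + 1};
        Cell up = {dp[i - 1][j].cost + 1, dp[i - 1][j].cols + 1};
        Cell left = {dp[i][j - 1].cost + 1, dp[i][j - 1].cols + 1};
        if (lt(up, best)) best = up;
        if (lt(left, best)) best = left;
        dp[i][j] = best;
      }
    }
    std::string proj(m, '-');
    int i = m, j = n;
    while (i > 0 || j > 0) {
      const Cell &c = dp[i][j];
      if (i > 0 && j > 0) {
        Cell diag = {dp[i - 1][j - 1].cost + (ref[i - 1] == b[j - 1] ? 0 : 1),
                     dp[i - 1][j - 1].cols + 1};
        if (diag.cost == c.cost && diag.cols == c.cols) {
          proj[i - 1] = b[j - 1];
          --i;
          --j;
          continue;
        }
      }
      if (i > 0) {
        Cell up = {dp[i - 1][j].cost + 1, dp[i - 1][j].cols + 1};
        if (up.cost == c.cost && up.cols == c.cols) {
          --i; // ref position deleted in query
          continue;
        }
      }
      --j; // query insertion, dropped
    }
    out[q] = proj;
  }
  return out;
}
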