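#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Local-cost matrix between the columns of X (d x n) and Y (d x m).
// metric: 0 = euclidean, 1 = manhattan, 2 = sq_euclidean
// [[Rcpp::export]]
NumericMatrix cpp_cost_matrix(const NumericMatrix& X, const NumericMatrix& Y,
                              int metric) {
  const int d = X.nrow(), n = X.ncol(), m = Y.ncol();
  if (Y.nrow() != d) stop("column dimension mismatch");
  NumericMatrix C(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (metric == 1) {
        for (int r = 0; r < d; ++r) acc += std::fabs(X(r, i) - Y(r, j));
      } else {
        for (int r = 0; r < d; ++r) {
          const double diff = X(r, i) - Y(r, j);
          acc += diff * diff;
        }
        if (metric == 0) acc = std::sqrt(acc);
      }
      C(i, j) = acc;
    }
  }
  return C;
}

static inline int cell(int i, int j, int n) { return i + j * n; }

// Exact minimizer of the path-length-normalized cost (1/K) * sum d[w(k)]
// over admissible warping paths (steps (1,1), (1,0), (0,1); endpoint,
// monotonicity and continuity constraints). DP is stratified by the number
// of path points K; ties on the normalized value prefer smaller K, and
// within a stratum ties prefer predecessor diagonal, then (i-1,j), then
// (i,j-1). Returns value, total cost, K and the attaining path (1-based).
// [[Rcpp::export]]
List cpp_dtw_normalized(const NumericMatrix& C) {
  const int n = C.nrow(), m = C.ncol();
  if (n < 1 || m < 1) stop("empty cost matrix");
  const int kmax = n + m - 1;
  const int kmin = std::max(n, m);
  const double INF = std::numeric_limits<double>::infinity();
  const int nm = n * m;

  std::vector<double> prev(nm, INF), cur(nm, INF);
  // pred[(k-1)*nm + cell]: 0 none, 1 diag, 2 up (i-1,j), 3 left (i,j-1)
  std::vector<unsigned char> pred((size_t)kmax * nm, 0);

  prev[cell(0, 0, n)] = C(0, 0);
  double bestVal = INF, bestTot = INF;
  int bestK = -1;
  if (n == 1 && m == 1) { bestVal = C(0, 0); bestTot = C(0, 0); bestK = 1; }

  for (int k = 2; k <= kmax; ++k) {
    std::fill(cur.begin(), cur.end(), INF);
    // reachable at step k: max(i+1, j+1) <= k <= i+j+1 (0-based i, j)
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) {
        if (i + j + 1 < k || std::max(i, j) + 1 > k) continue;
        double best = INF;
        unsigned char p = 0;
        if (i > 0 && j > 0 && prev[cell(i - 1, j - 1, n)] < best) {
          best = prev[cell(i - 1, j - 1, n)]; p = 1;
        }
        if (i > 0 && prev[cell(i - 1, j, n)] < best) {
          best = prev[cell(i - 1, j, n)]; p = 2;
        }
        if (j > 0 && prev[cell(i, j - 1, n)] < best) {
          best = prev[cell(i, j - 1, n)]; p = 3;
        }
        if (p == 0) continue;
        cur[cell(i, j, n)] = best + C(i, j);
        pred[(size_t)(k - 1) * nm + cell(i, j, n)] = p;
      }
    }
    if (k >= kmin) {
      const double tot = cur[cell(n - 1, m - 1, n)];
      if (R_finite(tot)) {
        const double val = tot / k;
        if (val < bestVal - 1e-15 ||
            (std::fabs(val - bestVal) <= 1e-15 && k < bestK)) {
          bestVal = val; bestTot = tot; bestK = k;
        }
      }
    }
    std::swap(prev, cur);
  }
  if (bestK < 0) stop("no admissible path found");

  IntegerVector pi(bestK), pj(bestK);
  int i = n - 1, j = m - 1;
  for (int k = bestK; k >= 1; --k) {
    pi[k - 1] = i + 1; pj[k - 1] = j + 1;
    if (k == 1) break;
    const unsigned char p = pred[(size_t)(k - 1) * nm + cell(i, j, n)];
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else if (p == 3) { --j; }
    else stop("broken predecessor chain");
  }
  return List::create(_["value"] = bestVal, _["total"] = bestTot,
                      _["k"] = bestK, _["i"] = pi, _["j"] = pj);
}

// Classic recursion: minimize the unnormalized sum, then report sum / K for
// the recovered path. Ties on the sum prefer smaller K, then the diagonal.
// [[Rcpp::export]]
List cpp_dtw_sum(const NumericMatrix& C) {
  const int n = C.nrow(), m = C.ncol();
  if (n < 1 || m < 1) stop("empty cost matrix");
  const int nm = n * m;
  std::vector<double> D(nm);
  std::vector<int> K(nm);
  std::vector<unsigned char> pred(nm, 0);
  const double EPS = 1e-12;

  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (i == 0 && j == 0) { D[0] = C(0, 0); K[0] = 1; continue; }
      double best = std::numeric_limits<double>::infinity();
      int bk = 0; unsigned char p = 0;
      if (i > 0 && j > 0) {
        best = D[cell(i - 1, j - 1, n)]; bk = K[cell(i - 1, j - 1, n)]; p = 1;
      }
      if (i > 0) {
        const double c = D[cell(i - 1, j, n)];
        const int kk = K[cell(i - 1, j, n)];
        if (c < best - EPS || (std::fabs(c - best) <= EPS && kk < bk)) {
          best = c; bk = kk; p = 2;
        }
      }
      if (j > 0) {
        const double c = D[cell(i, j - 1, n)];
        const int kk = K[cell(i, j - 1, n)];
        if (c < best - EPS || (std::fabs(c - best) <= EPS && kk < bk)) {
          best = c; bk = kk; p = 3;
        }
      }
      D[cell(i, j, n)] = best + C(i, j);
      K[cell(i, j, n)] = bk + 1;
      pred[cell(i, j, n)] = p;
    }
  }
  const int kPath = K[cell(n - 1, m - 1, n)];
  const double tot = D[cell(n - 1, m - 1, n)];
  IntegerVector pi(kPath), pj(kPath);
  int i = n - 1, j = m - 1;
  for (int k = kPath; k >= 1; --k) {
    pi[k - 1] = i + 1; pj[k - 1] = j + 1;
    if (k == 1) break;
    const unsigned char p = pred[cell(i, j, n)];
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
  }
  return List::create(_["value"] = tot / kPath, _["total"] = tot,
                      _["k"] = kPath, _["i"] = pi, _["j"] = pj);
}
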