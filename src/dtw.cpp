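#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Band admission for unequal lengths: the corridor follows the stretched
// diagonal j = i*(m-1)/(n-1) so the bounding endpoints (0,0) and
// (n-1,m-1) are always admitted. Degenerate single-element sequences admit
// every node (the path is forced anyway).
static inline bool node_admitted(int i, int j, int n, int m, double band) {
  if (band < 0.0)
    return true;
  if (n == 1 || m == 1)
    return true;
  double center = (double)i * (double)(m - 1) / (double)(n - 1);
  return std::fabs(center - (double)j) <= band + 1e-9;
}

// [[Rcpp::export]]
List dtw_cpp(NumericVector x, NumericVector y, double band) {
  int n = x.size(), m = y.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> M((size_t)n * m, INF);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!node_admitted(i, j, n, m, band))
        continue;
      double dx = x[i] - y[j];
      double w = dx * dx;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = INF;
        if (i > 0 && j > 0)
          best = M[(size_t)(i - 1) * m + (j - 1)];
        if (i > 0)
          best = std::min(best, M[(size_t)(i - 1) * m + j]);
        if (j > 0)
          best = std::min(best, M[(size_t)i * m + (j - 1)]);
      }
      if (best < INF)
        M[(size_t)i * m + j] = w + best;
    }
  }

  double cost = M[(size_t)(n - 1) * m + (m - 1)];
  bool feasible = std::isfinite(cost);

  if (!feasible) {
    return List::create(_["feasible"] = false);
  }

  // Backtrace; ties broken deterministically: diagonal, then vertical
  // (i-1, j), then horizontal (i, j-1) predecessor.
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i);
  pj.push_back(j);
  while (i > 0 || j > 0) {
    double d = (i > 0 && j > 0) ? M[(size_t)(i - 1) * m + (j - 1)] : INF;
    double v = (i > 0) ? M[(size_t)(i - 1) * m + j] : INF;
    double h = (j > 0) ? M[(size_t)i * m + (j - 1)] : INF;
    double mn = std::min(d, std::min(v, h));
    if (d == mn) {
      --i;
      --j;
    } else if (v == mn) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i);
    pj.push_back(j);
  }

  int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int l = 0; l < L; ++l) {
    path(l, 0) = pi[L - 1 - l] + 1; // 1-based for R
    path(l, 1) = pj[L - 1 - l] + 1;
  }

  return List::create(_["feasible"] = true, _["cost"] = cost,
                      _["normalized"] = cost / (double)L, _["path"] = path);
}

// [[Rcpp::export]]
bool dtw_band_feasible_cpp(int n, int m, double band) {
  // Reachability on admitted nodes with DTW steps.
  std::vector<char> R((size_t)n * m, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!node_admitted(i, j, n, m, band))
        continue;
      if (i == 0 && j == 0) {
        R[0] = 1;
        continue;
      }
      char r = 0;
      if (i > 0 && j > 0)
        r |= R[(size_t)(i - 1) * m + (j - 1)];
      if (i > 0)
        r |= R[(size_t)(i - 1) * m + j];
      if (j > 0)
        r |= R[(size_t)i * m + (j - 1)];
      R[(size_t)i * m + j] = r;
    }
  }
  return R[(size_t)(n - 1) * m + (m - 1)] != 0;
}
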