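#include <Rcpp.h>
using namespace Rcpp;

// Time-averaged MSD over all ordered pairs (i, i+lag) of a contiguous
// trajectory. Positions in um, one row per frame.
// [[Rcpp::export(name = ".tamsd_contiguous")]]
List tamsd_contiguous(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  NumericVector msd(max_lag);
  IntegerVector npairs(max_lag);
  for (int k = 1; k <= max_lag; ++k) {
    double s = 0.0;
    int m = n - k;
    for (int i = 0; i < m; ++i) {
      double dx = x[i + k] - x[i];
      double dy = y[i + k] - y[i];
      s += dx * dx + dy * dy;
    }
    msd[k - 1] = m > 0 ? s / m : NA_REAL;
    npairs[k - 1] = m > 0 ? m : 0;
  }
  return List::create(_["msd"] = msd, _["n_pairs"] = npairs);
}

// TA-MSD on a frame-indexed grid with NA for missing frames (closed gaps):
// pairs use the true frame difference as their lag.
// [[Rcpp::export(name = ".tamsd_gapped")]]
List tamsd_gapped(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  NumericVector msd(max_lag);
  IntegerVector npairs(max_lag);
  for (int k = 1; k <= max_lag; ++k) {
    double s = 0.0;
    int m = 0;
    for (int i = 0; i + k < n; ++i) {
      if (NumericVector::is_na(x[i]) || NumericVector::is_na(x[i + k])) continue;
      double dx = x[i + k] - x[i];
      double dy = y[i + k] - y[i];
      s += dx * dx + dy * dy;
      ++m;
    }
    msd[k - 1] = m > 0 ? s / m : NA_REAL;
    npairs[k - 1] = m;
  }
  return List::create(_["msd"] = msd, _["n_pairs"] = npairs);
}

// Cumulate Gaussian steps inside a reflecting circular corral of radius R
// centred on the start point. Overshoot beyond the boundary is folded back
// radially (r -> 2R - r); a step overshooting past the centre is rejected
// (particle stays put), which at step sizes << R never happens.
// [[Rcpp::export(name = ".reflect_walk")]]
NumericMatrix reflect_walk(NumericVector step_x, NumericVector step_y, double R) {
  int n = step_x.size() + 1;
  NumericMatrix pos(n, 2);
  double cx = 0.0, cy = 0.0;
  for (int i = 1; i < n; ++i) {
    double xn = cx + step_x[i - 1];
    double yn = cy + step_y[i - 1];
    double r = sqrt(xn * xn + yn * yn);
    if (r > R) {
      double f = (2.0 * R - r) / r;
      if (f >= 0.0) { xn *= f; yn *= f; } else { xn = cx; yn = cy; }
    }
    cx = xn; cy = yn;
    pos(i, 0) = cx; pos(i, 1) = cy;
  }
  return pos;
}

// Hungarian algorithm (Jonker-Volgenant shortest augmenting path, O(n^3))
// for a square cost matrix. Returns, for each row, the assigned column
// (1-based). Large finite costs stand in for forbidden assignments.
// [[Rcpp::export(name = ".solve_assignment")]]
IntegerVector solve_assignment(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) assign[p[j] - 1] = j;
  return assign;
}
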