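#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dense O(n^2 m) shortest-augmenting-path assignment (Jonker-Volkgenant style
// potentials). Requires nrow <= ncol; returns the 1-based column assigned to
// each row, minimizing total cost.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  int n = cost.nrow(), m = cost.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("hungarian_cpp needs nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---- grid-binned exact planar neighbor searches ----------------------------

struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int> > bins;
  Grid(const NumericVector& x, const NumericVector& y, double cell_) {
    int n = x.size();
    x0 = Rcpp::min(x); y0 = Rcpp::min(y);
    double x1 = Rcpp::max(x), y1 = Rcpp::max(y);
    cell = cell_ > 0 ? cell_ : 1.0;
    nx = std::max(1, (int)std::floor((x1 - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / cell) + 1);
    if ((double)nx * ny > 4e6) {  // cap memory; enlarge cells
      double f = std::sqrt((double)nx * ny / 4e6);
      cell *= f;
      nx = std::max(1, (int)std::floor((x1 - x0) / cell) + 1);
      ny = std::max(1, (int)std::floor((y1 - y0) / cell) + 1);
    }
    bins.assign((size_t)nx * ny, std::vector<int>());
    for (int i = 0; i < n; ++i) bins[idx(x[i], y[i])].push_back(i);
  }
  size_t idx(double px, double py) const {
    int ix = (int)std::floor((px - x0) / cell), iy = (int)std::floor((py - y0) / cell);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    return (size_t)iy * nx + ix;
  }
};

// count of points within distance r of each point, excluding the point itself
// [[Rcpp::export]]
IntegerVector count_within_cpp(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  IntegerVector out(n);
  Grid g(x, y, r);
  double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    int cix = (int)std::floor((x[i] - g.x0) / g.cell);
    int ciy = (int)std::floor((y[i] - g.y0) / g.cell);
    int c = 0;
    for (int iy = std::max(0, ciy - 1); iy <= std::min(g.ny - 1, ciy + 1); ++iy)
      for (int ix = std::max(0, cix - 1); ix <= std::min(g.nx - 1, cix + 1); ++ix) {
        const std::vector<int>& b = g.bins[(size_t)iy * g.nx + ix];
        for (size_t q = 0; q < b.size(); ++q) {
          int j = b[q];
          if (j == i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= r2) ++c;
        }
      }
    out[i] = c;
  }
  return out;
}

// nearest-neighbor distance from each query point to the point set; a query may
// optionally exclude one point index (1-based; 0 = none), used when queries are
// themselves members of the set.
// [[Rcpp::export]]
NumericVector nn_query_cpp(NumericVector qx, NumericVector qy,
                           NumericVector x, NumericVector y,
                           IntegerVector exclude) {
  int nq = qx.size(), n = x.size();
  NumericVector out(nq);
  if (n == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  // heuristic cell size ~ typical spacing
  double x0 = Rcpp::min(x), x1 = Rcpp::max(x), y0 = Rcpp::min(y), y1 = Rcpp::max(y);
  double span = std::max(x1 - x0, y1 - y0);
  double cell = (span > 0 && n > 1) ? span / std::sqrt((double)n) : 1.0;
  Grid g(x, y, cell);
  for (int i = 0; i < nq; ++i) {
    int excl = exclude.size() == nq ? exclude[i] - 1 : -1;
    int cix = (int)std::floor((qx[i] - g.x0) / g.cell);
    int ciy = (int)std::floor((qy[i] - g.y0) / g.cell);
    double best = R_PosInf;
    for (int ring = 0; ; ++ring) {
      bool any_cell = false;
      for (int iy = ciy - ring; iy <= ciy + ring; ++iy) {
        if (iy < 0 || iy >= g.ny) continue;
        for (int ix = cix - ring; ix <= cix + ring; ++ix) {
          if (ix < 0 || ix >= g.nx) continue;
          if (ring > 0 && std::abs(iy - ciy) != ring && std::abs(ix - cix) != ring)
            continue;  // only the new ring
          any_cell = true;
          const std::vector<int>& b = g.bins[(size_t)iy * g.nx + ix];
          for (size_t q = 0; q < b.size(); ++q) {
            int j = b[q];
            if (j == excl) continue;
            double dx = qx[i] - x[j], dy = qy[i] - y[j];
            double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
          }
        }
      }
      // stop when the found neighbor is provably nearer than any unexplored ring
      if (best < R_PosInf && std::sqrt(best) <= ring * g.cell) break;
      if (!any_cell && ring > g.nx + g.ny) break;
      if (ring > g.nx + g.ny) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
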