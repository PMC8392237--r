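#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// two-pass 1-D lower-envelope algorithm on squared distances.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in cell units) from every cell to the nearest TRUE cell of
// `target`. Cells on targets get 0. Returns +Inf if no target exists.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix target) {
  const int nr = target.nrow(), nc = target.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix g(nr, nc);
  // the lower-envelope recursion requires finite inputs; use a sentinel far
  // above any attainable squared distance
  const double BIG = 1e18;
  // column pass
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = target(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // row pass
  std::vector<double> fr(nc), dr(nc);
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = g(i, j);
    dt1d(fr, dr, nc);
    for (int j = 0; j < nc; ++j)
      out(i, j) = (dr[j] >= BIG) ? INF : std::sqrt(dr[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (BFS), 4- or 8-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nnb = (connectivity == 8) ? 8 : 4;
  const int* drp = (connectivity == 8) ? dr8 : dr4;
  const int* dcp = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int i = idx % nr, j = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ii = i + drp[k], jj = j + dcp[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra on the 8-neighbor raster graph.
// Edge cost between adjacent cells i,j: (r_i + r_j)/2 * cell_size * (sqrt(2)
// for diagonal moves). NA resistance blocks a cell.
// ---------------------------------------------------------------------------

struct QNode {
  double d;
  int idx;
  bool operator>(const QNode& o) const { return d > o.d; }
};

// Returns list(dist = matrix of cost-weighted distances (NA where blocked or
// unreachable), parent = integer matrix of 1-based linear predecessor index,
// 0 at sources / unreached). If `stop_mask` is given and `early_stop` is
// TRUE, the search halts once the cheapest stop cell is finalized, and
// `stop_cost`/`stop_idx` report it (dist is then only partially filled).
// [[Rcpp::export]]
List cpp_dijkstra(NumericMatrix resistance, LogicalMatrix source,
                  double cell_size,
                  Nullable<LogicalMatrix> stop_mask = R_NilValue,
                  bool early_stop = false) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int n = nr * nc;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<int> parent(n, 0);
  std::vector<char> done(n, 0);
  LogicalMatrix stop(nr, nc);
  bool has_stop = false;
  if (stop_mask.isNotNull()) {
    stop = LogicalMatrix(stop_mask);
    has_stop = true;
  }
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double SQRT2 = std::sqrt(2.0);

  std::priority_queue<QNode, std::vector<QNode>, std::greater<QNode> > pq;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (source(i, j) && !NumericMatrix::is_na(resistance(i, j))) {
        int idx = i + j * nr;
        dist[idx] = 0.0;
        pq.push({0.0, idx});
      }

  double stop_cost = NA_REAL;
  int stop_idx = NA_INTEGER;
  while (!pq.empty()) {
    QNode top = pq.top();
    pq.pop();
    if (done[top.idx]) continue;
    done[top.idx] = 1;
    int i = top.idx % nr, j = top.idx / nr;
    if (has_stop && stop(i, j)) {
      if (NumericVector::is_na(stop_cost)) {
        stop_cost = top.d;
        stop_idx = top.idx + 1;
      }
      if (early_stop) break;
    }
    double ri = resistance(i, j);
    for (int k = 0; k < 8; ++k) {
      int ii = i + dr8[k], jj = j + dc8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      double rj = resistance(ii, jj);
      if (NumericMatrix::is_na(rj)) continue;
      double step = (k == 0 || k == 2 || k == 5 || k == 7) ? SQRT2 : 1.0;
      double w = 0.5 * (ri + rj) * cell_size * step;
      int idx2 = ii + jj * nr;
      double nd = top.d + w;
      if (nd < dist[idx2]) {
        dist[idx2] = nd;
        parent[idx2] = top.idx + 1;
        pq.push({nd, idx2});
      }
    }
  }

  NumericMatrix dmat(nr, nc);
  IntegerMatrix pmat(nr, nc);
  for (int idx = 0; idx < n; ++idx) {
    dmat[idx] = std::isinf(dist[idx]) ? NA_REAL : dist[idx];
    pmat[idx] = parent[idx];
  }
  return List::create(_["dist"] = dmat, _["parent"] = pmat,
                      _["stop_cost"] = stop_cost, _["stop_idx"] = stop_idx);
}

// Least-cost cost between a source mask and a target mask (early-stopped
// Dijkstra); NA if unreachable.
// [[Rcpp::export]]
double cpp_lcp_cost(NumericMatrix resistance, LogicalMatrix source,
                    LogicalMatrix target, double cell_size) {
  List res = cpp_dijkstra(resistance, source, cell_size, wrap(target), true);
  return as<double>(res["stop_cost"]);
}

// ---------------------------------------------------------------------------
// Moving-window barrier scan: for each candidate center and each radius,
// set the circular window's resistance to `restore_value`, recompute the
// least-cost cost between the two patches, and score the improvement
// IS = (cost_before - cost_after) / (2 * radius).
// Returns per-center best IS and the radius (m) achieving it.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_barrier_scan(NumericMatrix resistance, LogicalMatrix source,
                      LogicalMatrix target, double cell_size,
                      IntegerVector centers, NumericVector radii,
                      double restore_value, double cost_before) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int ncand = centers.size();
  NumericVector best_is(ncand, 0.0);
  NumericVector best_rad(ncand, NA_REAL);
  NumericMatrix work(nr, nc);

  for (int c = 0; c < ncand; ++c) {
    int idx = centers[c] - 1;  // 1-based in
    int ci = idx % nr, cj = idx / nr;
    for (int rstep = 0; rstep < radii.size(); ++rstep) {
      double rad = radii[rstep];
      int rc = (int)std::floor(rad / cell_size);
      // copy resistance and restore the window
      std::copy(resistance.begin(), resistance.end(), work.begin());
      bool touched = false;
      for (int dj = -rc; dj <= rc; ++dj) {
        int jj = cj + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -rc; di <= rc; ++di) {
          int ii = ci + di;
          if (ii < 0 || ii >= nr) continue;
          double dd = (double)di * di + (double)dj * dj;
          if (dd * cell_size * cell_size > rad * rad) continue;
          double cur = work(ii, jj);
          if (!NumericMatrix::is_na(cur) && cur > restore_value) {
            work(ii, jj) = restore_value;
            touched = true;
          }
        }
      }
      if (!touched) continue;
      double after = cpp_lcp_cost(work, source, target, cell_size);
      if (NumericVector::is_na(after)) continue;
      double is = (cost_before - after) / (2.0 * rad);
      if (is > best_is[c]) {
        best_is[c] = is;
        best_rad[c] = rad;
      }
    }
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["is"] = best_is, _["radius"] = best_rad);
}

// Focal range (max - min) over a square window of half-width hw; NA cells are
// skipped; all-NA neighborhoods give NA.
// [[Rcpp::export]]
NumericMatrix cpp_focal_range(NumericMatrix x, int hw) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double mn = R_PosInf, mx = R_NegInf;
      bool any = false;
      for (int dj = -hw; dj <= hw; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -hw; di <= hw; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          double v = x(ii, jj);
          if (NumericMatrix::is_na(v)) continue;
          any = true;
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
      }
      out(i, j) = any ? (mx - mn) : NA_REAL;
    }
  }
  return out;
}
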