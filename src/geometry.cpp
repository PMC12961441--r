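#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// K nearest neighbours by Euclidean distance, self included, brute force.
// Ties broken by lower index; if n < k the lists are padded with the query
// point's own index. Returns an n x k matrix of 1-based indices ordered by
// non-decreasing distance.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    int m = std::min(k, n);
    std::partial_sort(d.begin(), d.begin() + m, d.end());
    for (int s = 0; s < m; ++s) out(i, s) = d[s].second + 1;
    for (int s = m; s < k; ++s) out(i, s) = i + 1;  // pad with self
  }
  return out;
}

// All indices within radius r of each query (self included); used for ball
// queries. Returns a list of integer vectors.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double r) {
  const int n = pts.nrow();
  const double r2 = r * r;
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) nb.push_back(j + 1);
    }
    out[i] = wrap(nb);
  }
  return out;
}

// Greedy furthest-point sampling. Starts at `start` (1-based); each
// subsequent pick maximizes the minimum distance to the selected set, ties
// resolved in favour of the lowest index (which.max semantics).
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix pts, int m, int start) {
  const int n = pts.nrow();
  IntegerVector sel(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  for (int s = 0; s < m; ++s) {
    sel[s] = cur + 1;
    double best = -1.0;
    int besti = 0;
    for (int j = 0; j < n; ++j) {
      double dx = pts(cur, 0) - pts(j, 0);
      double dy = pts(cur, 1) - pts(j, 1);
      double dz = pts(cur, 2) - pts(j, 2);
      double dj = dx * dx + dy * dy + dz * dz;
      if (dj < mind[j]) mind[j] = dj;
      if (mind[j] > best) { best = mind[j]; besti = j; }
    }
    cur = besti;
  }
  return sel;
}

// Textbook DBSCAN on d-dimensional points (d = ncol). Core point: at least
// minPts neighbours within eps (self counted). Cluster ids 1..k in order of
// discovery; noise = -1 (dense-reachable border points join the first core
// cluster that reaches them).
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  const double e2 = eps * eps;
  IntegerVector lab(n);           // 0 = unvisited, -1 = noise, >0 cluster
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> nb;
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) { double u = pts(i, c) - pts(j, c); s += u * u; }
      if (s <= e2) nb.push_back(j);
    }
    if ((int)nb.size() < min_pts) { lab[i] = -1; continue; }
    ++cl;
    lab[i] = cl;
    std::queue<int> q;
    for (size_t t = 0; t < nb.size(); ++t) q.push(nb[t]);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      if (lab[p] == -1) lab[p] = cl;           // border point claimed
      if (lab[p] != 0) continue;
      lab[p] = cl;
      std::vector<int> nb2;
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) { double u = pts(p, c) - pts(j, c); s += u * u; }
        if (s <= e2) nb2.push_back(j);
      }
      if ((int)nb2.size() >= min_pts)
        for (size_t t = 0; t < nb2.size(); ++t) q.push(nb2[t]);
    }
  }
  return lab;
}

// ---- Bowyer-Watson incremental Delaunay triangulation in 2-D ----

struct Tri { int a, b, c; double cx, cy, r2; bool alive; };

static void circum(const std::vector<double>& px, const std::vector<double>& py,
                   Tri& t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double dd = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(dd) < 1e-300) { t.cx = t.cy = 0.0; t.r2 = R_PosInf; return; }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / dd;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / dd;
  double rx = ax - t.cx, ry = ay - t.cy;
  t.r2 = rx * rx + ry * ry;
}

// Returns an nt x 3 matrix of 1-based vertex indices. Collinear input yields
// zero triangles.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  double xmin = *std::min_element(px.begin(), px.end());
  double xmax = *std::max_element(px.begin(), px.end());
  double ymin = *std::min_element(py.begin(), py.end());
  double ymax = *std::max_element(py.begin(), py.end());
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) span = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle well outside the data
  px.push_back(midx - 30.0 * span); py.push_back(midy - span);
  px.push_back(midx + 30.0 * span); py.push_back(midy - span);
  px.push_back(midx);               py.push_back(midy + 30.0 * span);
  std::vector<Tri> tris;
  Tri super; super.a = n; super.b = n + 1; super.c = n + 2; super.alive = true;
  circum(px, py, super);
  tris.push_back(super);

  // insertion in input order; perturbation-free with an epsilon in-circle
  const double eps = 1e-12 * span * span;
  std::vector<std::pair<int,int> > edges;
  for (int ip = 0; ip < n; ++ip) {
    edges.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = px[ip] - tris[t].cx, dy = py[ip] - tris[t].cy;
      if (tris[t].r2 < R_PosInf && dx * dx + dy * dy < tris[t].r2 - eps) {
        tris[t].alive = false;
        edges.push_back(std::make_pair(tris[t].a, tris[t].b));
        edges.push_back(std::make_pair(tris[t].b, tris[t].c));
        edges.push_back(std::make_pair(tris[t].c, tris[t].a));
      }
    }
    // boundary of the cavity = edges appearing exactly once (unordered)
    for (size_t e = 0; e < edges.size(); ++e) {
      bool dup = false;
      for (size_t f = 0; f < edges.size(); ++f) {
        if (e == f) continue;
        if ((edges[e].first == edges[f].second && edges[e].second == edges[f].first) ||
            (edges[e].first == edges[f].first && edges[e].second == edges[f].second)) {
          dup = true; break;
        }
      }
      if (dup) continue;
      Tri t; t.a = edges[e].first; t.b = edges[e].second; t.c = ip; t.alive = true;
      // skip zero-area triangles (duplicate / collinear points)
      double area2 = (px[t.b] - px[t.a]) * (py[t.c] - py[t.a]) -
                     (px[t.c] - px[t.a]) * (py[t.b] - py[t.a]);
      if (std::fabs(area2) < 1e-14 * span * span) continue;
      circum(px, py, t);
      tris.push_back(t);
    }
  }
  std::vector<int> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back((int)t);
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t t = 0; t < keep.size(); ++t) {
    out(t, 0) = tris[keep[t]].a + 1;
    out(t, 1) = tris[keep[t]].b + 1;
    out(t, 2) = tris[keep[t]].c + 1;
  }
  return out;
}
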