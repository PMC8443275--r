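#include <Rcpp.h>
#include <map>
#include <vector>
#include <utility>
using namespace Rcpp;

// Signed double area of triangle abc (>0 when counter-clockwise).
static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// In-circumcircle predicate for a CCW triangle abc; strict interior test.
static inline bool in_circle(double ax, double ay, double bx, double by,
                             double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd - bd * cdy)
                   - ady * (bdx * cd - bd * cdx)
                   + ad  * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

struct Tri { int a, b, c; bool alive; };

// Bowyer-Watson incremental Delaunay triangulation.
// pts: n x 2 coordinates. Returns an m x 3 matrix of 1-based vertex
// indices. Caller guarantees n >= 3 and no duplicate points; collinear
// input yields zero triangles.
// [[Rcpp::export]]
IntegerMatrix delaunay_bw(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> x(n + 3), y(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0);
    y[i] = pts(i, 1);
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0) span = 1.0;
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  // Super-triangle far outside the data so its circumcircles dwarf any
  // real-point margin at double precision.
  const double M = 1e3 * span;
  x[n]     = cx - 3.0 * M; y[n]     = cy - M;
  x[n + 1] = cx + 3.0 * M; y[n + 1] = cy - M;
  x[n + 2] = cx;           y[n + 2] = cy + 3.0 * M;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  std::map<std::pair<int, int>, std::pair<int, int> > edges; // sorted -> directed

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &tr = tris[t];
      if (in_circle(x[tr.a], y[tr.a], x[tr.b], y[tr.b],
                    x[tr.c], y[tr.c], x[p], y[p]))
        bad.push_back(t);
    }
    edges.clear();
    for (int k = 0; k < (int)bad.size(); ++k) {
      const Tri &tr = tris[bad[k]];
      const int e[3][2] = {{tr.a, tr.b}, {tr.b, tr.c}, {tr.c, tr.a}};
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v)
                                        : std::make_pair(v, u);
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
            edges.find(key);
        if (it == edges.end())
          edges[key] = std::make_pair(u, v);
        else
          it->second = std::make_pair(-1, -1); // interior edge, shared twice
      }
      tris[bad[k]].alive = false;
    }
    for (std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
             edges.begin(); it != edges.end(); ++it) {
      const int u = it->second.first, v = it->second.second;
      if (u < 0) continue; // not a cavity boundary edge
      Tri nt;
      if (orient2d(x[u], y[u], x[v], y[v], x[p], y[p]) > 0.0)
        nt = {u, v, p, true};
      else
        nt = {v, u, p, true};
      tris.push_back(nt);
    }
  }

  int m = 0;
  for (int t = 0; t < (int)tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n)
      ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (int t = 0; t < (int)tris.size(); ++t) {
    const Tri &tr = tris[t];
    if (!tr.alive || tr.a >= n || tr.b >= n || tr.c >= n) continue;
    out(r, 0) = tr.a + 1;
    out(r, 1) = tr.b + 1;
    out(r, 2) = tr.c + 1;
    ++r;
  }
  return out;
}
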