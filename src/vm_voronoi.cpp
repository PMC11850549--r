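#include "vm.h"
#include <algorithm>

using namespace Rcpp;

// Voronoi tiles by half-plane clipping with mirrored seed padding: seeds
// within `cutoff` of a wall are reflected across it (and across corners), so
// the bisector between a seed and its mirror image lies exactly on the wall.
// This yields straight clamped boundaries and tiles that exactly partition
// the box. A uniform grid accelerates the neighbour search; clipping stops
// once the next candidate is provably irrelevant (distance > 2 * max vertex
// distance from the seed).

namespace {

struct Gen { double x, y; };

struct Grid {
  double x0, y0, h;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  Grid(const std::vector<Gen> &g, double cell) {
    x0 = y0 = 1e300;
    double x1 = -1e300, y1 = -1e300;
    for (auto &p : g) {
      x0 = std::min(x0, p.x); x1 = std::max(x1, p.x);
      y0 = std::min(y0, p.y); y1 = std::max(y1, p.y);
    }
    h = cell;
    nx = std::max(1, (int)std::ceil((x1 - x0) / h) + 1);
    ny = std::max(1, (int)std::ceil((y1 - y0) / h) + 1);
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < (int)g.size(); ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)((g[i].x - x0) / h)));
      int iy = std::min(ny - 1, std::max(0, (int)((g[i].y - y0) / h)));
      bins[(size_t)iy * nx + ix].push_back(i);
    }
  }
  // generator indices within `ring` bins of the bin containing p
  void collectRing(double px, double py, int ring, std::vector<int> &out) const {
    int ix = std::min(nx - 1, std::max(0, (int)((px - x0) / h)));
    int iy = std::min(ny - 1, std::max(0, (int)((py - y0) / h)));
    for (int dy = -ring; dy <= ring; ++dy) {
      for (int dx = -ring; dx <= ring; ++dx) {
        if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
        int jx = ix + dx, jy = iy + dy;
        if (jx < 0 || jy < 0 || jx >= nx || jy >= ny) continue;
        for (int i : bins[(size_t)jy * nx + jx]) out.push_back(i);
      }
    }
  }
};

void clipHalfPlane(std::vector<double> &px, std::vector<double> &py,
                   double ax, double ay, double bx, double by) {
  // keep {r : (r - a) . (b - a) <= |b - a|^2 / 2}, the side of seed a
  double dx = bx - ax, dy = by - ay;
  double c = 0.5 * (dx * dx + dy * dy);
  size_t n = px.size();
  if (n == 0) return;
  std::vector<double> qx, qy;
  qx.reserve(n + 4); qy.reserve(n + 4);
  std::vector<double> s(n);
  for (size_t i = 0; i < n; ++i)
    s[i] = (px[i] - ax) * dx + (py[i] - ay) * dy - c;
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    bool in_i = s[i] <= 0, in_j = s[j] <= 0;
    if (in_i) { qx.push_back(px[i]); qy.push_back(py[i]); }
    if (in_i != in_j) {
      double t = s[i] / (s[i] - s[j]);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
    }
  }
  px.swap(qx); py.swap(qy);
}

std::vector<Gen> withMirrors(const std::vector<Gen> &pts, double L, double cutoff) {
  std::vector<Gen> all(pts);
  for (auto &p : pts) {
    bool w = p.x < cutoff, e = p.x > L - cutoff;
    bool s = p.y < cutoff, n = p.y > L - cutoff;
    if (w) all.push_back({-p.x, p.y});
    if (e) all.push_back({2 * L - p.x, p.y});
    if (s) all.push_back({p.x, -p.y});
    if (n) all.push_back({p.x, 2 * L - p.y});
    if (w && s) all.push_back({-p.x, -p.y});
    if (w && n) all.push_back({-p.x, 2 * L - p.y});
    if (e && s) all.push_back({2 * L - p.x, -p.y});
    if (e && n) all.push_back({2 * L - p.x, 2 * L - p.y});
  }
  return all;
}

// Voronoi tile of generator i within the mirrored configuration
void voronoiTile(int i, const std::vector<Gen> &all, const Grid &grid,
                 double L, std::vector<double> &px, std::vector<double> &py) {
  double cxp = all[i].x, cyp = all[i].y;
  double W = 1.5 * L + 1.0;     // generous starting square: contains any tile
  px = {cxp - W, cxp + W, cxp + W, cxp - W};
  py = {cyp - W, cyp - W, cyp + W, cyp + W};

  std::vector<int> cand;
  std::vector<std::pair<double, int>> byDist;
  int maxRing = std::max(grid.nx, grid.ny) + 1;
  for (int ring = 0; ring <= maxRing; ++ring) {
    cand.clear();
    grid.collectRing(cxp, cyp, ring, cand);
    byDist.clear();
    for (int j : cand) {
      if (j == i) continue;
      byDist.push_back({std::hypot(all[j].x - cxp, all[j].y - cyp), j});
    }
    std::sort(byDist.begin(), byDist.end());
    double maxd2 = 0.0;
    for (size_t k = 0; k < px.size(); ++k)
      maxd2 = std::max(maxd2, std::hypot(px[k] - cxp, py[k] - cyp));
    for (auto &dj : byDist) {
      if (dj.first > 2.0 * maxd2) break;
      clipHalfPlane(px, py, cxp, cyp, all[dj.second].x, all[dj.second].y);
      maxd2 = 0.0;
      for (size_t k = 0; k < px.size(); ++k)
        maxd2 = std::max(maxd2, std::hypot(px[k] - cxp, py[k] - cyp));
    }
    // done once the nearest unseen ring is provably beyond reach
    double ringDist = (ring - 1) * grid.h;   // lower bound to ring+1 bins
    if (ring >= 2 && ringDist > 2.0 * maxd2) break;
  }

  // Clip to the box. For seeds within the mirror cutoff this is a no-op
  // (the bisector with the mirrored seed IS the wall, exactly); it bounds
  // tiles of deep-interior seeds in sparse configurations.
  if (cxp > 1e-12) clipHalfPlane(px, py, cxp, cyp, -cxp, cyp);
  if (L - cxp > 1e-12) clipHalfPlane(px, py, cxp, cyp, 2 * L - cxp, cyp);
  if (cyp > 1e-12) clipHalfPlane(px, py, cxp, cyp, cxp, -cyp);
  if (L - cyp > 1e-12) clipHalfPlane(px, py, cxp, cyp, cxp, 2 * L - cyp);
}

} // namespace

// [[Rcpp::export]]
List cpp_lloyd(NumericVector x, NumericVector y, double L, double tol,
               double cutoff, int maxit) {
  int n = x.size();
  std::vector<Gen> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {x[i], y[i]};
  double gridh = std::max(cutoff, 2.0 * L / std::sqrt((double)std::max(1, n)));
  double resid = NA_REAL;
  int it = 0;
  bool conv = false;
  std::vector<double> px, py;
  for (it = 1; it <= maxit; ++it) {
    std::vector<Gen> all = withMirrors(pts, L, cutoff);
    Grid grid(all, gridh);
    double maxdisp = 0.0;
    std::vector<Gen> next(n);
    for (int i = 0; i < n; ++i) {
      voronoiTile(i, all, grid, L, px, py);
      if (px.size() < 3) stop("Lloyd iteration produced an empty tile");
      double a = polyArea(px, py);
      double gx = 0.0, gy = 0.0;
      size_t m = px.size();
      for (size_t k = 0; k < m; ++k) {
        size_t j = (k + 1) % m;
        double cr = px[k] * py[j] - px[j] * py[k];
        gx += (px[k] + px[j]) * cr;
        gy += (py[k] + py[j]) * cr;
      }
      gx /= 6.0 * a; gy /= 6.0 * a;
      gx = std::min(L, std::max(0.0, gx));
      gy = std::min(L, std::max(0.0, gy));
      maxdisp = std::max(maxdisp, std::hypot(gx - pts[i].x, gy - pts[i].y));
      next[i] = {gx, gy};
    }
    pts = next;
    resid = maxdisp / L;
    if (resid < tol) { conv = true; break; }
  }
  NumericVector ox(n), oy(n);
  for (int i = 0; i < n; ++i) { ox[i] = pts[i].x; oy[i] = pts[i].y; }
  return List::create(_["x"] = ox, _["y"] = oy, _["iterations"] = it,
                      _["residual"] = resid, _["converged"] = conv);
}

// [[Rcpp::export]]
List cpp_voronoi_polys(NumericVector x, NumericVector y, double L, double cutoff) {
  int n = x.size();
  std::vector<Gen> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {x[i], y[i]};
  std::vector<Gen> all = withMirrors(pts, L, cutoff);
  double gridh = std::max(cutoff, 2.0 * L / std::sqrt((double)std::max(1, n)));
  Grid grid(all, gridh);
  List out(n);
  std::vector<double> px, py;
  for (int i = 0; i < n; ++i) {
    voronoiTile(i, all, grid, L, px, py);
    NumericMatrix m(px.size(), 2);
    for (size_t k = 0; k < px.size(); ++k) { m(k, 0) = px[k]; m(k, 1) = py[k]; }
    out[i] = m;
  }
  return out;
}
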