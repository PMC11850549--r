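#include "vm.h"
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

// ------------------------------------------------------------------- T1 move
//
// Junction h: a -> b with twin t. Cells: c1 = left of h, c2 = left of t.
// Flanking cells cA (third cell at a) and cB (third cell at b) gain the
// junction; c1 and c2 lose it. The junction is rotated 90 degrees
// counterclockwise about its midpoint and extended to length lnew. Both
// endpoints must be 3-valent and unclamped, both incident cells interior
// with > 3 vertices, and all four participating cells distinct.
bool t1Impl(Tissue &T, int h, double lnew, std::string *why) {
  auto fail = [&](const char *m) { if (why) *why = m; return false; };
  if (h < 0 || h >= T.nH() || !T.halive[h]) return fail("junction not alive");
  int t = T.ht[h];
  int c1 = T.hc[h], c2 = T.hc[t];
  if (c1 < 0 || c2 < 0) return fail("boundary junction");
  int a = T.ho[h], b = T.ho[t];
  if (T.vclamp[a] || T.vclamp[b]) return fail("clamped endpoint");
  if (T.vertexDegree(a) != 3 || T.vertexDegree(b) != 3)
    return fail("endpoint not 3-valent");
  if (T.cellSize(c1) <= 3 || T.cellSize(c2) <= 3)
    return fail("incident cell would drop below 3 vertices");

  int p1 = T.hp[h], n1 = T.hn[h];
  int p2 = T.hp[t], n2 = T.hn[t];
  int ta = T.ht[p1];    // origin a, third cell at a
  int tb = T.ht[p2];    // origin b, third cell at b
  int tn1 = T.ht[n1];   // ends at b, in cB
  int tn2 = T.ht[n2];   // ends at a, in cA
  int cA = T.hc[ta], cB = T.hc[tb];
  if (cA < 0 || cB < 0) return fail("flanking face is the boundary");
  if (cA == cB || cA == c1 || cA == c2 || cB == c1 || cB == c2)
    return fail("participating cells not distinct");

  // geometry: rotate about the midpoint, c1 keeps vertex a on its side
  double mx = 0.5 * (T.vx[a] + T.vx[b]), my = 0.5 * (T.vy[a] + T.vy[b]);
  double dx = T.vx[b] - T.vx[a], dy = T.vy[b] - T.vy[a];
  double len = std::hypot(dx, dy);
  double ux, uy;
  if (len < 1e-14) { ux = 1.0; uy = 0.0; } else { ux = -dy / len; uy = dx / len; }
  T.vx[a] = mx + 0.5 * lnew * ux; T.vy[a] = my + 0.5 * lnew * uy;
  T.vx[b] = mx - 0.5 * lnew * ux; T.vy[b] = my - 0.5 * lnew * uy;

  // connectivity surgery
  T.ho[n1] = a;
  T.ho[n2] = b;
  T.hn[p1] = n1; T.hp[n1] = p1;
  T.hn[p2] = n2; T.hp[n2] = p2;
  T.hc[h] = cB; T.hp[h] = tn1; T.hn[h] = tb; T.hn[tn1] = h; T.hp[tb] = h;
  T.hc[t] = cA; T.hp[t] = tn2; T.hn[t] = ta; T.hn[tn2] = t; T.hp[ta] = t;
  T.che[c1] = n1;
  T.che[c2] = n2;
  if (why) *why = "";
  return true;
}

// ------------------------------------------------- T2 / ingression collapse
//
// Replace the whole cell by a single vertex at its centroid. Rejected when
// the cell touches a clamped vertex, a neighbouring cell would drop below
// 3 vertices, or a neighbour is shared across more than one junction.
bool collapseImpl(Tissue &T, int c, int *newVertex, std::string *why) {
  auto fail = [&](const char *m) { if (why) *why = m; return false; };
  if (c < 0 || c >= T.nC() || !T.calive[c]) return fail("cell not alive");
  std::vector<int> hes = T.cellHalfedges(c);
  int n = (int)hes.size();
  std::vector<int> verts(n), nbr(n);
  for (int i = 0; i < n; ++i) {
    verts[i] = T.ho[hes[i]];
    if (T.vclamp[verts[i]]) return fail("cell touches a clamped vertex");
    nbr[i] = T.hc[T.ht[hes[i]]];
    if (nbr[i] < 0) return fail("cell touches the boundary");
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (nbr[i] == nbr[j]) return fail("neighbour shared across two junctions");
  for (int i = 0; i < n; ++i)
    if (T.cellSize(nbr[i]) < 4)
      return fail("neighbour would drop below 3 vertices");

  // area centroid of the collapsing cell
  double A = 0.0, gx = 0.0, gy = 0.0;
  for (int i = 0; i < n; ++i) {
    int u = verts[i], v = verts[(i + 1) % n];
    double cr = T.vx[u] * T.vy[v] - T.vx[v] * T.vy[u];
    A += 0.5 * cr;
    gx += (T.vx[u] + T.vx[v]) * cr;
    gy += (T.vy[u] + T.vy[v]) * cr;
  }
  gx /= 6.0 * A; gy /= 6.0 * A;
  int w = T.addVertex(gx, gy, false);

  std::unordered_set<int> vset(verts.begin(), verts.end());
  std::unordered_set<int> eset;
  for (int h : hes) { eset.insert(h); eset.insert(T.ht[h]); }

  // re-origin all surviving spokes onto the new vertex
  for (int e = 0; e < T.nH(); ++e) {
    if (!T.halive[e] || eset.count(e)) continue;
    if (vset.count(T.ho[e])) T.ho[e] = w;
  }
  // unlink the twin of each cell edge from its neighbour's cycle
  for (int h : hes) {
    int ti = T.ht[h], Ni = T.hc[ti];
    int a = T.hp[ti], b = T.hn[ti];
    T.hn[a] = b; T.hp[b] = a;
    if (T.che[Ni] == ti) T.che[Ni] = b;
    T.killHalfedge(h);
    T.killHalfedge(ti);
  }
  for (int v : verts) T.killVertex(v);
  T.killCell(c);
  if (newVertex) *newVertex = w;
  if (why) *why = "";
  return true;
}

// --------------------------------------------- high-coordination resolution
//
// Split a vertex of coordination k >= 4 by picking a random admissible cut:
// two distinct incident faces, each side keeping >= 2 spokes. A new junction
// of length lnew is inserted. Repeats until every produced vertex is
// 3-valent; an n-valent vertex takes exactly n - 3 splits.
int resolveVertexImpl(Tissue &T, int v, double lnew, std::vector<EventRec> *ev) {
  int splits = 0;
  std::vector<int> stack = {v};
  while (!stack.empty()) {
    int vv = stack.back(); stack.pop_back();
    int e0 = T.findOutEdge(vv);
    if (e0 < 0) continue;
    std::vector<int> ring = T.vertexOutEdges(vv, e0);
    int k = (int)ring.size();
    if (k <= 3) continue;

    // admissible cuts: gap pair (i, j), side sizes >= 2, distinct faces
    std::vector<std::pair<int, int>> cuts;
    for (int i = 0; i < k; ++i) {
      for (int j = i + 1; j < k; ++j) {
        int s = j - i;
        if (s < 2 || k - s < 2) continue;
        int F1 = T.hc[ring[(i + 1) % k]], F2 = T.hc[ring[(j + 1) % k]];
        if (F1 < 0 || F2 < 0 || F1 == F2) continue;
        cuts.push_back({i, j});
      }
    }
    if (cuts.empty())
      stop("vertex resolution: no admissible cut at vertex %d", vv + 1);
    int pick = (int)std::floor(unif_rand() * cuts.size());
    if (pick >= (int)cuts.size()) pick = (int)cuts.size() - 1;
    int i = cuts[pick].first, j = cuts[pick].second;
    int F1 = T.hc[ring[(i + 1) % k]], F2 = T.hc[ring[(j + 1) % k]];

    // new vertex offset towards the mean direction of the moved spokes
    double sx = 0.0, sy = 0.0;
    for (int m = i + 1; m <= j; ++m) {
      int e = ring[m % k];
      int head = T.ho[T.ht[e]];
      double dx = T.vx[head] - T.vx[vv], dy = T.vy[head] - T.vy[vv];
      double dn = std::hypot(dx, dy);
      if (dn > 1e-14) { sx += dx / dn; sy += dy / dn; }
    }
    double sn = std::hypot(sx, sy);
    if (sn < 1e-14) {
      int head = T.ho[T.ht[ring[(i + 1) % k]]];
      sx = T.vx[head] - T.vx[vv]; sy = T.vy[head] - T.vy[vv];
      sn = std::hypot(sx, sy);
      if (sn < 1e-14) { sx = 1.0; sy = 0.0; sn = 1.0; }
    }
    int w = T.addVertex(T.vx[vv] + lnew * sx / sn, T.vy[vv] + lnew * sy / sn, false);

    for (int m = i + 1; m <= j; ++m) T.ho[ring[m % k]] = w;
    int ei = ring[i], ej = ring[j % k];
    int a = T.addHalfedge(vv, F1);   // v -> w in F1
    int b = T.addHalfedge(w, F2);    // w -> v in F2
    T.ht[a] = b; T.ht[b] = a;
    int ein = T.ht[ei], ejn = T.ht[ej];
    T.hp[a] = ein; T.hn[a] = ring[(i + 1) % k];
    T.hn[ein] = a; T.hp[ring[(i + 1) % k]] = a;
    T.hp[b] = ejn; T.hn[b] = ring[(j + 1) % k];
    T.hn[ejn] = b; T.hp[ring[(j + 1) % k]] = b;

    ++splits;
    if (ev) {
      EventRec r; r.time = T.time; r.kind = 3; r.junction = a;
      ev->push_back(r);
    }
    // re-examine both endpoints
    if (k - (j - i) + 1 > 3) stack.push_back(vv);
    if ((j - i) + 1 > 3) stack.push_back(w);
  }
  return splits;
}

// ------------------------------------------------------------ division edge
namespace {
// split half-edge h (u -> v) and its twin at the given point; returns the new
// vertex. The half of h nearest u keeps id h, so callers' references into the
// cycle before the split point stay valid.
int splitEdgeAt(Tissue &T, int h, double x, double y) {
  int tw = T.ht[h];
  int u = T.ho[h], v = T.ho[tw];
  bool clamp = T.vclamp[u] && T.vclamp[v];
  int w = T.addVertex(x, y, clamp);
  int h2 = T.addHalfedge(w, T.hc[h]);
  int t2 = T.addHalfedge(w, T.hc[tw]);
  T.hn[h2] = T.hn[h]; T.hp[T.hn[h]] = h2; T.hn[h] = h2; T.hp[h2] = h;
  T.hn[t2] = T.hn[tw]; T.hp[T.hn[tw]] = t2; T.hn[tw] = t2; T.hp[t2] = tw;
  T.ht[h] = t2; T.ht[t2] = h;
  T.ht[h2] = tw; T.ht[tw] = h2;
  return w;
}
} // namespace

// Divide cell c along the line through its centroid perpendicular to the
// unit vector (ax, ay). Daughters get generation + 1 and inherit the
// parent's kind and targets (callers re-draw targets as needed).
bool divideImpl(Tissue &T, int c, double ax, double ay, double tol,
                int *d1, int *d2, std::string *why) {
  auto fail = [&](const char *m) { if (why) *why = m; return false; };
  if (c < 0 || c >= T.nC() || !T.calive[c]) return fail("cell not alive");
  std::vector<int> hes = T.cellHalfedges(c);
  int n = (int)hes.size();

  // centroid
  double A = 0.0, gx = 0.0, gy = 0.0;
  for (int i = 0; i < n; ++i) {
    int u = T.ho[hes[i]], v = T.ho[hes[(i + 1) % n]];
    double cr = T.vx[u] * T.vy[v] - T.vx[v] * T.vy[u];
    A += 0.5 * cr; gx += (T.vx[u] + T.vx[v]) * cr; gy += (T.vy[u] + T.vy[v]) * cr;
  }
  if (A <= 0) return fail("non-positive area");
  gx /= 6.0 * A; gy /= 6.0 * A;

  // cut line through centroid, direction perpendicular to the long axis
  double dxl = -ay, dyl = ax;
  // signed distance of each vertex from the cut line
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) {
    int u = T.ho[hes[i]];
    s[i] = dxl * (T.vy[u] - gy) - dyl * (T.vx[u] - gx);
    if (std::fabs(s[i]) < tol) s[i] = 0.0;   // on-line: reuse the vertex
  }
  // crossing sites walking the cycle: vertex sites (s == 0) or edge sites
  struct Site { int idx; bool atVertex; double t; };
  std::vector<Site> sites;
  for (int i = 0; i < n; ++i) {
    if (s[i] == 0.0) sites.push_back({i, true, 0.0});
    int j = (i + 1) % n;
    if (s[i] * s[j] < 0.0)
      sites.push_back({i, false, s[i] / (s[i] - s[j])});
  }
  if ((int)sites.size() != 2) return fail("cut line does not cross exactly twice");
  // vertices strictly between the sites along each arc
  auto arcCount = [&](const Site &p, const Site &q) {
    int first = p.atVertex ? (p.idx + 1) % n : (p.idx + 1) % n;
    int cnt = 0;
    for (int i = first; ; i = (i + 1) % n) {
      if (q.atVertex && i == q.idx) break;
      if (!q.atVertex && i == (q.idx + 1) % n) break;
      ++cnt;
      if (cnt > n) return -1;
    }
    return cnt;
  };
  int m1 = arcCount(sites[0], sites[1]);
  int m2 = arcCount(sites[1], sites[0]);
  if (m1 < 1 || m2 < 1) return fail("a daughter would have fewer than 3 vertices");

  // site vertices (split edges where needed)
  int w[2];
  for (int k = 1; k >= 0; --k) {  // split the later site first: earlier hes stay valid
    const Site &st = sites[k];
    if (st.atVertex) {
      w[k] = T.ho[hes[st.idx]];
    } else {
      int h = hes[st.idx];
      int u = T.ho[h], v = T.ho[T.ht[h]];
      double x = T.vx[u] + st.t * (T.vx[v] - T.vx[u]);
      double y = T.vy[u] + st.t * (T.vy[v] - T.vy[u]);
      w[k] = splitEdgeAt(T, h, x, y);
    }
  }
  if (w[0] == w[1]) return fail("degenerate cut through a single vertex");

  // cell-c half-edges ending at each site vertex
  auto incoming = [&](int vtx) {
    int h0 = T.che[c], h = h0;
    do {
      if (T.ho[T.hn[h]] == vtx) return h;
      h = T.hn[h];
    } while (h != h0);
    return -1;
  };
  int e1 = incoming(w[0]), e2 = incoming(w[1]);
  if (e1 < 0 || e2 < 0) return fail("internal error: site vertex not on cell");
  int f1 = T.hn[e1], f2 = T.hn[e2];

  int d12 = T.addHalfedge(w[0], -2), d21 = T.addHalfedge(w[1], -2);
  T.ht[d12] = d21; T.ht[d21] = d12;
  T.hn[e1] = d12; T.hp[d12] = e1; T.hn[d12] = f2; T.hp[f2] = d12;
  T.hn[e2] = d21; T.hp[d21] = e2; T.hn[d21] = f1; T.hp[f1] = d21;

  int cA = T.addCell(T.ckind[c], T.cA0[c], T.cP0[c], T.cgen[c] + 1);
  int cB = T.addCell(T.ckind[c], T.cA0[c], T.cP0[c], T.cgen[c] + 1);
  T.che[cA] = d12; T.che[cB] = d21;
  int h = d12;
  do { T.hc[h] = cA; h = T.hn[h]; } while (h != d12);
  h = d21;
  do { T.hc[h] = cB; h = T.hn[h]; } while (h != d21);
  T.killCell(c);
  if (d1) *d1 = cA;
  if (d2) *d2 = cB;
  if (why) *why = "";
  return true;
}

// -------------------------------------------------------- type conversion
//
// A cell whose neighbours are all of the opposite type flips type. Flips are
// determined simultaneously, then applied in ascending cell id order (one
// target draw per passive -> active flip).
void convertEncircledImpl(Tissue &T, const Params &P, std::vector<EventRec> *ev) {
  std::vector<int> flips;
  for (int c = 0; c < T.nC(); ++c) {
    if (!T.calive[c]) continue;
    std::vector<int> nb = T.cellNeighbours(c);
    if (nb.empty() || (int)nb.size() < T.cellSize(c)) continue; // touches boundary
    bool all = true;
    for (int q : nb) if (T.ckind[q] == T.ckind[c]) { all = false; break; }
    if (all) flips.push_back(c);
  }
  for (int c : flips) {
    if (T.ckind[c] == 1) {          // passive -> active: draw fresh targets
      double p0 = -1.0;
      do { p0 = R::rnorm(P.mu, P.sigma); } while (p0 <= 0.0);
      T.ckind[c] = 0;
      T.cP0[c] = p0;
      T.cA0[c] = (p0 / P.p0a) * (p0 / P.p0a);
    } else {                        // active -> passive: fixed targets
      T.ckind[c] = 1;
      T.cP0[c] = P.P0p;
      T.cA0[c] = (P.P0p / P.p0p) * (P.P0p / P.p0p);
    }
    if (ev) {
      EventRec r; r.time = T.time; r.kind = 4; r.cell = c;
      ev->push_back(r);
    }
  }
}

// ------------------------------------------------------------- R wrappers

// [[Rcpp::export]]
List cpp_t1(List mesh, int junction, double lnew) {
  Tissue T = tissueFromList(mesh);
  std::string why;
  bool ok = t1Impl(T, junction - 1, lnew, &why);
  return List::create(_["mesh"] = tissueToList(T), _["ok"] = ok, _["why"] = why);
}

// [[Rcpp::export]]
List cpp_collapse(List mesh, int cell) {
  Tissue T = tissueFromList(mesh);
  std::string why;
  int w = -1;
  bool ok = collapseImpl(T, cell - 1, &w, &why);
  return List::create(_["mesh"] = tissueToList(T), _["ok"] = ok,
                      _["why"] = why, _["newVertex"] = w + 1);
}

// [[Rcpp::export]]
List cpp_resolve(List mesh, int vertex, double lnew) {
  Tissue T = tissueFromList(mesh);
  int splits = resolveVertexImpl(T, vertex - 1, lnew, nullptr);
  return List::create(_["mesh"] = tissueToList(T), _["splits"] = splits);
}

// [[Rcpp::export]]
List cpp_divide(List mesh, int cell, double ax, double ay, double tol) {
  Tissue T = tissueFromList(mesh);
  std::string why;
  int d1 = -1, d2 = -1;
  bool ok = divideImpl(T, cell - 1, ax, ay, tol, &d1, &d2, &why);
  return List::create(_["mesh"] = tissueToList(T), _["ok"] = ok,
                      _["why"] = why, _["daughters"] =
                        IntegerVector::create(d1 + 1, d2 + 1));
}

// [[Rcpp::export]]
List cpp_convert_encircled(List mesh, List params) {
  Tissue T = tissueFromList(mesh);
  Params P = paramsFromList(params);
  std::vector<EventRec> ev;
  convertEncircledImpl(T, P, &ev);
  IntegerVector cells(ev.size());
  for (size_t i = 0; i < ev.size(); ++i) cells[i] = ev[i].cell + 1;
  return List::create(_["mesh"] = tissueToList(T), _["cells"] = cells);
}

// Gyration-tensor long axis: principal eigenvector of the second-moment
// tensor of vertex positions about their mean. A degenerate spectrum
// (relative gap < 1e-9) yields a uniformly random direction (one RNG draw).
void longAxisOf(Tissue &T, int c, double *ax, double *ay, bool *degen) {
  std::vector<int> hes = T.cellHalfedges(c);
  int n = (int)hes.size();
  double mx = 0.0, my = 0.0;
  for (int h : hes) { mx += T.vx[T.ho[h]]; my += T.vy[T.ho[h]]; }
  mx /= n; my /= n;
  double gxx = 0.0, gxy = 0.0, gyy = 0.0;
  for (int h : hes) {
    double dx = T.vx[T.ho[h]] - mx, dy = T.vy[T.ho[h]] - my;
    gxx += dx * dx; gxy += dx * dy; gyy += dy * dy;
  }
  gxx /= n; gxy /= n; gyy /= n;
  double tr = gxx + gyy;
  double disc = std::sqrt((gxx - gyy) * (gxx - gyy) + 4.0 * gxy * gxy);
  double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  if (l1 <= 0.0 || (l1 - l2) / l1 < 1e-9) {
    double th = 2.0 * M_PI * unif_rand();
    *ax = std::cos(th); *ay = std::sin(th);
    *degen = true;
    return;
  }
  *degen = false;
  double ex, ey;
  if (std::fabs(gxy) > 1e-300) { ex = gxy; ey = l1 - gxx; }
  else if (gxx >= gyy) { ex = 1.0; ey = 0.0; }
  else { ex = 0.0; ey = 1.0; }
  double en = std::hypot(ex, ey);
  *ax = ex / en; *ay = ey / en;
}

// [[Rcpp::export]]
List cpp_long_axes(List mesh) {
  Tissue T = tissueFromList(mesh);
  int nc = T.nC();
  NumericMatrix axes(nc, 2);
  LogicalVector degen(nc);
  std::fill(axes.begin(), axes.end(), NA_REAL);
  for (int c = 0; c < nc; ++c) {
    if (!T.calive[c]) { degen[c] = NA_LOGICAL; continue; }
    double ax, ay; bool dg;
    longAxisOf(T, c, &ax, &ay, &dg);
    axes(c, 0) = ax; axes(c, 1) = ay;
    degen[c] = dg;
  }
  return List::create(_["axis"] = axes, _["degenerate"] = degen);
}
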