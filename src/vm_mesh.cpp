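#include "vm.h"
#include <unordered_map>
#include <sstream>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- list I/O

Tissue tissueFromList(const List &m) {
  Tissue T;
  NumericVector vx = m["vx"], vy = m["vy"];
  LogicalVector vc = m["vclamped"], va = m["valive"];
  IntegerVector ho = m["h_origin"], ht = m["h_twin"], hn = m["h_next"],
                hp = m["h_prev"], hc = m["h_cell"];
  LogicalVector ha = m["h_alive"];
  IntegerVector ck = m["c_kind"], cg = m["c_gen"], ce = m["c_he"];
  NumericVector ca0 = m["c_A0"], cp0 = m["c_P0"];
  LogicalVector cal = m["c_alive"];

  int nv = vx.size(), nh = ho.size(), nc = ck.size();
  T.vx.assign(vx.begin(), vx.end());
  T.vy.assign(vy.begin(), vy.end());
  T.vclamp.resize(nv); T.valive.resize(nv);
  for (int i = 0; i < nv; ++i) { T.vclamp[i] = vc[i]; T.valive[i] = va[i]; }
  T.ho.resize(nh); T.ht.resize(nh); T.hn.resize(nh); T.hp.resize(nh);
  T.hc.resize(nh); T.halive.resize(nh);
  for (int i = 0; i < nh; ++i) {
    T.ho[i] = ho[i] - 1; T.ht[i] = ht[i] - 1; T.hn[i] = hn[i] - 1;
    T.hp[i] = hp[i] - 1; T.hc[i] = hc[i] - 1;  // R cell 0 (outer) -> -1
    T.halive[i] = ha[i];
  }
  T.ckind.resize(nc); T.cgen.resize(nc); T.che.resize(nc);
  T.cA0.assign(ca0.begin(), ca0.end());
  T.cP0.assign(cp0.begin(), cp0.end());
  T.calive.resize(nc);
  for (int i = 0; i < nc; ++i) {
    T.ckind[i] = ck[i]; T.cgen[i] = cg[i]; T.che[i] = ce[i] - 1;
    T.calive[i] = cal[i];
  }
  T.L = as<double>(m["L"]);
  T.La = as<double>(m["La"]);
  T.time = as<double>(m["time"]);
  return T;
}

List tissueToList(const Tissue &T) {
  int nv = T.nV(), nh = T.nH(), nc = T.nC();
  NumericVector vx(nv), vy(nv);
  LogicalVector vc(nv), va(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = T.vx[i]; vy[i] = T.vy[i]; vc[i] = T.vclamp[i]; va[i] = T.valive[i];
  }
  IntegerVector ho(nh), ht(nh), hn(nh), hp(nh), hc(nh);
  LogicalVector ha(nh);
  for (int i = 0; i < nh; ++i) {
    ho[i] = T.ho[i] + 1; ht[i] = T.ht[i] + 1; hn[i] = T.hn[i] + 1;
    hp[i] = T.hp[i] + 1; hc[i] = T.hc[i] + 1; ha[i] = T.halive[i];
  }
  IntegerVector ck(nc), cg(nc), ce(nc);
  NumericVector ca0(nc), cp0(nc);
  LogicalVector cal(nc);
  for (int i = 0; i < nc; ++i) {
    ck[i] = T.ckind[i]; cg[i] = T.cgen[i]; ce[i] = T.che[i] + 1;
    ca0[i] = T.cA0[i]; cp0[i] = T.cP0[i]; cal[i] = T.calive[i];
  }
  return List::create(
    _["vx"] = vx, _["vy"] = vy, _["vclamped"] = vc, _["valive"] = va,
    _["h_origin"] = ho, _["h_twin"] = ht, _["h_next"] = hn, _["h_prev"] = hp,
    _["h_cell"] = hc, _["h_alive"] = ha,
    _["c_kind"] = ck, _["c_A0"] = ca0, _["c_P0"] = cp0, _["c_gen"] = cg,
    _["c_alive"] = cal, _["c_he"] = ce,
    _["L"] = T.L, _["La"] = T.La, _["time"] = T.time);
}

Params paramsFromList(const List &p) {
  Params P;
  P.KA = as<double>(p["KA"]);      P.KP = as<double>(p["KP"]);
  P.zeta = as<double>(p["zeta"]);  P.g = as<double>(p["g"]);
  P.alpha = as<double>(p["alpha"]); P.beta = as<double>(p["beta"]);
  P.Ad = as<double>(p["Ad"]);      P.Ai = as<double>(p["Ai"]);
  P.lT1 = as<double>(p["lT1"]);    P.dt = as<double>(p["dt"]);
  P.p0a = as<double>(p["p0a"]);    P.p0p = as<double>(p["p0p"]);
  P.mu = as<double>(p["mu"]);      P.sigma = as<double>(p["sigma"]);
  P.P0p = as<double>(p["P0p"]);
  P.eventInterval = as<int>(p["eventInterval"]);
  P.recordInterval = as<int>(p["recordInterval"]);
  return P;
}

// ------------------------------------------------------------- basic counts

int Tissue::nAliveVertices() const {
  int n = 0; for (auto a : valive) n += a; return n;
}
int Tissue::nAliveCells() const {
  int n = 0; for (auto a : calive) n += a; return n;
}
int Tissue::nAliveHalfedges() const {
  int n = 0; for (auto a : halive) n += a; return n;
}

void Tissue::computeGeometry() {
  int nc = nC();
  area.assign(nc, 0.0); perim.assign(nc, 0.0);
  cx.assign(nc, 0.0); cy.assign(nc, 0.0);
  for (int h = 0; h < nH(); ++h) {
    if (!halive[h] || hc[h] < 0) continue;
    int c = hc[h], u = ho[h], v = ho[hn[h]];
    double cross = vx[u] * vy[v] - vx[v] * vy[u];
    area[c] += 0.5 * cross;
    { double _dx = vx[v] - vx[u], _dy = vy[v] - vy[u]; perim[c] += std::sqrt(_dx * _dx + _dy * _dy); }
    cx[c] += (vx[u] + vx[v]) * cross;
    cy[c] += (vy[u] + vy[v]) * cross;
  }
  for (int c = 0; c < nc; ++c) {
    if (calive[c] && area[c] != 0.0) {
      cx[c] /= 6.0 * area[c];
      cy[c] /= 6.0 * area[c];
    }
  }
}

int Tissue::cellSize(int c) const {
  int h0 = che[c], h = h0, n = 0;
  do { ++n; h = hn[h]; } while (h != h0 && n < nH() + 1);
  return n;
}

std::vector<int> Tissue::cellHalfedges(int c) const {
  std::vector<int> out;
  int h0 = che[c], h = h0;
  do { out.push_back(h); h = hn[h]; } while (h != h0 && (int)out.size() <= nH());
  return out;
}

std::vector<int> Tissue::cellNeighbours(int c) const {
  std::vector<int> out;
  for (int h : cellHalfedges(c)) {
    int n = hc[ht[h]];
    if (n < 0) continue;
    bool seen = false;
    for (int q : out) if (q == n) { seen = true; break; }
    if (!seen) out.push_back(n);
  }
  return out;
}

int Tissue::findOutEdge(int v) const {
  for (int h = 0; h < nH(); ++h)
    if (halive[h] && ho[h] == v) return h;
  return -1;
}

std::vector<int> Tissue::vertexOutEdges(int v, int start) const {
  std::vector<int> ring;
  int e = start;
  do {
    ring.push_back(e);
    e = hn[ht[e]];               // next outgoing half-edge around v
  } while (e != start && (int)ring.size() <= nH());
  return ring;
}

int Tissue::vertexDegree(int v) const {
  int e = findOutEdge(v);
  if (e < 0) return 0;
  return (int)vertexOutEdges(v, e).size();
}

int Tissue::addVertex(double x, double y, bool clamped) {
  vx.push_back(x); vy.push_back(y);
  vclamp.push_back(clamped ? 1 : 0); valive.push_back(1);
  return nV() - 1;
}
int Tissue::addHalfedge(int origin, int cell) {
  ho.push_back(origin); ht.push_back(-1); hn.push_back(-1); hp.push_back(-1);
  hc.push_back(cell); halive.push_back(1);
  return nH() - 1;
}
int Tissue::addCell(int kind, double A0, double P0, int gen) {
  ckind.push_back(kind); cA0.push_back(A0); cP0.push_back(P0);
  cgen.push_back(gen); calive.push_back(1); che.push_back(-1);
  return nC() - 1;
}

// --------------------------------------------------- build mesh from polygons

// Vertices are merged by proximity (radius mergeTol) using a spatial hash, so
// tiles clipped independently share exact vertex ids along common edges.
// Coordinates within snapTol of the box walls are snapped exactly onto them.
// [[Rcpp::export]]
List cpp_build_mesh(List polys, double L, double La, bool snapWalls,
                    double mergeTol = 1e-8) {
  Tissue T;
  T.L = L; T.La = La; T.time = 0.0;
  const double q = 4.0 * mergeTol;   // hash bucket size
  std::unordered_map<long long, std::vector<int>> buckets;
  auto key = [&](long long ix, long long iy) { return ix * 2000003LL + iy; };

  auto getVertex = [&](double x, double y) {
    if (snapWalls) {
      if (std::fabs(x) < 1e-7) x = 0.0;
      if (std::fabs(x - L) < 1e-7) x = L;
      if (std::fabs(y) < 1e-7) y = 0.0;
      if (std::fabs(y - L) < 1e-7) y = L;
    }
    long long ix = (long long)std::floor(x / q), iy = (long long)std::floor(y / q);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = buckets.find(key(ix + dx, iy + dy));
        if (it == buckets.end()) continue;
        for (int id : it->second)
          if (std::hypot(T.vx[id] - x, T.vy[id] - y) <= mergeTol) return id;
      }
    int id = T.addVertex(x, y, false);
    buckets[key(ix, iy)].push_back(id);
    return id;
  };

  // directed edge -> half-edge id, for twin matching
  std::unordered_map<long long, int> edgeMap;
  auto ekey = [](int u, int v) { return (long long)u * 10000019LL + v; };

  int np = polys.size();
  for (int p = 0; p < np; ++p) {
    NumericMatrix poly = polys[p];
    int n = poly.nrow();
    std::vector<double> px(n), py(n);
    for (int i = 0; i < n; ++i) { px[i] = poly(i, 0); py[i] = poly(i, 1); }
    if (polyArea(px, py) < 0) {            // enforce counterclockwise winding
      std::reverse(px.begin(), px.end());
      std::reverse(py.begin(), py.end());
    }
    std::vector<int> ids;
    for (int i = 0; i < n; ++i) {
      int id = getVertex(px[i], py[i]);
      if (ids.empty() || ids.back() != id) ids.push_back(id);
    }
    while (ids.size() > 1 && ids.front() == ids.back()) ids.pop_back();
    if ((int)ids.size() < 3) stop("degenerate polygon %d after vertex merging", p + 1);

    int c = T.addCell(1, 0.0, 0.0, 0);
    int m = (int)ids.size();
    std::vector<int> hes(m);
    for (int i = 0; i < m; ++i) hes[i] = T.addHalfedge(ids[i], c);
    for (int i = 0; i < m; ++i) {
      int j = (i + 1) % m;
      T.hn[hes[i]] = hes[j];
      T.hp[hes[j]] = hes[i];
      long long k = ekey(ids[i], ids[j]);
      if (edgeMap.count(k)) stop("duplicate directed edge in polygon input");
      edgeMap[k] = hes[i];
    }
    T.che[c] = hes[0];
  }

  // twin matching; unmatched edges get outer-face (-1) twins
  std::vector<int> outer;
  for (auto &kv : edgeMap) {
    int h = kv.second;
    int u = T.ho[h], v = T.ho[T.hn[h]];
    auto it = edgeMap.find(ekey(v, u));
    if (it != edgeMap.end()) {
      T.ht[h] = it->second;
    } else {
      int o = T.addHalfedge(v, -1);
      T.ht[h] = o; T.ht[o] = h;
      outer.push_back(o);
    }
  }
  // link outer cycle: next of outer half-edge starts at its head
  std::unordered_map<int, int> outerByOrigin;
  for (int o : outer) outerByOrigin[T.ho[o]] = o;
  for (int o : outer) {
    int head = T.ho[T.ht[o]];  // = origin of twin
    auto it = outerByOrigin.find(head);
    if (it == outerByOrigin.end()) stop("open boundary: outer cycle broken");
    T.hn[o] = it->second;
    T.hp[it->second] = o;
  }
  return tissueToList(T);
}

// ------------------------------------------------------------------ queries

// [[Rcpp::export]]
List cpp_cell_geometry(List mesh) {
  Tissue T = tissueFromList(mesh);
  T.computeGeometry();
  int nc = T.nC();
  NumericVector a(nc), p(nc), x(nc), y(nc);
  for (int c = 0; c < nc; ++c) {
    if (T.calive[c]) { a[c] = T.area[c]; p[c] = T.perim[c]; x[c] = T.cx[c]; y[c] = T.cy[c]; }
    else { a[c] = NA_REAL; p[c] = NA_REAL; x[c] = NA_REAL; y[c] = NA_REAL; }
  }
  return List::create(_["area"] = a, _["perimeter"] = p,
                      _["cx"] = x, _["cy"] = y);
}

// [[Rcpp::export]]
IntegerVector cpp_neighbour_counts(List mesh) {
  Tissue T = tissueFromList(mesh);
  IntegerVector out(T.nC(), NA_INTEGER);
  for (int c = 0; c < T.nC(); ++c)
    if (T.calive[c]) out[c] = (int)T.cellNeighbours(c).size();
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_cell_sizes(List mesh) {
  Tissue T = tissueFromList(mesh);
  IntegerVector out(T.nC(), NA_INTEGER);
  for (int c = 0; c < T.nC(); ++c)
    if (T.calive[c]) out[c] = T.cellSize(c);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_vertex_degrees(List mesh) {
  Tissue T = tissueFromList(mesh);
  IntegerVector out(T.nV(), NA_INTEGER);
  std::vector<int> deg(T.nV(), 0);
  for (int h = 0; h < T.nH(); ++h)
    if (T.halive[h]) deg[T.ho[h]]++;
  for (int v = 0; v < T.nV(); ++v)
    if (T.valive[v]) out[v] = deg[v];
  return out;
}

// ---------------------------------------------------------------- validation

std::vector<std::string> validateImpl(Tissue &T, double relTol) {
  std::vector<std::string> bad;
  std::ostringstream os;
  auto flag = [&](const std::ostringstream &o) { bad.push_back(o.str()); };

  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h]) continue;
    std::ostringstream o;
    int t = T.ht[h];
    if (t < 0 || t >= T.nH() || !T.halive[t] || T.ht[t] != h) {
      o << "junction " << h + 1 << ": twin involution broken"; flag(o); continue;
    }
    if (T.hn[h] < 0 || !T.halive[T.hn[h]] || T.hp[T.hn[h]] != h) {
      o << "junction " << h + 1 << ": next/prev chain broken"; flag(o); continue;
    }
    if (T.ho[t] != T.ho[T.hn[h]]) {
      o << "junction " << h + 1 << ": twin origin does not match head"; flag(o);
    }
    if (!T.valive[T.ho[h]]) {
      o << "junction " << h + 1 << ": dead origin vertex"; flag(o);
    }
  }
  if (!bad.empty()) return bad;   // pointer structure broken; stop here

  // every alive interior half-edge reachable from its cell's cycle, once
  std::vector<int> seen(T.nH(), 0);
  for (int c = 0; c < T.nC(); ++c) {
    if (!T.calive[c]) continue;
    std::ostringstream o;
    auto hes = T.cellHalfedges(c);
    if ((int)hes.size() < 3) {
      o << "cell " << c + 1 << ": fewer than 3 vertices"; flag(o); continue;
    }
    std::vector<int> verts;
    bool dup = false;
    for (int h : hes) {
      if (T.hc[h] != c) {
        std::ostringstream o2;
        o2 << "cell " << c + 1 << ": cycle contains foreign junction " << h + 1;
        flag(o2);
      }
      seen[h]++;
      for (int v : verts) if (v == T.ho[h]) dup = true;
      verts.push_back(T.ho[h]);
    }
    if (dup) {
      std::ostringstream o3;
      o3 << "cell " << c + 1 << ": cycle is not simple"; flag(o3);
    }
  }
  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h] || T.hc[h] < 0) continue;
    if (seen[h] != 1) {
      std::ostringstream o;
      o << "junction " << h + 1 << ": visited " << seen[h] << " times in cell cycles";
      flag(o);
    }
    if (!T.calive[T.hc[h]]) {
      std::ostringstream o;
      o << "junction " << h + 1 << ": points to dead cell"; flag(o);
    }
  }

  // Euler characteristic of the disk: V - E + F = 1 (outer face not counted)
  int V = T.nAliveVertices(), E = T.nAliveHalfedges() / 2, F = T.nAliveCells();
  if (V - E + F != 1) {
    std::ostringstream o;
    o << "Euler characteristic V-E+F = " << V - E + F << " (expected 1)";
    flag(o);
  }

  // positive areas and confluence against the outer boundary area
  T.computeGeometry();
  double total = 0.0;
  for (int c = 0; c < T.nC(); ++c) {
    if (!T.calive[c]) continue;
    total += T.area[c];
    if (T.area[c] <= 0) {
      std::ostringstream o;
      o << "cell " << c + 1 << ": non-positive area " << T.area[c]; flag(o);
    }
    if (T.calive[c] && (T.cA0[c] < 0 || T.cP0[c] < 0)) {
      std::ostringstream o;
      o << "cell " << c + 1 << ": negative target"; flag(o);
    }
  }
  // outer face: one closed clockwise cycle
  double outerArea = 0.0;
  int outerCycles = 0;
  std::vector<int> ovisit(T.nH(), 0);
  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h] || T.hc[h] >= 0 || ovisit[h]) continue;
    ++outerCycles;
    int e = h;
    do {
      ovisit[e] = 1;
      int u = T.ho[e], v = T.ho[T.hn[e]];
      outerArea += 0.5 * (T.vx[u] * T.vy[v] - T.vx[v] * T.vy[u]);
      e = T.hn[e];
    } while (e != h);
  }
  if (outerCycles != 1) {
    std::ostringstream o;
    o << "outer face has " << outerCycles << " cycles (expected 1)"; flag(o);
  }
  double enclosed = -outerArea;   // outer cycle winds clockwise
  if (enclosed > 0 && std::fabs(total - enclosed) > relTol * enclosed) {
    std::ostringstream o;
    o << "confluence broken: cell areas sum to " << total
      << " but boundary encloses " << enclosed;
    flag(o);
  }

  // interior vertices need degree >= 3
  std::vector<int> deg(T.nV(), 0), onOuter(T.nV(), 0);
  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h]) continue;
    deg[T.ho[h]]++;
    if (T.hc[h] < 0) onOuter[T.ho[h]] = 1;
  }
  for (int v = 0; v < T.nV(); ++v) {
    if (!T.valive[v]) continue;
    if (deg[v] == 0) {
      std::ostringstream o;
      o << "vertex " << v + 1 << ": isolated"; flag(o);
    } else if (!onOuter[v] && deg[v] < 3) {
      std::ostringstream o;
      o << "vertex " << v + 1 << ": interior degree " << deg[v] << " < 3"; flag(o);
    }
  }
  return bad;
}

// [[Rcpp::export]]
CharacterVector cpp_validate(List mesh, double relTol = 1e-6) {
  Tissue T = tissueFromList(mesh);
  auto bad = validateImpl(T, relTol);
  return wrap(bad);
}
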