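#ifndef EPIVERTEX_VM_H
#define EPIVERTEX_VM_H

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

// Half-edge (DCEL) representation of a confluent polygonal tiling.
// Indices are 0-based internally, 1-based on the R side. hc == -1 marks a
// half-edge bordering the single outer face of the disk-like tiling.
// Dead entries are tombstoned (alive flag), never reused within a run, so
// event logs can reference stable ids.
struct Tissue {
  // vertices
  std::vector<double> vx, vy;
  std::vector<uint8_t> vclamp, valive;
  // half-edges: origin, twin, next, prev, cell
  std::vector<int> ho, ht, hn, hp, hc;
  std::vector<uint8_t> halive;
  // cells: kind 0 = active, 1 = passive
  std::vector<int> ckind;
  std::vector<double> cA0, cP0;
  std::vector<int> cgen;
  std::vector<uint8_t> calive;
  std::vector<int> che;   // one representative half-edge per cell
  double L = 0.0, La = 0.0, time = 0.0;

  // scratch geometry, filled by computeGeometry()
  std::vector<double> area, perim, cx, cy;

  int nV() const { return (int)vx.size(); }
  int nH() const { return (int)ho.size(); }
  int nC() const { return (int)ckind.size(); }

  int nAliveVertices() const;
  int nAliveCells() const;
  int nAliveHalfedges() const;

  void computeGeometry();                 // area, perim, centroid per cell
  int cellSize(int c) const;              // vertex count of cell c
  std::vector<int> cellHalfedges(int c) const;
  std::vector<int> cellNeighbours(int c) const; // distinct adjacent cells
  std::vector<int> vertexOutEdges(int v, int start) const; // ring around v
  int findOutEdge(int v) const;           // any alive half-edge with origin v
  int vertexDegree(int v) const;

  int addVertex(double x, double y, bool clamped);
  int addHalfedge(int origin, int cell);
  int addCell(int kind, double A0, double P0, int gen);

  void killVertex(int v) { valive[v] = 0; }
  void killHalfedge(int h) { halive[h] = 0; }
  void killCell(int c) { calive[c] = 0; }
};

struct Params {
  double KA = 3.0, KP = 1.0, zeta = 1.0;
  double g = 2e-3, alpha = 8.0, beta = 6.0;
  double Ad = NA_REAL, Ai = NA_REAL;
  double lT1 = 5e-3, dt = 5e-3;
  double p0a = 3.60, p0p = 3.80;
  double mu = 5.98, sigma = 0.3, P0p = 5.98;
  int eventInterval = 5, recordInterval = 5;
};

Tissue tissueFromList(const Rcpp::List &m);
Rcpp::List tissueToList(const Tissue &T);
Params paramsFromList(const Rcpp::List &p);

// geometry helpers
inline double polyArea(const std::vector<double> &x, const std::vector<double> &y) {
  double a = 0.0; size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

// mechanics (vm_mech.cpp)
double tissueEnergyImpl(Tissue &T, const Params &P);
void vertexForcesImpl(Tissue &T, const Params &P,
                      std::vector<double> &fx, std::vector<double> &fy);

// topology (vm_topo.cpp); each returns success and fills event info
struct EventRec {
  double time; int kind;   // 0 T1, 1 T2/ingression, 2 division, 3 resolution, 4 conversion
  int cell = NA_INTEGER, cell2 = NA_INTEGER, junction = NA_INTEGER;
  int d1 = NA_INTEGER, d2 = NA_INTEGER;
};
bool t1Impl(Tissue &T, int h, double lnew, std::string *why);
bool collapseImpl(Tissue &T, int c, int *newVertex, std::string *why);
int resolveVertexImpl(Tissue &T, int v, double lnew, std::vector<EventRec> *ev);
bool divideImpl(Tissue &T, int c, double ax, double ay, double tol,
                int *d1, int *d2, std::string *why);
void convertEncircledImpl(Tissue &T, const Params &P, std::vector<EventRec> *ev);
void longAxisOf(Tissue &T, int c, double *ax, double *ay, bool *degen);

// validation (vm_mesh.cpp)
std::vector<std::string> validateImpl(Tissue &T, double relTol);

// division / ingression probabilities: overflow-safe logistic
inline double logisticStable(double z) {
  // 1 / (1 + exp(-z)) without overflow
  if (z >= 0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

#endif
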