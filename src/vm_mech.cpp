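#include "vm.h"

using namespace Rcpp;

// Shape energy: E = sum_c [ KA/2 (A_c - A_c0)^2 + KP/2 (P_c - P_c0)^2 ]
double tissueEnergyImpl(Tissue &T, const Params &P) {
  T.computeGeometry();
  double E = 0.0;
  for (int c = 0; c < T.nC(); ++c) {
    if (!T.calive[c]) continue;
    double da = T.area[c] - T.cA0[c];
    double dp = T.perim[c] - T.cP0[c];
    E += 0.5 * P.KA * da * da + 0.5 * P.KP * dp * dp;
  }
  return E;
}

// Analytic force F_i = -grad_{r_i} E, accumulated per half-edge.
// For half-edge u -> v in cell c:
//   shoelace term x_u*y_v - x_v*y_u contributes to dA/dr at both ends;
//   the perimeter term |r_v - r_u| likewise.
// Clamped vertices report exactly zero force. Zero-length junctions have an
// undefined perimeter unit vector; their perimeter contribution is dropped.
void vertexForcesImpl(Tissue &T, const Params &P,
                      std::vector<double> &fx, std::vector<double> &fy) {
  T.computeGeometry();
  fx.assign(T.nV(), 0.0);
  fy.assign(T.nV(), 0.0);
  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h] || T.hc[h] < 0) continue;
    int c = T.hc[h], u = T.ho[h], v = T.ho[T.hn[h]];
    double ca = -P.KA * (T.area[c] - T.cA0[c]);
    fx[u] += ca * 0.5 * T.vy[v];
    fy[u] -= ca * 0.5 * T.vx[v];
    fx[v] -= ca * 0.5 * T.vy[u];
    fy[v] += ca * 0.5 * T.vx[u];
    double dx = T.vx[v] - T.vx[u], dy = T.vy[v] - T.vy[u];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-14) continue;
    double cp = -P.KP * (T.perim[c] - T.cP0[c]) / len;
    fx[u] -= cp * dx;
    fy[u] -= cp * dy;
    fx[v] += cp * dx;
    fy[v] += cp * dy;
  }
  for (int i = 0; i < T.nV(); ++i)
    if (!T.valive[i] || T.vclamp[i]) { fx[i] = 0.0; fy[i] = 0.0; }
}

// [[Rcpp::export]]
double cpp_tissue_energy(List mesh, List params) {
  Tissue T = tissueFromList(mesh);
  Params P = paramsFromList(params);
  return tissueEnergyImpl(T, P);
}

// [[Rcpp::export]]
NumericMatrix cpp_vertex_forces(List mesh, List params) {
  Tissue T = tissueFromList(mesh);
  Params P = paramsFromList(params);
  std::vector<double> fx, fy;
  vertexForcesImpl(T, P, fx, fy);
  NumericMatrix out(T.nV(), 2);
  for (int i = 0; i < T.nV(); ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// Homeostatic pressure of a cell: P_r^c = -K_A (A_c - A_c0)
// [[Rcpp::export]]
NumericVector cpp_cell_pressures(List mesh, List params) {
  Tissue T = tissueFromList(mesh);
  Params P = paramsFromList(params);
  T.computeGeometry();
  NumericVector out(T.nC(), NA_REAL);
  for (int c = 0; c < T.nC(); ++c)
    if (T.calive[c]) out[c] = -P.KA * (T.area[c] - T.cA0[c]);
  return out;
}
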