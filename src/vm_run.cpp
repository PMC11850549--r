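#include "vm.h"
#include <algorithm>

using namespace Rcpp;

namespace {

struct ObsAccum {
  std::vector<double> time, Aa, Atot, Pa, Pp, prMean, prSd, energy;
  std::vector<int> Na, Np, sigmaD, sigmaI;
  std::vector<std::vector<int>> hist;   // bins n = 3..12 plus overflow

  void record(Tissue &T, const Params &P, int sigmaDNow, int sigmaINow) {
    T.computeGeometry();
    int na = 0, np = 0;
    double aa = 0.0, atot = 0.0, pa = 0.0, pp = 0.0;
    double prs = 0.0, prs2 = 0.0;
    std::vector<int> bins(11, 0);
    double E = 0.0;
    for (int c = 0; c < T.nC(); ++c) {
      if (!T.calive[c]) continue;
      double A = T.area[c], Pe = T.perim[c];
      double da = A - T.cA0[c], dp = Pe - T.cP0[c];
      E += 0.5 * P.KA * da * da + 0.5 * P.KP * dp * dp;
      atot += A;
      double press = -P.KA * da;
      if (T.ckind[c] == 0) {
        ++na; aa += A; pa += press;
        double pr = Pe / std::sqrt(A);
        prs += pr; prs2 += pr * pr;
        // distinct neighbours, allocation-free (cells are small polygons)
        int buf[64]; int nn = 0;
        int h0 = T.che[c], h = h0;
        do {
          int q = T.hc[T.ht[h]];
          if (q >= 0) {
            bool seen = false;
            for (int k = 0; k < nn; ++k) if (buf[k] == q) { seen = true; break; }
            if (!seen && nn < 64) buf[nn++] = q;
          }
          h = T.hn[h];
        } while (h != h0);
        int n = nn < 3 ? 3 : nn;
        bins[std::min(n, 13) - 3] += 1;
      } else {
        ++np; pp += press;
      }
    }
    time.push_back(T.time);
    Na.push_back(na); Np.push_back(np);
    Aa.push_back(aa); Atot.push_back(atot);
    Pa.push_back(na > 0 ? pa / na : NA_REAL);
    Pp.push_back(np > 0 ? pp / np : NA_REAL);
    if (na > 0) {
      double m = prs / na;
      double var = prs2 / na - m * m;     // population convention
      prMean.push_back(m);
      prSd.push_back(std::sqrt(std::max(0.0, var)));
    } else {
      prMean.push_back(NA_REAL); prSd.push_back(NA_REAL);
    }
    energy.push_back(E);
    sigmaD.push_back(sigmaDNow); sigmaI.push_back(sigmaINow);
    hist.push_back(bins);
  }
};

// one pass of T1 transitions: all interior junctions shorter than lT1,
// processed in ascending length order; junctions whose endpoints were touched
// by an earlier T1 in the same sweep are skipped and retried next step
int t1Sweep(Tissue &T, const Params &P, std::vector<EventRec> *ev) {
  std::vector<std::pair<double, int>> cand;
  for (int h = 0; h < T.nH(); ++h) {
    if (!T.halive[h] || T.ht[h] < h) continue;   // undirected: visit once
    int t = T.ht[h];
    if (T.hc[h] < 0 || T.hc[t] < 0) continue;
    int a = T.ho[h], b = T.ho[t];
    if (T.vclamp[a] || T.vclamp[b]) continue;
    double len = std::sqrt((T.vx[b] - T.vx[a]) * (T.vx[b] - T.vx[a]) + (T.vy[b] - T.vy[a]) * (T.vy[b] - T.vy[a]));
    if (len < P.lT1) cand.push_back({len, h});
  }
  if (cand.empty()) return 0;
  std::sort(cand.begin(), cand.end());
  std::vector<uint8_t> touched(T.nV(), 0);
  int done = 0;
  double lnew = 1.02 * P.lT1;
  for (auto &ch : cand) {
    int h = ch.second;
    int a = T.ho[h], b = T.ho[T.ht[h]];
    if (touched[a] || touched[b]) continue;
    int c1 = T.hc[h], c2 = T.hc[T.ht[h]];
    if (t1Impl(T, h, lnew, nullptr)) {
      touched[a] = touched[b] = 1;
      ++done;
      if (ev) {
        EventRec r; r.time = T.time; r.kind = 0;
        r.cell = c1; r.cell2 = c2; r.junction = h;
        ev->push_back(r);
      }
    }
  }
  return done;
}

bool anyBadArea(Tissue &T) {
  T.computeGeometry();
  for (int c = 0; c < T.nC(); ++c)
    if (T.calive[c] && (!(T.area[c] > 0.0) || !std::isfinite(T.area[c])))
      return true;
  return false;
}

double truncNorm(double mu, double sigma) {
  double p;
  do { p = R::rnorm(mu, sigma); } while (p <= 0.0);
  return p;
}

} // namespace

// Advance one phase of a run by nsteps first-order Euler steps.
// Per-step schedule: (1) integrate unclamped vertices, (2) T1 sweep,
// (3) in the active phase: target-area growth every step and, every
// eventInterval-th step, division sweep -> ingression sweep -> encircled
// type conversion, (4) stability check (positive areas). Observables are
// sampled every recordInterval-th step (counted from stepOffset).
// [[Rcpp::export]]
List cpp_run_phase(List mesh, List params, int nsteps, bool activePhase,
                   int stepOffset, int sigmaD0, int sigmaI0,
                   double divisionTol = 1e-9) {
  Tissue T = tissueFromList(mesh);
  Params P = paramsFromList(params);
  std::vector<EventRec> events;
  ObsAccum obs;
  int sigmaD = sigmaD0, sigmaI = sigmaI0;
  std::string status = "completed";
  std::vector<double> fx, fy;
  int stepsDone = 0;

  if (stepOffset == 0) obs.record(T, P, sigmaD, sigmaI);  // initial sample

  for (int s = 1; s <= nsteps; ++s) {
    int gstep = stepOffset + s;

    // (1) overdamped Euler update; the force pass refreshes the cell
    // geometry, which doubles as the stability check on the current state
    vertexForcesImpl(T, P, fx, fy);
    for (int c = 0; c < T.nC(); ++c) {
      if (T.calive[c] && (!(T.area[c] > 0.0) || !std::isfinite(T.area[c]))) {
        status = "unstable";
        break;
      }
    }
    if (status != "completed") { stepsDone = s - 1; break; }
    double scale = P.dt / P.zeta;
    for (int v = 0; v < T.nV(); ++v) {
      if (!T.valive[v] || T.vclamp[v]) continue;
      T.vx[v] += scale * fx[v];
      T.vy[v] += scale * fy[v];
    }
    T.time += P.dt;

    // (2) neighbour exchanges
    t1Sweep(T, P, &events);

    // (3) active processes
    if (activePhase) {
      for (int c = 0; c < T.nC(); ++c) {
        if (!T.calive[c] || T.ckind[c] != 0) continue;
        T.cA0[c] += P.g * P.dt;
        T.cP0[c] = P.p0a * std::sqrt(T.cA0[c]);
      }
      if (gstep % P.eventInterval == 0) {
        T.computeGeometry();
        std::vector<int> sweep;
        for (int c = 0; c < T.nC(); ++c)
          if (T.calive[c] && T.ckind[c] == 0) sweep.push_back(c);

        // divisions (Hertwig's rule: cut perpendicular to the long axis)
        for (int c : sweep) {
          if (!T.calive[c]) continue;
          double u = unif_rand();
          double pd = logisticStable(P.alpha * (T.area[c] - P.Ad));
          if (u >= pd) continue;
          double ax, ay; bool dg;
          longAxisOf(T, c, &ax, &ay, &dg);
          int d1 = -1, d2 = -1;
          std::string why;
          if (divideImpl(T, c, ax, ay, divisionTol, &d1, &d2, &why)) {
            for (int d : {d1, d2}) {
              double p0 = truncNorm(P.mu, P.sigma);
              T.cP0[d] = p0;
              T.cA0[d] = (p0 / P.p0a) * (p0 / P.p0a);
            }
            ++sigmaD;
            EventRec r; r.time = T.time; r.kind = 2;
            r.cell = c; r.d1 = d1; r.d2 = d2;
            events.push_back(r);
            T.computeGeometry();
          }
        }
        // ingressions (divided cells and fresh daughters are exempt)
        for (int c : sweep) {
          if (!T.calive[c]) continue;
          double u = unif_rand();
          double pi = logisticStable(-P.beta * (T.area[c] - P.Ai));
          if (u >= pi) continue;
          int w = -1;
          std::string why;
          if (collapseImpl(T, c, &w, &why)) {
            ++sigmaI;
            EventRec r; r.time = T.time; r.kind = 1; r.cell = c;
            events.push_back(r);
            resolveVertexImpl(T, w, 1.02 * P.lT1, &events);
            T.computeGeometry();
          }
        }
        convertEncircledImpl(T, P, &events);
      }
    }

    stepsDone = s;

    if (gstep % P.recordInterval == 0) obs.record(T, P, sigmaD, sigmaI);
  }

  // (4) final stability guard on the end state
  if (status == "completed" && anyBadArea(T)) status = "unstable";

  // pack events
  int ne = (int)events.size();
  NumericVector etime(ne);
  IntegerVector ekind(ne), ecell(ne), ecell2(ne), ejun(ne), ed1(ne), ed2(ne);
  for (int i = 0; i < ne; ++i) {
    etime[i] = events[i].time;
    ekind[i] = events[i].kind;
    ecell[i] = events[i].cell == NA_INTEGER ? NA_INTEGER : events[i].cell + 1;
    ecell2[i] = events[i].cell2 == NA_INTEGER ? NA_INTEGER : events[i].cell2 + 1;
    ejun[i] = events[i].junction == NA_INTEGER ? NA_INTEGER : events[i].junction + 1;
    ed1[i] = events[i].d1 == NA_INTEGER ? NA_INTEGER : events[i].d1 + 1;
    ed2[i] = events[i].d2 == NA_INTEGER ? NA_INTEGER : events[i].d2 + 1;
  }
  // pack observables (neighbour histogram bins n3..n12 + overflow)
  int ns = (int)obs.time.size();
  IntegerMatrix hist(ns, 11);
  for (int i = 0; i < ns; ++i)
    for (int b = 0; b < 11; ++b) hist(i, b) = obs.hist[i][b];

  return List::create(
    _["mesh"] = tissueToList(T),
    _["status"] = status,
    _["stepsDone"] = stepsDone,
    _["sigmaD"] = sigmaD, _["sigmaI"] = sigmaI,
    _["events"] = List::create(
      _["time"] = etime, _["kind"] = ekind, _["cell"] = ecell,
      _["cell2"] = ecell2, _["junction"] = ejun,
      _["daughter1"] = ed1, _["daughter2"] = ed2),
    _["obs"] = List::create(
      _["time"] = wrap(obs.time), _["nActive"] = wrap(obs.Na),
      _["nPassive"] = wrap(obs.Np), _["activeArea"] = wrap(obs.Aa),
      _["totalArea"] = wrap(obs.Atot), _["sigmaD"] = wrap(obs.sigmaD),
      _["sigmaI"] = wrap(obs.sigmaI),
      _["meanPressureActive"] = wrap(obs.Pa),
      _["meanPressurePassive"] = wrap(obs.Pp),
      _["shapeIndexMean"] = wrap(obs.prMean),
      _["shapeIndexSd"] = wrap(obs.prSd),
      _["energy"] = wrap(obs.energy),
      _["hist"] = hist));
}

// Division and ingression probabilities (overflow-safe logistic forms)
// [[Rcpp::export]]
NumericVector cpp_division_probability(NumericVector area, double alpha, double Ad) {
  int n = area.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = logisticStable(alpha * (area[i] - Ad));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ingression_probability(NumericVector area, double beta, double Ai) {
  int n = area.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = logisticStable(-beta * (area[i] - Ai));
  return out;
}
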