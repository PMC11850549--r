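---
title: "Modelling homeostasis of a confined epithelium with epiVertex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homeostasis of a confined epithelium with epiVertex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiVertex)
```

## The model

epiVertex simulates a confluent epithelial monolayer as a two-dimensional
vertex model: the apical plane of the tissue is a polygonal tiling, each
cell a polygon, each junction shared by two cells, and the vertices (where
three or more junctions meet) are the dynamical degrees of freedom. The
mechanical energy is the standard quadratic shape energy

$$E = \sum_{c}\left[\frac{K_A}{2}\,(A_c - A_{c,0})^2 +
      \frac{K_P}{2}\,(P_c - P_{c,0})^2\right],$$

where $A_c$, $P_c$ are the actual area and perimeter of cell $c$ and
$A_{c,0}$, $P_{c,0}$ the targets. The area term models volume conservation
at preferred cell height, the perimeter term the contractile adhesion
belt. The ratio $p_{c,0} = P_{c,0}/\sqrt{A_{c,0}}$ — the *target shape
index* — controls whether the tissue behaves solid-like (low $p_0$) or
fluid-like (high $p_0$): for a regular-hexagon tiling the shear modulus
vanishes at $p_0 = 6/\sqrt{3\sqrt3/2} \approx 3.722$, while the energy
barrier for neighbour exchange persists up to the regular-pentagon value
$\approx 3.81$. Simulations here stay in the empirically stable window
$p_0 \in [3.600, 3.825]$.

Vertices move by overdamped gradient dynamics
$\zeta\,\dot{\mathbf r}_i = -\nabla_{\mathbf r_i} E$, integrated with a
first-order Euler scheme. The microscopic noise term often added to such
dynamics is deliberately omitted: on the time scales of interest its
effect on tissue-level behaviour is negligible. Forces are evaluated
analytically (shoelace gradient for the area term, junction unit vectors
for the perimeter term); the numerical-gradient computation survives only
as a test oracle.

The simulated system is an **active inclusion in a passive host**: a
centred $L_a \times L_a$ patch of proliferating cells inside an
$L \times L$ box of passive cells, whose outermost vertex layers are
clamped (immobile), emulating attachment to rigid surrounding tissue.
Passive cells deform and rearrange but never grow, divide or ingress.

### Cellular processes

* **Intercalation (T1).** A junction shorter than $\ell_{T1}$ is rotated
  90° counterclockwise about its midpoint, extended to
  $1.02\,\ell_{T1}$, and the adjacency is rewired: the two cells that
  shared it lose a vertex, the two flanking cells gain one.
* **Growth.** Each active target area grows linearly,
  $\dot A_{c,0} = g$, with the target perimeter reset to
  $p_0^a \sqrt{A_{c,0}}$ so the target shape index is constant.
* **Division.** Every five steps each active cell draws a uniform number
  against the logistic probability
  $\mathbb{P}_d = \left[1 + e^{-\alpha(A_c - A_d)}\right]^{-1}$.
  A dividing cell is cut through its centroid perpendicular to its long
  axis (Hertwig's rule; the axis is the principal eigenvector of the
  gyration tensor of its vertices). Daughters draw fresh target
  perimeters from $\mathcal N(\mu, \sigma)$.
* **Ingression (T2).** On the same cadence, cells draw against
  $\mathbb{P}_i = \left[1 + e^{+\beta(A_c - A_i)}\right]^{-1}$ —
  preferentially removing small cells — and are collapsed onto their
  centroid. The resulting high-coordination vertex is split by random
  admissible cuts (each side keeping at least two junctions, the two cut
  faces distinct) until all vertices are 3-valent; each split inserts a
  junction of length $1.02\,\ell_{T1}$.
* **Type conversion.** A cell whose neighbours are all of the opposite
  type (a rare outcome of intercalations at the patch boundary) flips
  type, drawing or resetting targets accordingly.

The half-probability areas are anchored to the relaxed tissue:
$A_d = 1.6\,\bar A^a$ and $A_i = 0.3\,\bar A^a$, where $\bar A^a$ is the
mean active-cell area measured once at the end of the passive relaxation
phase ($t_{\rm rel} = 50$, integration and T1 only). The arithmetic mean
over active cells only is used, and the thresholds are frozen thereafter.

### Parameters

| Parameter | Meaning | Default (simulation units) |
|---|---|---|
| $K_A$ | area modulus | 3.0 |
| $K_P$ | perimeter modulus (energy scale) | 1.0 |
| $\zeta$ | substrate friction | 1.0 |
| $N$ | initial cell count | 1000 (250 reduced) |
| $L$ | box side | 50 (25 reduced) |
| $L_a$ | active patch side | 20 (10 reduced) |
| $\mu,\sigma$ | active target-perimeter distribution | 5.98, 0.3 |
| $P_0^p$ | passive target perimeter | 5.98 |
| $g$ | growth rate | $2\cdot10^{-3}$ |
| $\alpha$ | division sensitivity | 8.0 |
| $\beta$ | ingression sensitivity | 6.0 |
| $\ell_{T1}$ | T1 threshold length | $5\cdot10^{-3}$ |
| $\delta t$ | Euler time step | $5\cdot10^{-3}$ |
| $t_{\rm rel}$ | passive relaxation time | 50 |

The defaults keep the number density at $N/L^2 = 0.4$ cells per unit
area (mean cell area 2.5), which makes $\mu = 5.98$ a consistent mean
perimeter for the initial centroidal tiling at either scale.

## Initial conditions

`buildInitialTiling()` seeds $N$ uniform random points in the box and
applies Lloyd iteration — each seed moves to the centroid of its Voronoi
tile until the largest displacement falls below $5\cdot10^{-5}$ of $L$ —
producing a centroidal Voronoi tessellation: disordered but uniform, the
standard proxy for epithelial packing. Seeds within a cutoff (default
$2L/\sqrt N$, about two cell diameters) of a wall are mirrored across it,
so wall bisectors lie exactly on the box boundary and the tiling ends in
straight edges; tiles are also clipped to the box so sparse
configurations behave. Wall vertices plus one interior ring (the
"outermost layers"; the ring depth is the `clampRings` knob) are clamped.
The tolerance is interpreted relative to $L$ because the stopping rule
needs a reference scale and the box side is the only global one.

Two interpretation choices here were genuinely open and are fixed as
follows: the mirroring depth (unspecified beyond "a preset cutoff") is
two typical cell diameters, deep enough to straighten two boundary
layers; and clamping covers the wall vertices plus one ring, with the
depth exposed rather than hard-coded, since "outermost layers" does not
pin down a count.

## Numerical choices

* **Geometry tolerances.** Coincidence tests (vertex reuse in division)
  use $10^{-9}$ length units — far below $\ell_{T1}$ and typical
  displacements $\delta t\,F$, far above double-precision noise.
  Voronoi tile vertices are merged within $10^{-8}$ when the half-edge
  mesh is assembled; wall coordinates are snapped exactly.
* **T1 ordering.** When several junctions are short in the same step
  they are processed in ascending length order; a junction whose
  endpoint was already moved by a T1 this sweep waits for the next step.
  Both endpoints must be 3-valent and all four participating cells
  distinct, so the surgery is always well defined.
* **Event ordering.** Within an event sweep, divisions are evaluated
  first (in ascending cell id), then ingressions, then conversions.
  Cells divided in a sweep, and their daughters, are exempt from
  ingression until the next sweep. All randomness flows through the
  single seeded R RNG in a documented order, so runs are bit-for-bit
  reproducible.
* **Degenerate long axes.** A cell whose gyration tensor has a relative
  eigenvalue gap below $10^{-9}$ (squares, regular hexagons) divides
  along a uniformly random direction, and the degeneracy is flagged.
* **Instability as an outcome.** Aggressive parameters (large $g$ or
  $\beta$, $p_0 > 3.825$) can invert cells. A non-positive or
  non-finite cell area stops the run with status `"unstable"` and
  partial outputs — mirroring the truncated parameter regions of the
  full-scale phase diagrams — rather than crashing.
* **Collapse preconditions.** A T2 collapse is rejected if the cell
  touches a clamped vertex or the boundary, if a neighbour would drop
  below three vertices, or if a neighbour shares two junctions with it;
  rejected cells are simply retried at the next sweep.

## Observables

Per sample (every 5 steps by default): active/passive counts and areas;
the fractional changes $f_N = N^a(t)/N^a(t_{\rm ref})$ and
$f_A = A^a(t)/A^a(t_{\rm ref})$ (reference either $t=0$ or
$t=t_{\rm rel}$; $f_N$ is insensitive since the count cannot change
during relaxation); cumulative division and ingression counts
$\Sigma_d,\ \Sigma_i$ (the exact ledger identity
$\Sigma_d-\Sigma_i = N^a(t)-N^a(t_{\rm ref})$ is asserted in tests);
per-population means of the cell pressure
$\mathcal P_r^c=-K_A(A_c-A_{c,0})$; the realised shape index
$p_{r,c} = P_c/\sqrt{A_c}$ of active cells (mean and population-
convention standard deviation); and the neighbour-count histogram of
active cells. `steadyStateSummary()` time-averages a window (500 time
units by default, shorter for reduced runs).

## What the reduced-scale experiments establish — and what they do not

Full-scale runs of this model ($N = 1000$, $t \gtrsim 2000$) take days
per realisation. The test suite therefore works at quarter scale:
$N = 250$, $L = 25$, $L_a = 10$, identical parameters otherwise and
identical number density, three seeds per condition, comparing
seed-averaged steady-state means. At this scale the simulations
reproduce, as qualitative trends: homeostasis itself (saturating $f_N$,
$f_A$ with ongoing balanced division and ingression), the decrease of
$\bar f_N$ with division sensitivity $\alpha$ and its increase with
ingression sensitivity $\beta$ and growth rate $g$; the increase with
the passive shape index and decrease with the active one; the decrease
under stronger confinement $L_a/L \to 1$; near-unity active/passive
pressure balance; and the dominance hierarchy
$P_6 \ge P_5 \ge P_7$ of the neighbour-count distribution with a
hexagon fraction that falls from the initial tiling to the steady
state.

Three caveats are deliberate. First, with only ~40 active cells the
shape-index sweeps separate from seed noise only with a longer horizon
($t = 600$, averaging the final 200 time units) and the widest parameter
contrast ($p_0 = 3.600$ vs $3.825$). Second, population pressures
equilibrate more slowly than the cell count; the pressure ratio is
measured at $t = 1000$, where it settles near 1.05 (at $t = 400$ it is
still relaxing through $\approx 1.2$). Third, quantitative full-scale
values — e.g. the $\approx1.5\times$ gain-ratio between the
stiff-active/soft-passive configuration and its reverse — are checked
only directionally; at reduced scale the measured ratio happens to land
near 1.45, but a green directional test should not be read as a
quantitative reproduction. The confinement sweep varies $L_a$ at fixed
$L$ (ratios 0.4 vs 0.8) rather than varying $L$ at fixed $L_a$, keeping
the cell density and target perimeters unchanged; the confinement ratio
is the control parameter either way.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(
  init = initConfig(nCells = 250, boxSize = 25, patchSize = 10, seed = 1),
  params = modelParams(p0Active = 3.60, p0Passive = 3.80),
  schedule = runSchedule(endTime = 400))
res <- runSimulation(cfg)
steadyStateSummary(res, window = 100)
```

On this seed the run completes in a few seconds; the active population
grows from 42 to 57 cells through 24 divisions and 9 ingressions, and
the summary reports $\bar f_N \approx 1.27$, $\bar f_A \approx 1.37$, a
realised shape index of $\approx 3.82$, and neighbour fractions led by
hexagons and pentagons.

## Known limitations

Junctions are straight; there is no cell motility force, no junction-
level tension dynamics, no internal dissipation, no cell-cycle state,
and no biochemical signalling. Boundary T1s involving clamped vertices
are excluded, and the box is always square. The Euler integrator is
first order: halving $\delta t$ is the cheap convergence check. These
boundaries match the scope of the modelled system, not oversights.
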