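# epiVertex

A two-dimensional vertex model of **homeostasis in a confined
epithelium**: a square patch of active cells — which grow, divide and
ingress — embedded in a passive epithelium clamped to a rigid square
boundary. The package is for quantitative biologists and tissue-mechanics
modellers who want a seedable, testable simulator of the dynamic steady
state in which cell divisions and removals balance, together with the
full set of observables that characterise it.

## The model

The tissue is a confluent polygonal tiling; vertices are the degrees of
freedom. Cell shapes carry the quadratic shape energy

    E = Σ_c [ K_A/2 (A_c − A_c0)² + K_P/2 (P_c − P_c0)² ]

and vertices follow overdamped gradient dynamics ζ ṙᵢ = −∇ᵢE (first-order
Euler, no noise term). The target shape index p₀ = P₀/√A₀ tunes
solid-like vs fluid-like behaviour (hexagon value 6/√(3√3/2) ≈ 3.722;
pentagon ≈ 3.81). Topology changes through T1 intercalations (short
junctions rotate 90° and re-open at 1.02 ℓ_T1), T2 ingressions (a cell
collapses to a vertex, which is then split back to 3-valent vertices),
and division edges inserted through the centroid perpendicular to the
cell's long axis (Hertwig's rule, gyration-tensor axis). Active cells
grow linearly (Ȧ_c0 = g) and divide/ingress stochastically with logistic
probabilities 1/(1+e^(−α(A−A_d))) and 1/(1+e^(+β(A−A_i))), with
A_d = 1.6 Ā and A_i = 0.3 Ā anchored to the mean active area Ā of the
relaxed tissue. Initial conditions are centroidal Voronoi tessellations
(Lloyd relaxation with mirrored boundary padding) with clamped outermost
vertex layers.

The mesh is a half-edge (DCEL) structure behind S4 classes; the
time-stepping core is compiled (Rcpp). Every topological move preserves
the Euler characteristic V − E + F = 1 and confluence (cell areas sum to
L²), and both are enforced in the test suite through randomized
stress tests.

## A worked example

```r
library(epiVertex)

cfg <- simulationConfig(
  init = initConfig(nCells = 250, boxSize = 25, patchSize = 10, seed = 1),
  params = modelParams(p0Active = 3.60, p0Passive = 3.80),
  schedule = runSchedule(endTime = 400))
res <- runSimulation(cfg)
res
#> SimulationResult (completed): 16001 samples to t = 400
#>   active cells 42 -> 57, divisions 24, ingressions 9
#> GrowthState: mean active area 2.7121 at t = 50 (A_i = 0.8136, A_d = 4.3394)

steadyStateSummary(res, window = 100)
#> SteadyStateSummary over t = [300, 400] (4001 samples)
#>   fN = 1.2703 (sd 0.0312), fA = 1.3673 (sd 0.0369)
#>   pressures: active 0.7982, passive 0.6614 (ratio 1.207)
#>   realised shape index 3.8150 (sd 0.0523)
#>   neighbour fractions: P_6 = 0.375, P_5 = 0.367, P_7 = 0.220
```

The run reaches homeostasis: the fractional active-cell count fN and
area fA saturate around 1.27 and 1.37 (the stiff-active/soft-passive
configuration gains cells), divisions and ingressions continue in
balance (Σ_d − Σ_i equals the net count change exactly, at every
sample), and the neighbour distribution is led by hexagons and
pentagons. Note the pressures are still equilibrating at t = 400; by
t = 1000 their ratio settles near 1.05 — mechanical balance between the
two tissues.

Lower-level entry points mirror the pipeline: `buildInitialTiling()`,
`assignTypesAndTargets()`, `runPassiveRelaxation()`, `stepTissue()`, the
topological operations (`t1Transition()`, `collapseCell()`,
`resolveVertex()`, `insertDivisionEdge()`, `convertEncircledCells()`),
and the observables (`realisedShapeIndex()`, `meanPressures()`,
`neighbourDistribution()`, `steadyStateSummary()`). Meshes snapshot to
self-describing JSON (`writeMeshSnapshot()`, lossless round-trip) and
export to legacy VTK for visualization. A thin CLI with
run/relax/resume/validate/sweep subcommands ships in `inst/cli/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the package's main computation — the reduced-scale homeostasis run
above at the given seed (N = 250, L = 25, La = 10, t_end = 400) — prints
its steady-state summary, and writes the machine-readable target report
to `--out`.

## Vignette

`vignettes/vertex-model-homeostasis.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
initial-condition generator, the numerical tolerances and orderings, and
what the reduced-scale experiments do and do not establish.
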