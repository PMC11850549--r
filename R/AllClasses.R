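#' @import methods
NULL

#' Polygonal tissue mesh
#'
#' Half-edge (doubly connected edge list) representation of a confluent
#' epithelial tiling. Vertices are the dynamical degrees of freedom;
#' directed junctions (half-edges) encode connectivity; each cell is the
#' counterclockwise cycle of junctions around one polygonal face. The
#' single outer face is encoded as cell id 0. Dead entries are tombstoned
#' (`alive = FALSE`) and ids are never reused within a run, so event logs
#' can reference them stably.
#'
#' @slot vertices data.frame with columns `x`, `y`, `clamped`, `alive`.
#'   Clamped vertices model attachment to rigid surrounding tissue and
#'   never move.
#' @slot junctions data.frame with columns `origin`, `twin`, `nxt`, `prev`,
#'   `cell`, `alive` (all ids 1-based; `cell` 0 denotes the outer face).
#' @slot cells data.frame with columns `kind` (0 = active, 1 = passive),
#'   `targetArea`, `targetPerimeter`, `generation`, `alive`, `halfedge`.
#' @slot boxSize side length L of the simulation box.
#' @slot patchSize side length La of the centred active patch.
#' @slot time current simulation time.
#'
#' @seealso [buildInitialTiling()], [validateMesh()], [cellArea()]
#' @export
setClass("TissueMesh",
  representation(
    vertices = "data.frame",
    junctions = "data.frame",
    cells = "data.frame",
    boxSize = "numeric",
    patchSize = "numeric",
    time = "numeric"
  )
)

setValidity("TissueMesh", function(object) {
  msgs <- character()
  v <- object@vertices; j <- object@junctions; cl <- object@cells
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("%s missing columns: %s", what,
                              paste(miss, collapse = ", "))
  }
  msgs <- c(msgs,
    need(v, c("x", "y", "clamped", "alive"), "vertices"),
    need(j, c("origin", "twin", "nxt", "prev", "cell", "alive"), "junctions"),
    need(cl, c("kind", "targetArea", "targetPerimeter", "generation",
               "alive", "halfedge"), "cells"))
  if (length(object@boxSize) != 1 || object@boxSize <= 0)
    msgs <- c(msgs, "boxSize must be a single positive number")
  if (length(object@patchSize) != 1 || object@patchSize < 0)
    msgs <- c(msgs, "patchSize must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Model parameters
#'
#' All mechanical and active-process parameters of the vertex model, in
#' simulation units (perimeter modulus fixes the energy scale; the box
#' size fixes length).
#'
#' @slot areaModulus K_A, elastic modulus of the area penalty (default 3).
#' @slot perimeterModulus K_P, modulus of the perimeter penalty (fixed 1).
#' @slot friction zeta, substrate friction in the overdamped equation of
#'   motion (fixed 1).
#' @slot growthRate g, constant growth rate of active target areas
#'   (default 2e-3).
#' @slot divisionSensitivity alpha, steepness of the division probability
#'   (default 8).
#' @slot ingressionSensitivity beta, steepness of the ingression
#'   probability (default 6).
#' @slot divisionArea A_d, area of division probability 1/2; `NA` until
#'   measured from the relaxed tissue (1.6 x mean active area).
#' @slot ingressionArea A_i, area of ingression probability 1/2; `NA`
#'   until measured (0.3 x mean active area).
#' @slot t1Threshold ell_T1, junction length below which a T1 fires
#'   (default 5e-3).
#' @slot timeStep delta t of the Euler integrator (default 5e-3).
#' @slot relaxTime duration of the initial passive relaxation (default 50).
#' @slot eventCheckInterval steps between division/ingression sweeps
#'   (default 5).
#' @slot p0Active target shape index of active cells.
#' @slot p0Passive target shape index of passive cells.
#' @slot targetPerimeterMean mu of the active target-perimeter
#'   distribution (default 5.98).
#' @slot targetPerimeterSd sigma of the same distribution (default 0.3).
#' @slot passivePerimeter fixed target perimeter of passive cells
#'   (default 5.98).
#'
#' @seealso [modelParams()]
#' @export
setClass("ModelParams",
  representation(
    areaModulus = "numeric", perimeterModulus = "numeric",
    friction = "numeric", growthRate = "numeric",
    divisionSensitivity = "numeric", ingressionSensitivity = "numeric",
    divisionArea = "numeric", ingressionArea = "numeric",
    t1Threshold = "numeric", timeStep = "numeric", relaxTime = "numeric",
    eventCheckInterval = "numeric",
    p0Active = "numeric", p0Passive = "numeric",
    targetPerimeterMean = "numeric", targetPerimeterSd = "numeric",
    passivePerimeter = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msgs <- character()
  pos <- c(areaModulus = object@areaModulus,
           perimeterModulus = object@perimeterModulus,
           friction = object@friction,
           growthRate = object@growthRate,
           divisionSensitivity = object@divisionSensitivity,
           ingressionSensitivity = object@ingressionSensitivity,
           t1Threshold = object@t1Threshold,
           timeStep = object@timeStep,
           p0Active = object@p0Active, p0Passive = object@p0Passive,
           targetPerimeterMean = object@targetPerimeterMean,
           passivePerimeter = object@passivePerimeter)
  bad <- names(pos)[!(pos > 0)]
  if (length(bad))
    msgs <- c(msgs, sprintf("parameters must be positive: %s",
                            paste(bad, collapse = ", ")))
  if (object@targetPerimeterSd < 0)
    msgs <- c(msgs, "targetPerimeterSd must be >= 0")
  if (object@relaxTime < 0) msgs <- c(msgs, "relaxTime must be >= 0")
  if (object@eventCheckInterval < 1)
    msgs <- c(msgs, "eventCheckInterval must be >= 1")
  if (!is.na(object@divisionArea) && !is.na(object@ingressionArea) &&
      object@ingressionArea >= object@divisionArea)
    msgs <- c(msgs, "ingressionArea must be below divisionArea")
  if (length(msgs)) msgs else TRUE
})

#' Initial-condition configuration
#'
#' Settings for building the clamped two-population tiling: random seeds
#' relaxed to a centroidal Voronoi tessellation by Lloyd iteration with
#' mirrored padding, wall and first-ring vertices clamped, active patch
#' assigned by centroid position.
#'
#' @slot nCells initial number of cells N.
#' @slot boxSize box side L.
#' @slot patchSize active patch side La (0 < La < L).
#' @slot lloydTol Lloyd stopping tolerance: max per-seed displacement
#'   between iterations, relative to L (default 5e-5).
#' @slot mirrorCutoff distance from each wall within which seeds are
#'   mirrored (default 2 L / sqrt(N), about two cell diameters).
#' @slot clampRings vertex rings clamped beyond the wall vertices
#'   (default 1).
#' @slot maxIterations Lloyd iteration cap.
#' @slot seed RNG seed for the run (NA = do not reseed).
#'
#' @seealso [initConfig()], [buildInitialTiling()]
#' @export
setClass("InitConfig",
  representation(
    nCells = "numeric", boxSize = "numeric", patchSize = "numeric",
    lloydTol = "numeric", mirrorCutoff = "numeric",
    clampRings = "numeric", maxIterations = "numeric", seed = "numeric"
  )
)

setValidity("InitConfig", function(object) {
  msgs <- character()
  if (object@nCells < 4) msgs <- c(msgs, "nCells must be >= 4")
  if (!(object@patchSize > 0) || object@patchSize >= object@boxSize)
    msgs <- c(msgs, "need 0 < patchSize < boxSize")
  if (!(object@lloydTol > 0)) msgs <- c(msgs, "lloydTol must be > 0")
  if (!(object@mirrorCutoff > 0)) msgs <- c(msgs, "mirrorCutoff must be > 0")
  if (object@clampRings < 0) msgs <- c(msgs, "clampRings must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Run schedule
#'
#' @slot endTime total simulated time (relaxation included).
#' @slot recordInterval steps between observable samples (default 5).
#' @slot checkpointInterval steps between snapshot writes (0 = never).
#' @slot outputDir directory for checkpoints ("" = none).
#' @export
setClass("RunSchedule",
  representation(
    endTime = "numeric", recordInterval = "numeric",
    checkpointInterval = "numeric", outputDir = "character"
  )
)

setValidity("RunSchedule", function(object) {
  msgs <- character()
  if (!(object@endTime > 0)) msgs <- c(msgs, "endTime must be > 0")
  if (object@recordInterval < 1) msgs <- c(msgs, "recordInterval must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Full simulation configuration
#'
#' @slot init an [InitConfig-class].
#' @slot params a [ModelParams-class].
#' @slot schedule a [RunSchedule-class].
#' @seealso [simulationConfig()], [runSimulation()]
#' @export
setClass("SimulationConfig",
  representation(init = "InitConfig", params = "ModelParams",
                 schedule = "RunSchedule")
)

setValidity("SimulationConfig", function(object) {
  if (object@schedule@endTime <= object@params@relaxTime)
    "endTime must exceed relaxTime" else TRUE
})

#' Growth reference state
#'
#' The mean active-cell area measured at the end of passive relaxation,
#' which fixes the half-probability areas for division (1.6 x mean) and
#' ingression (0.3 x mean). Frozen once measured.
#'
#' @slot referenceArea mean active-cell area at t = relaxTime.
#' @slot divisionArea 1.6 x referenceArea.
#' @slot ingressionArea 0.3 x referenceArea.
#' @slot referenceTime the time of the measurement.
#' @export
setClass("GrowthState",
  representation(referenceArea = "numeric", divisionArea = "numeric",
                 ingressionArea = "numeric", referenceTime = "numeric")
)

setValidity("GrowthState", function(object) {
  if (!(object@referenceArea > 0)) return("referenceArea must be > 0")
  ok <- object@ingressionArea < object@referenceArea &&
    object@referenceArea < object@divisionArea
  if (!ok) return("need ingressionArea < referenceArea < divisionArea")
  TRUE
})

#' Simulation result
#'
#' @slot mesh final [TissueMesh-class].
#' @slot series data.frame of observable samples (one row per sample).
#' @slot events data.frame event log (divisions, ingressions, T1s,
#'   resolutions, conversions).
#' @slot growth the frozen [GrowthState-class].
#' @slot references named numeric: active cell count and area at t = 0 and
#'   at the end of relaxation, used to normalise fractional changes.
#' @slot status "completed" or "unstable" (overlapping/inverted cells
#'   detected; partial outputs retained).
#' @slot config the [SimulationConfig-class] that produced the run.
#' @export
setClass("SimulationResult",
  representation(mesh = "TissueMesh", series = "data.frame",
                 events = "data.frame", growth = "GrowthState",
                 references = "numeric", status = "character",
                 config = "SimulationConfig")
)

#' Steady-state summary
#'
#' Time means over a homeostasis window (default width 500 time units).
#'
#' @slot fN,fA mean fractional change in active cell number / area.
#' @slot fNSd,fASd their standard deviations over the window.
#' @slot pressureActive,pressurePassive mean homeostatic pressures.
#' @slot shapeIndexMean,shapeIndexSd realised shape index statistics of
#'   active cells.
#' @slot neighbourFractions mean fraction of active cells with n
#'   neighbours (names "3".."12", "13+").
#' @slot window numeric length 2, the averaging window.
#' @slot nSamples samples in the window.
#' @export
setClass("SteadyStateSummary",
  representation(fN = "numeric", fA = "numeric", fNSd = "numeric",
                 fASd = "numeric", pressureActive = "numeric",
                 pressurePassive = "numeric", shapeIndexMean = "numeric",
                 shapeIndexSd = "numeric", neighbourFractions = "numeric",
                 window = "numeric", nSamples = "numeric")
)
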