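#' @include mesh-core.R params.R active.R
NULL

.KIND_LABELS <- c("t1", "ingression", "division", "resolution", "conversion")

.eventsToFrame <- function(ev) {
  data.frame(time = ev$time,
             kind = factor(.KIND_LABELS[ev$kind + 1L],
                           levels = .KIND_LABELS),
             cell = ev$cell, cell2 = ev$cell2, junction = ev$junction,
             daughter1 = ev$daughter1, daughter2 = ev$daughter2)
}

.obsToFrame <- function(obs) {
  hist <- obs$hist
  colnames(hist) <- c(paste0("n", 3:12), "n13plus")
  cbind(data.frame(time = obs$time, nActive = obs$nActive,
                   nPassive = obs$nPassive, activeArea = obs$activeArea,
                   totalArea = obs$totalArea, sigmaD = obs$sigmaD,
                   sigmaI = obs$sigmaI,
                   meanPressureActive = obs$meanPressureActive,
                   meanPressurePassive = obs$meanPressurePassive,
                   shapeIndexMean = obs$shapeIndexMean,
                   shapeIndexSd = obs$shapeIndexSd, energy = obs$energy),
        as.data.frame(hist))
}

.runPhase <- function(mesh, params, nsteps, active, stepOffset = 0,
                      sigmaD = 0, sigmaI = 0, recordInterval = 5) {
  res <- cpp_run_phase(.meshToList(mesh),
                       .paramsToList(params, recordInterval),
                       as.integer(nsteps), active,
                       as.integer(stepOffset), as.integer(sigmaD),
                       as.integer(sigmaI))
  list(mesh = .listToMesh(res$mesh), status = res$status,
       stepsDone = res$stepsDone, sigmaD = res$sigmaD,
       sigmaI = res$sigmaI, events = .eventsToFrame(res$events),
       series = .obsToFrame(res$obs))
}

#' Advance the tissue by Euler steps
#'
#' Each step applies, in order: (1) the overdamped first-order Euler
#' update `r <- r + dt F / zeta` for every unclamped vertex; (2) a T1
#' sweep over junctions shorter than the threshold, processed in
#' ascending length order (junctions touched by an earlier T1 this sweep
#' wait until the next step); (3) in the active phase, target growth
#' every step and, on the event cadence, division, ingression and
#' type-conversion sweeps; (4) a stability check (any non-positive cell
#' area stops the run with status "unstable").
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param nsteps number of steps
#' @param active enable growth/division/ingression (requires `growth`)
#' @param growth a [GrowthState-class] (active phase only)
#' @param stepOffset global step counter offset, used to phase the event
#'   and recording cadences
#' @param recordInterval steps between observable samples
#' @return list with `mesh`, `series`, `events`, `status`, `stepsDone`,
#'   `sigmaD`, `sigmaI`
#' @export
stepTissue <- function(mesh, params, nsteps = 1, active = FALSE,
                       growth = NULL, stepOffset = 0, recordInterval = 5) {
  if (active) {
    if (is.null(growth)) stop("active stepping requires a GrowthState")
    params@divisionArea <- growth@divisionArea
    params@ingressionArea <- growth@ingressionArea
  }
  .runPhase(mesh, params, nsteps, active, stepOffset = stepOffset,
            recordInterval = recordInterval)
}

#' Passive relaxation phase
#'
#' Evolves a fresh tiling for the relaxation time with integration and
#' T1 sweeps only (no growth, division or ingression), letting the
#' tissue settle near a local energy minimum, then measures the growth
#' reference state (mean active area) that fixes the division and
#' ingression half-probability areas.
#'
#' @param mesh a typed [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param recordInterval steps between samples
#' @return list with `mesh`, `series`, `events`, `growth`
#'   (a [GrowthState-class]), `status`
#' @export
runPassiveRelaxation <- function(mesh, params, recordInterval = 5) {
  nRel <- round(params@relaxTime / params@timeStep)
  ph <- .runPhase(mesh, params, nRel, active = FALSE,
                  recordInterval = recordInterval)
  growth <- measureGrowthState(ph$mesh)
  list(mesh = ph$mesh, series = ph$series, events = ph$events,
       growth = growth, status = ph$status)
}

#' Run a full simulation
#'
#' The complete pipeline: seeded initial tiling
#' ([buildInitialTiling()] + [assignTypesAndTargets()]), passive
#' relaxation ([runPassiveRelaxation()]), then the active homeostasis
#' phase to the scheduled end time. All randomness flows through the
#' single R RNG (seeded from `config@init@seed` when set), so an
#' identical configuration and seed reproduces the outputs bit for bit.
#' An instability (inverted cell) stops the run early with status
#' "unstable" and partial outputs retained.
#'
#' The returned series carries the fractional changes `fN`, `fA`
#' normalised by the post-relaxation reference (use
#' [fractionalChanges()] for the t = 0 normalisation) and the ledger
#' identity `sigmaD - sigmaI = nActive(t) - nActive(t_rel)` holds at
#' every sample.
#'
#' @param config a [SimulationConfig-class]
#' @return a [SimulationResult-class]
#' @examples
#' \donttest{
#' cfg <- simulationConfig(
#'   init = initConfig(nCells = 250, boxSize = 25, patchSize = 10, seed = 1),
#'   params = modelParams(p0Active = 3.60, p0Passive = 3.80),
#'   schedule = runSchedule(endTime = 400))
#' res <- runSimulation(cfg)
#' steadyStateSummary(res, window = 100)
#' }
#' @export
runSimulation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  params <- config@params
  sched <- config@schedule

  mesh <- buildInitialTiling(config@init)
  mesh <- assignTypesAndTargets(mesh, params)
  refs <- c(nActive0 = length(activeCells(mesh)),
            activeArea0 = sum(cellArea(mesh, activeCells(mesh))))

  rel <- runPassiveRelaxation(mesh, params,
                              recordInterval = sched@recordInterval)
  growth <- rel$growth
  params@divisionArea <- growth@divisionArea
  params@ingressionArea <- growth@ingressionArea
  refs <- c(refs,
            nActiveRel = length(activeCells(rel$mesh)),
            activeAreaRel = sum(cellArea(rel$mesh, activeCells(rel$mesh))))

  nRel <- round(params@relaxTime / params@timeStep)
  nAct <- round((sched@endTime - params@relaxTime) / params@timeStep)
  status <- rel$status
  series <- rel$series
  events <- rel$events
  meshNow <- rel$mesh
  sigmaD <- 0; sigmaI <- 0
  if (status == "completed" && nAct > 0) {
    act <- .runPhase(meshNow, params, nAct, active = TRUE,
                     stepOffset = nRel, sigmaD = 0, sigmaI = 0,
                     recordInterval = sched@recordInterval)
    status <- act$status
    meshNow <- act$mesh
    sigmaD <- act$sigmaD; sigmaI <- act$sigmaI
    series <- rbind(series, act$series)
    events <- rbind(events, act$events)
  }
  series$fN <- series$nActive / refs[["nActiveRel"]]
  series$fA <- series$activeArea / refs[["activeAreaRel"]]

  new("SimulationResult", mesh = meshNow, series = series,
      events = events, growth = growth, references = refs,
      status = status, config = config)
}

setMethod("show", "SimulationResult", function(object) {
  s <- object@series
  cat(sprintf("SimulationResult (%s): %d samples to t = %g\n",
              object@status, nrow(s), max(s$time)))
  cat(sprintf("  active cells %d -> %d, divisions %d, ingressions %d\n",
              s$nActive[1], s$nActive[nrow(s)],
              max(s$sigmaD), max(s$sigmaI)))
  show(object@growth)
})
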