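#' @include AllClasses.R
NULL

#' Construct model parameters
#'
#' Defaults are the simulation-unit values used throughout: area modulus
#' K_A = 3, perimeter modulus K_P = 1 (energy scale), friction zeta = 1,
#' growth rate g = 2e-3, division sensitivity alpha = 8, ingression
#' sensitivity beta = 6, T1 threshold 5e-3, time step 5e-3, relaxation
#' time 50, event sweeps every 5 steps, target-perimeter distribution
#' Normal(5.98, 0.3), passive target perimeter 5.98. The half-probability
#' areas `divisionArea` / `ingressionArea` stay `NA` until measured from
#' the relaxed tissue (see [measureGrowthState()]).
#'
#' @param p0Active,p0Passive target shape indices (the stable range for
#'   disordered tilings is about 3.60-3.825)
#' @param areaModulus,perimeterModulus,friction,growthRate elastic and
#'   kinetic constants
#' @param divisionSensitivity,ingressionSensitivity logistic steepness
#'   alpha and beta
#' @param divisionArea,ingressionArea half-probability areas A_d, A_i
#' @param t1Threshold,timeStep,relaxTime,eventCheckInterval numerical
#'   schedule constants
#' @param targetPerimeterMean,targetPerimeterSd,passivePerimeter target
#'   perimeter distribution (active) and constant (passive)
#' @return a [ModelParams-class]
#' @examples
#' p <- modelParams(p0Active = 3.60, p0Passive = 3.80)
#' @export
modelParams <- function(p0Active = 3.60, p0Passive = 3.80,
                        areaModulus = 3.0, perimeterModulus = 1.0,
                        friction = 1.0, growthRate = 2e-3,
                        divisionSensitivity = 8.0,
                        ingressionSensitivity = 6.0,
                        divisionArea = NA_real_, ingressionArea = NA_real_,
                        t1Threshold = 5e-3, timeStep = 5e-3,
                        relaxTime = 50, eventCheckInterval = 5,
                        targetPerimeterMean = 5.98,
                        targetPerimeterSd = 0.3,
                        passivePerimeter = 5.98) {
  new("ModelParams",
      areaModulus = areaModulus, perimeterModulus = perimeterModulus,
      friction = friction, growthRate = growthRate,
      divisionSensitivity = divisionSensitivity,
      ingressionSensitivity = ingressionSensitivity,
      divisionArea = divisionArea, ingressionArea = ingressionArea,
      t1Threshold = t1Threshold, timeStep = timeStep,
      relaxTime = relaxTime, eventCheckInterval = eventCheckInterval,
      p0Active = p0Active, p0Passive = p0Passive,
      targetPerimeterMean = targetPerimeterMean,
      targetPerimeterSd = targetPerimeterSd,
      passivePerimeter = passivePerimeter)
}

# flat list consumed by the C++ core
.paramsToList <- function(p, recordInterval = 5L) {
  list(KA = p@areaModulus, KP = p@perimeterModulus, zeta = p@friction,
       g = p@growthRate, alpha = p@divisionSensitivity,
       beta = p@ingressionSensitivity,
       Ad = p@divisionArea, Ai = p@ingressionArea,
       lT1 = p@t1Threshold, dt = p@timeStep,
       p0a = p@p0Active, p0p = p@p0Passive,
       mu = p@targetPerimeterMean, sigma = p@targetPerimeterSd,
       P0p = p@passivePerimeter,
       eventInterval = as.integer(p@eventCheckInterval),
       recordInterval = as.integer(recordInterval))
}

#' Construct an initial-condition configuration
#'
#' @param nCells initial number of cells N
#' @param boxSize box side L
#' @param patchSize active-patch side La
#' @param lloydTol Lloyd stopping tolerance relative to L
#' @param mirrorCutoff wall mirroring depth; default 2 L / sqrt(N)
#'   (about two cell diameters, enough to straighten two boundary layers)
#' @param clampRings vertex rings clamped beyond the wall vertices
#' @param maxIterations Lloyd iteration cap
#' @param seed RNG seed (NA: caller controls seeding)
#' @return an [InitConfig-class]
#' @examples
#' cfg <- initConfig(nCells = 250, boxSize = 25, patchSize = 10, seed = 1)
#' @export
initConfig <- function(nCells = 1000, boxSize = 50, patchSize = 20,
                       lloydTol = 5e-5, mirrorCutoff = NULL,
                       clampRings = 1, maxIterations = 20000,
                       seed = NA_real_) {
  if (is.null(mirrorCutoff)) mirrorCutoff <- 2 * boxSize / sqrt(nCells)
  new("InitConfig", nCells = nCells, boxSize = boxSize,
      patchSize = patchSize, lloydTol = lloydTol,
      mirrorCutoff = mirrorCutoff, clampRings = clampRings,
      maxIterations = maxIterations, seed = as.numeric(seed))
}

#' Construct a run schedule
#'
#' @param endTime total simulated time, relaxation included
#' @param recordInterval steps between observable samples
#' @param checkpointInterval steps between snapshots (0 = never)
#' @param outputDir checkpoint directory ("" = none)
#' @return a [RunSchedule-class]
#' @export
runSchedule <- function(endTime = 2000, recordInterval = 5,
                        checkpointInterval = 0, outputDir = "") {
  new("RunSchedule", endTime = endTime, recordInterval = recordInterval,
      checkpointInterval = checkpointInterval, outputDir = outputDir)
}

#' Assemble a full simulation configuration
#'
#' @param init an [InitConfig-class]
#' @param params a [ModelParams-class]
#' @param schedule a [RunSchedule-class]
#' @return a [SimulationConfig-class]
#' @examples
#' cfg <- simulationConfig(
#'   init = initConfig(nCells = 250, boxSize = 25, patchSize = 10, seed = 1),
#'   params = modelParams(p0Active = 3.60, p0Passive = 3.80),
#'   schedule = runSchedule(endTime = 400))
#' @export
simulationConfig <- function(init = initConfig(),
                             params = modelParams(),
                             schedule = runSchedule()) {
  new("SimulationConfig", init = init, params = params, schedule = schedule)
}

#' Read a run configuration file
#'
#' JSON file with the flat keys `n_cells`, `box_size`, `patch_size`,
#' `lloyd_tol`, `mirror_cutoff`, `clamp_rings`, `p0_active`, `p0_passive`,
#' `target_perimeter_mean`, `target_perimeter_sd`, `seed` plus the
#' optional `k_area`, `growth_rate`, `alpha`, `beta`, `ell_t1`, `dt`,
#' `t_rel`, `t_end`, `event_check_interval`, `record_interval`. Missing
#' keys fall back to the package defaults.
#'
#' @param path JSON file
#' @return a [SimulationConfig-class]
#' @export
readRunConfig <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(key, default) if (!is.null(doc[[key]])) doc[[key]] else default
  init <- initConfig(
    nCells = pick("n_cells", 1000),
    boxSize = pick("box_size", 50),
    patchSize = pick("patch_size", 20),
    lloydTol = pick("lloyd_tol", 5e-5),
    mirrorCutoff = doc[["mirror_cutoff"]],
    clampRings = pick("clamp_rings", 1),
    seed = pick("seed", NA_real_))
  params <- modelParams(
    p0Active = pick("p0_active", 3.60),
    p0Passive = pick("p0_passive", 3.80),
    areaModulus = pick("k_area", 3.0),
    growthRate = pick("growth_rate", 2e-3),
    divisionSensitivity = pick("alpha", 8.0),
    ingressionSensitivity = pick("beta", 6.0),
    t1Threshold = pick("ell_t1", 5e-3),
    timeStep = pick("dt", 5e-3),
    relaxTime = pick("t_rel", 50),
    eventCheckInterval = pick("event_check_interval", 5),
    targetPerimeterMean = pick("target_perimeter_mean", 5.98),
    targetPerimeterSd = pick("target_perimeter_sd", 0.3))
  schedule <- runSchedule(
    endTime = pick("t_end", 2000),
    recordInterval = pick("record_interval", 5))
  simulationConfig(init = init, params = params, schedule = schedule)
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams:\n")
  cat(sprintf("  K_A = %g, K_P = %g, zeta = %g\n", object@areaModulus,
              object@perimeterModulus, object@friction))
  cat(sprintf("  p0 (active/passive) = %g / %g\n", object@p0Active,
              object@p0Passive))
  cat(sprintf("  g = %g, alpha = %g, beta = %g, A_d = %s, A_i = %s\n",
              object@growthRate, object@divisionSensitivity,
              object@ingressionSensitivity,
              format(object@divisionArea), format(object@ingressionArea)))
  cat(sprintf("  ell_T1 = %g, dt = %g, t_rel = %g, event sweep every %g steps\n",
              object@t1Threshold, object@timeStep, object@relaxTime,
              object@eventCheckInterval))
  cat(sprintf("  target perimeter ~ Normal(%g, %g); passive P0 = %g\n",
              object@targetPerimeterMean, object@targetPerimeterSd,
              object@passivePerimeter))
})

setMethod("show", "InitConfig", function(object) {
  cat(sprintf("InitConfig: N = %g in [0, %g]^2, patch %g x %g\n",
              object@nCells, object@boxSize, object@patchSize,
              object@patchSize))
  cat(sprintf("  Lloyd tol %g (of L), mirror cutoff %g, clamp rings %g, seed %s\n",
              object@lloydTol, object@mirrorCutoff, object@clampRings,
              format(object@seed)))
})

setMethod("show", "SimulationConfig", function(object) {
  show(object@init)
  show(object@params)
  cat(sprintf("Schedule: t_end = %g, record every %g steps\n",
              object@schedule@endTime, object@schedule@recordInterval))
})

setMethod("show", "GrowthState", function(object) {
  cat(sprintf(
    "GrowthState: mean active area %.4f at t = %g (A_i = %.4f, A_d = %.4f)\n",
    object@referenceArea, object@referenceTime, object@ingressionArea,
    object@divisionArea))
})
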