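#' @include simulation.R
NULL

#' Fractional changes in active cell number and area
#'
#' `f_N(t) = N_a(t) / N_a(t_ref)` and `f_A(t) = A_a(t) / A_a(t_ref)`.
#' The reference is either the configuration before passive relaxation
#' (`"initial"`, t_ref = 0) or after it (`"relaxed"`, t_ref = t_rel).
#' `f_N` is insensitive to the choice because the cell count does not
#' change during relaxation; `f_A` differs by the passive area
#' relaxation.
#'
#' @param result a [SimulationResult-class]
#' @param reference "relaxed" or "initial"
#' @return data.frame with columns `time`, `fN`, `fA`
#' @export
fractionalChanges <- function(result, reference = c("relaxed", "initial")) {
  reference <- match.arg(reference)
  refs <- result@references
  nRef <- if (reference == "relaxed") refs[["nActiveRel"]] else refs[["nActive0"]]
  aRef <- if (reference == "relaxed") refs[["activeAreaRel"]] else refs[["activeArea0"]]
  if (!(nRef > 0) || !(aRef > 0)) stop("zero reference population")
  data.frame(time = result@series$time,
             fN = result@series$nActive / nRef,
             fA = result@series$activeArea / aRef)
}

#' Realised shape index of the active tissue
#'
#' Per-cell `p = P_c / sqrt(A_c)` over the live active cells; reports the
#' mean and the population standard deviation. A regular-hexagon tiling
#' gives ~3.722 with zero spread.
#'
#' @param mesh a [TissueMesh-class]
#' @return named numeric: `mean`, `sd`
#' @export
realisedShapeIndex <- function(mesh) {
  act <- activeCells(mesh)
  if (!length(act)) stop("no active cells")
  p <- cellPerimeter(mesh, act) / sqrt(cellArea(mesh, act))
  m <- mean(p)
  c(mean = m, sd = sqrt(mean((p - m)^2)))
}

#' Mean homeostatic pressures by population
#'
#' Arithmetic means of the per-cell pressure `-K_A (A_c - A_c0)` over
#' the active and passive populations of one mesh state. (Time averaging
#' over a steady window is done by [steadyStateSummary()].) An empty
#' population reports NA.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @return named numeric: `active`, `passive`
#' @export
meanPressures <- function(mesh, params) {
  act <- activeCells(mesh)
  pas <- passiveCells(mesh)
  p <- cellPressure(mesh, params)
  c(active = if (length(act)) mean(p[as.character(act)]) else NA_real_,
    passive = if (length(pas)) mean(p[as.character(pas)]) else NA_real_)
}

#' Neighbour-count distribution of the active tissue
#'
#' Fraction of live active cells with n neighbours (distinct cells
#' sharing at least one junction; for interior cells of a confluent
#' tiling this equals the vertex count). Fractions sum to one.
#'
#' @param mesh a [TissueMesh-class]
#' @return named numeric vector of fractions, names the observed n
#' @export
neighbourDistribution <- function(mesh) {
  act <- activeCells(mesh)
  if (!length(act)) stop("no active cells")
  n <- neighbourCount(mesh, act)
  tab <- table(n)
  as.numeric(tab) / length(act) -> fr
  names(fr) <- names(tab)
  fr
}

#' Steady-state summary over a homeostasis window
#'
#' Time means (and standard deviations) of the sampled observables over
#' the window `[tStart, tStart + window]`: fractional changes, mean
#' pressures, realised shape index, and the mean neighbour-count
#' fractions. Standard deviations use the population convention
#' (divide by the number of samples). By default the window is the final
#' 500 time units of the series, matching the usual averaging interval.
#'
#' @param x a [SimulationResult-class] or its series data.frame
#' @param tStart window start (default: end of series minus `window`)
#' @param window window width in time units
#' @return a [SteadyStateSummary-class]
#' @export
steadyStateSummary <- function(x, tStart = NULL, window = 500) {
  series <- if (is(x, "SimulationResult")) x@series else x
  if (is.null(series$fN))
    stop("series lacks fN/fA columns; pass a SimulationResult")
  tMax <- max(series$time)
  if (is.null(tStart)) tStart <- tMax - window
  sel <- series$time >= tStart & series$time <= tStart + window
  if (sum(sel) < 2)
    stop("steady-state window holds fewer than 2 samples")
  s <- series[sel, ]
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  histCols <- c(paste0("n", 3:12), "n13plus")
  histMean <- colMeans(s[, histCols] / s$nActive)
  names(histMean) <- c(as.character(3:12), "13+")
  new("SteadyStateSummary",
      fN = mean(s$fN), fA = mean(s$fA),
      fNSd = popSd(s$fN), fASd = popSd(s$fA),
      pressureActive = mean(s$meanPressureActive),
      pressurePassive = mean(s$meanPressurePassive),
      shapeIndexMean = mean(s$shapeIndexMean),
      shapeIndexSd = mean(s$shapeIndexSd),
      neighbourFractions = histMean,
      window = c(tStart, tStart + window), nSamples = sum(sel))
}

setMethod("show", "SteadyStateSummary", function(object) {
  cat(sprintf("SteadyStateSummary over t = [%g, %g] (%d samples)\n",
              object@window[1], object@window[2], object@nSamples))
  cat(sprintf("  fN = %.4f (sd %.4f), fA = %.4f (sd %.4f)\n", object@fN,
              object@fNSd, object@fA, object@fASd))
  cat(sprintf("  pressures: active %.4f, passive %.4f (ratio %.3f)\n",
              object@pressureActive, object@pressurePassive,
              object@pressureActive / object@pressurePassive))
  cat(sprintf("  realised shape index %.4f (sd %.4f)\n",
              object@shapeIndexMean, object@shapeIndexSd))
  top <- sort(object@neighbourFractions, decreasing = TRUE)[1:3]
  cat("  neighbour fractions:",
      paste(sprintf("P_%s = %.3f", names(top), top), collapse = ", "), "\n")
})

#' Write the observable series as CSV
#'
#' One row per sample with all sampled quantities, the neighbour-count
#' histogram in columns n3..n12 plus overflow, and the fN/fA columns.
#' Standard deviations reported elsewhere use the population convention.
#'
#' @param result a [SimulationResult-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeObservablesCsv <- function(result, path) {
  utils::write.csv(result@series, path, row.names = FALSE)
  invisible(path)
}

#' Write the event log as CSV
#'
#' @param result a [SimulationResult-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEventsCsv <- function(result, path) {
  utils::write.csv(result@events, path, row.names = FALSE)
  invisible(path)
}
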