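#' @include mesh-core.R params.R
NULL

#' Division probability
#'
#' Logistic in the actual cell area: `1 / (1 + exp(-alpha (A - A_d)))`,
#' equal to 1/2 at `A = A_d` and increasing with area. Evaluated through
#' the numerically stable branch, so extreme areas neither overflow nor
#' underflow to values outside (0, 1).
#'
#' @param area numeric vector of cell areas
#' @param params a [ModelParams-class] with `divisionArea` set, or a
#'   [GrowthState-class] via `growth`
#' @param growth optional [GrowthState-class] overriding `divisionArea`
#' @return probabilities in (0, 1)
#' @examples
#' p <- modelParams(divisionArea = 4, ingressionArea = 0.75)
#' divisionProbability(4, p)  # exactly 0.5
#' @export
divisionProbability <- function(area, params, growth = NULL) {
  Ad <- if (!is.null(growth)) growth@divisionArea else params@divisionArea
  if (is.na(Ad)) stop("divisionArea is unset; measure the growth state first")
  cpp_division_probability(as.numeric(area), params@divisionSensitivity, Ad)
}

#' Ingression probability
#'
#' Logistic decreasing in area: `1 / (1 + exp(+beta (A - A_i)))`, equal
#' to 1/2 at `A = A_i`; small cells are removed preferentially.
#'
#' @inheritParams divisionProbability
#' @return probabilities in (0, 1)
#' @export
ingressionProbability <- function(area, params, growth = NULL) {
  Ai <- if (!is.null(growth)) growth@ingressionArea else params@ingressionArea
  if (is.na(Ai)) stop("ingressionArea is unset; measure the growth state first")
  cpp_ingression_probability(as.numeric(area), params@ingressionSensitivity, Ai)
}

#' Cell long axis (gyration tensor)
#'
#' Principal eigenvector of the 2 x 2 gyration tensor of the cell's
#' vertex positions about their mean. A degenerate spectrum (relative
#' eigenvalue gap below 1e-9, e.g. squares or regular hexagons) yields a
#' uniformly random unit vector drawn from the R RNG and is flagged.
#'
#' @param mesh a [TissueMesh-class]
#' @param cells cell ids, or NULL for every live cell
#' @return matrix with columns `x`, `y` (unit vectors) and attribute
#'   `degenerate` (logical per requested cell)
#' @export
longAxis <- function(mesh, cells = NULL) {
  cells <- .checkCells(mesh, cells)
  res <- cpp_long_axes(.meshToList(mesh))
  out <- res$axis[cells, , drop = FALSE]
  colnames(out) <- c("x", "y")
  rownames(out) <- cells
  attr(out, "degenerate") <- res$degenerate[cells]
  out
}

#' Measure the growth reference state
#'
#' Mean area of active cells (arithmetic mean over the active population
#' only), setting the half-probability areas: division at 1.6 x the mean
#' and ingression at 0.3 x the mean. Called once at the end of passive
#' relaxation; the state is frozen afterwards.
#'
#' @param mesh the relaxed [TissueMesh-class]
#' @return a [GrowthState-class]
#' @export
measureGrowthState <- function(mesh) {
  act <- activeCells(mesh)
  if (!length(act)) stop("no active cells to measure")
  aRef <- mean(cellArea(mesh, act))
  new("GrowthState", referenceArea = aRef, divisionArea = 1.6 * aRef,
      ingressionArea = 0.3 * aRef, referenceTime = mesh@time)
}

#' Grow active target areas
#'
#' One time step of the linear growth law: every active cell's target
#' area increases by `growthRate x timeStep` and its target perimeter is
#' reset to `p0Active x sqrt(targetArea)`, keeping the target shape index
#' constant. Passive targets never change.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param steps number of growth increments to apply
#' @return the modified mesh
#' @export
growTargets <- function(mesh, params, steps = 1) {
  act <- which(mesh@cells$alive & mesh@cells$kind == 0L)
  if (length(act)) {
    mesh@cells$targetArea[act] <- mesh@cells$targetArea[act] +
      steps * params@growthRate * params@timeStep
    mesh@cells$targetPerimeter[act] <-
      params@p0Active * sqrt(mesh@cells$targetArea[act])
  }
  mesh
}

#' Division sweep
#'
#' Visits every live active cell in ascending id order; each draws one
#' uniform number and divides when it falls below its division
#' probability, along the line through the centroid perpendicular to the
#' long axis (Hertwig's rule). Each daughter draws an independent target
#' perimeter from Normal(mu, sigma) with target area `(P0 / p0Active)^2`.
#' Geometrically rejected divisions are reported and leave the parent in
#' place.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param growth a [GrowthState-class]
#' @return list with `mesh`, `events` (data.frame: cell, daughter1,
#'   daughter2), and `rejected` (cell ids)
#' @export
sweepDivisions <- function(mesh, params, growth) {
  ids <- which(mesh@cells$alive & mesh@cells$kind == 0L)
  events <- list()
  rejected <- integer()
  for (cc in ids) {
    if (!mesh@cells$alive[cc]) next
    u <- stats::runif(1)
    a <- unname(cellArea(mesh, cc))
    if (u >= divisionProbability(a, params, growth)) next
    ax <- longAxis(mesh, cc)
    res <- insertDivisionEdge(mesh, cc, ax[1, ])
    if (!res$ok) {
      rejected <- c(rejected, cc)
      next
    }
    mesh <- res$mesh
    for (d in res$daughters) {
      p0 <- stats::rnorm(1, params@targetPerimeterMean,
                         params@targetPerimeterSd)
      while (p0 <= 0)
        p0 <- stats::rnorm(1, params@targetPerimeterMean,
                           params@targetPerimeterSd)
      mesh@cells$targetPerimeter[d] <- p0
      mesh@cells$targetArea[d] <- (p0 / params@p0Active)^2
    }
    events[[length(events) + 1]] <-
      data.frame(cell = cc, daughter1 = res$daughters[1],
                 daughter2 = res$daughters[2])
  }
  list(mesh = mesh,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(cell = integer(), daughter1 = integer(),
                                daughter2 = integer()),
       rejected = rejected)
}

#' Ingression sweep
#'
#' Visits the live active cells in ascending id order (cells divided in
#' the same sweep, and their daughters, are exempt until the next sweep:
#' pass the pre-division id set via `eligible`). Each draws one uniform
#' number and ingresses when it falls below its ingression probability:
#' the cell collapses to a vertex ([collapseCell()]) and the produced
#' high-coordination vertex is resolved ([resolveVertex()]).
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @param growth a [GrowthState-class]
#' @param eligible cell ids eligible this sweep (default: current live
#'   active cells)
#' @return list with `mesh`, `events` (data.frame: cell, newVertex),
#'   and `rejected` (cell ids whose collapse was rejected)
#' @export
sweepIngressions <- function(mesh, params, growth, eligible = NULL) {
  if (is.null(eligible))
    eligible <- which(mesh@cells$alive & mesh@cells$kind == 0L)
  events <- list()
  rejected <- integer()
  for (cc in eligible) {
    if (!mesh@cells$alive[cc]) next
    u <- stats::runif(1)
    a <- unname(cellArea(mesh, cc))
    if (u >= ingressionProbability(a, params, growth)) next
    res <- collapseCell(mesh, cc)
    if (!res$ok) {
      rejected <- c(rejected, cc)
      next
    }
    mesh <- res$mesh
    mesh <- resolveVertex(mesh, res$newVertex, params)$mesh
    events[[length(events) + 1]] <-
      data.frame(cell = cc, newVertex = res$newVertex)
  }
  list(mesh = mesh,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(cell = integer(), newVertex = integer()),
       rejected = rejected)
}
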