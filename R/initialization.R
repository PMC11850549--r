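#' @include mesh-core.R
NULL

#' Lloyd relaxation towards a centroidal Voronoi tessellation
#'
#' Iteratively moves every seed to the area centroid of its Voronoi tile
#' until the maximum per-seed displacement between consecutive iterations,
#' relative to the box side, drops below `tol`. Seeds within `cutoff` of a
#' wall are mirrored across it, so tiles end exactly on the box walls
#' (straight boundaries); tiles are additionally clipped to the box.
#'
#' @param points two-column matrix of seed positions inside the box
#' @param boxSize box side L
#' @param tol stopping tolerance (relative to L)
#' @param cutoff mirroring depth; default 2 L / sqrt(n)
#' @param maxIterations iteration cap; exceeding it is an error that
#'   reports the residual reached
#' @return matrix of relaxed positions with attributes `iterations` and
#'   `residual`
#' @examples
#' p <- lloydRelax(matrix(c(10, 12), 1), boxSize = 20)
#' stopifnot(max(abs(p - 10)) < 1e-3)  # single seed ends at the box centre
#' @export
lloydRelax <- function(points, boxSize, tol = 5e-5, cutoff = NULL,
                       maxIterations = 20000) {
  points <- matrix(points, ncol = 2)
  if (any(points < 0) || any(points > boxSize))
    stop("all seed points must lie inside the box")
  if (is.null(cutoff)) cutoff <- 2 * boxSize / sqrt(nrow(points))
  res <- cpp_lloyd(points[, 1], points[, 2], boxSize, tol, cutoff,
                   as.integer(maxIterations))
  if (!res$converged)
    stop(sprintf(
      "Lloyd iteration did not converge in %d iterations (residual %.3g)",
      maxIterations, res$residual))
  out <- cbind(res$x, res$y)
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  out
}

#' Build a tissue mesh from explicit polygons
#'
#' Low-level constructor shared by the Voronoi initial condition and the
#' deterministic test fixtures. Vertices closer than the merge tolerance
#' are identified, so independently supplied tiles sharing edges produce
#' a consistent half-edge structure. Cell targets are set to each cell's
#' actual area and perimeter (a zero-energy state) and every cell starts
#' passive, generation 0.
#'
#' @param polys list of two-column matrices (one polygon per cell, any
#'   winding; counterclockwise is enforced internally)
#' @param boxSize box side stored on the mesh
#' @param patchSize active patch side stored on the mesh
#' @param snapWalls snap coordinates within 1e-7 of the box walls exactly
#'   onto them
#' @return a [TissueMesh-class]
#' @export
meshFromPolygons <- function(polys, boxSize, patchSize = 0,
                             snapWalls = FALSE) {
  lst <- cpp_build_mesh(polys, boxSize, patchSize, snapWalls)
  mesh <- .listToMesh(lst)
  g <- cpp_cell_geometry(.meshToList(mesh))
  alive <- mesh@cells$alive
  mesh@cells$targetArea[alive] <- g$area[alive]
  mesh@cells$targetPerimeter[alive] <- g$perimeter[alive]
  mesh
}

# clamp wall vertices plus `rings` rings of their neighbours
.clampBoundary <- function(mesh, rings = 1) {
  v <- mesh@vertices
  j <- mesh@junctions
  L <- mesh@boxSize
  onWall <- v$alive & (v$x == 0 | v$x == L | v$y == 0 | v$y == L)
  clamped <- onWall
  keep <- j$alive
  a <- j$origin[keep]
  b <- j$origin[j$twin[keep]]
  for (r in seq_len(rings)) {
    hit <- clamped[a] | clamped[b]
    clamped[a[hit]] <- TRUE
    clamped[b[hit]] <- TRUE
  }
  mesh@vertices$clamped <- clamped
  mesh
}

#' Build the initial clamped tiling
#'
#' Places N random seeds in the box, relaxes them to a centroidal Voronoi
#' tessellation ([lloydRelax()]), builds the half-edge mesh from the
#' final tiles, and clamps the outermost vertex layers (wall vertices
#' plus `clampRings` rings). The mesh is confluent: live cell areas sum
#' to L^2. Cell types and targets are not assigned here; see
#' [assignTypesAndTargets()].
#'
#' @param config an [InitConfig-class]. Its `seed` (when not NA) seeds
#'   the RNG before the seed points are drawn.
#' @return a [TissueMesh-class]
#' @export
buildInitialTiling <- function(config) {
  stopifnot(is(config, "InitConfig"))
  if (!is.na(config@seed)) set.seed(config@seed)
  L <- config@boxSize
  n <- as.integer(config@nCells)
  pts <- cbind(stats::runif(n, 0, L), stats::runif(n, 0, L))
  relaxed <- lloydRelax(pts, L, tol = config@lloydTol,
                        cutoff = config@mirrorCutoff,
                        maxIterations = config@maxIterations)
  polys <- cpp_voronoi_polys(relaxed[, 1], relaxed[, 2], L,
                             config@mirrorCutoff)
  mesh <- meshFromPolygons(polys, boxSize = L,
                           patchSize = config@patchSize, snapWalls = TRUE)
  mesh <- .clampBoundary(mesh, rings = config@clampRings)
  bad <- validateMesh(mesh)
  if (length(bad))
    stop("initial tiling failed validation: ", paste(bad, collapse = "; "))
  mesh
}

#' Assign cell types and target properties
#'
#' Cells whose area centroid falls in the centred half-open square
#' `[c - La/2, c + La/2)` become active, the rest passive. Active cells
#' draw target perimeters from Normal(mu, sigma) (resampled while
#' non-positive) with target area `(P0 / p0Active)^2`; passive cells get
#' the fixed targets `passivePerimeter` and
#' `(passivePerimeter / p0Passive)^2`. Draws consume the R RNG in cell-id
#' order, so a fixed seed reproduces the assignment exactly.
#'
#' @param mesh a [TissueMesh-class] (typically from [buildInitialTiling()])
#' @param params a [ModelParams-class]
#' @return the typed mesh
#' @export
assignTypesAndTargets <- function(mesh, params) {
  stopifnot(is(params, "ModelParams"))
  alive <- which(mesh@cells$alive)
  cen <- cellCentroid(mesh, alive)
  c0 <- mesh@boxSize / 2
  half <- mesh@patchSize / 2
  inPatch <- cen[, 1] >= c0 - half & cen[, 1] < c0 + half &
             cen[, 2] >= c0 - half & cen[, 2] < c0 + half
  mesh@cells$kind[alive] <- ifelse(inPatch, 0L, 1L)
  nAct <- sum(inPatch)
  p0 <- stats::rnorm(nAct, params@targetPerimeterMean,
                     params@targetPerimeterSd)
  while (any(p0 <= 0))
    p0[p0 <= 0] <- stats::rnorm(sum(p0 <= 0), params@targetPerimeterMean,
                                params@targetPerimeterSd)
  act <- alive[inPatch]
  mesh@cells$targetPerimeter[act] <- p0
  mesh@cells$targetArea[act] <- (p0 / params@p0Active)^2
  pas <- alive[!inPatch]
  mesh@cells$targetPerimeter[pas] <- params@passivePerimeter
  mesh@cells$targetArea[pas] <- (params@passivePerimeter /
                                   params@p0Passive)^2
  mesh
}

#' Regular honeycomb test fixture
#'
#' A rows x cols patch of regular hexagons with the given side length,
#' every cell at its target (area 3 sqrt(3)/2 side^2, perimeter 6 side;
#' shape index 6 / sqrt(3 sqrt(3)/2) ~ 3.722), so the configuration is an
#' exact zero-force energy minimum. No vertex is clamped.
#'
#' @param rows,cols patch dimensions (>= 1)
#' @param side hexagon side length
#' @param kind "active" or "passive" for every cell
#' @return a [TissueMesh-class]
#' @examples
#' hx <- makeHexagonalFixture(3, 3)
#' range(cellPerimeter(hx) / sqrt(cellArea(hx)))  # ~3.722
#' @export
makeHexagonalFixture <- function(rows, cols, side = 1, kind = "active") {
  stopifnot(rows >= 1, cols >= 1, side > 0)
  s <- side
  sq3 <- sqrt(3)
  ang <- pi / 3 * (0:5)
  hexX <- s * cos(ang)
  hexY <- s * sin(ang)
  polys <- list()
  shift <- 2 * s       # keep all coordinates positive
  for (q in seq_len(cols) - 1) {
    for (r in seq_len(rows) - 1) {
      cx <- 1.5 * s * q + shift
      cy <- sq3 * s * r + (q %% 2) * (sq3 / 2) * s + shift
      polys[[length(polys) + 1]] <- cbind(cx + hexX, cy + hexY)
    }
  }
  L <- 1.5 * s * cols + sq3 * s * rows + 4 * s
  mesh <- meshFromPolygons(polys, boxSize = L, patchSize = 0)
  mesh@cells$kind[mesh@cells$alive] <-
    if (match.arg(kind, c("active", "passive")) == "active") 0L else 1L
  mesh@cells$targetArea[mesh@cells$alive] <- 1.5 * sq3 * s^2
  mesh@cells$targetPerimeter[mesh@cells$alive] <- 6 * s
  mesh
}

#' Single-polygon test mesh
#'
#' One cell whose boundary is the supplied polygon; targets default to
#' the actual geometry (zero energy).
#'
#' @param coords two-column matrix of vertex positions
#' @param kind "active" or "passive"
#' @param targetArea,targetPerimeter optional explicit targets
#' @return a [TissueMesh-class]
#' @examples
#' sq <- makeSingleCellMesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' cellArea(sq)       # 1
#' cellPerimeter(sq)  # 4
#' @export
makeSingleCellMesh <- function(coords, kind = "active",
                               targetArea = NULL, targetPerimeter = NULL) {
  coords <- matrix(coords, ncol = 2)
  L <- max(abs(coords)) * 2 + 1
  mesh <- meshFromPolygons(list(coords), boxSize = L, patchSize = 0)
  mesh@cells$kind[1] <-
    if (match.arg(kind, c("active", "passive")) == "active") 0L else 1L
  if (!is.null(targetArea)) mesh@cells$targetArea[1] <- targetArea
  if (!is.null(targetPerimeter))
    mesh@cells$targetPerimeter[1] <- targetPerimeter
  mesh
}
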