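#' @include mesh-core.R params.R
NULL

#' T1 transition (cell intercalation)
#'
#' Rotates a short junction 90 degrees counterclockwise about its
#' midpoint, extends it to 1.02 x the T1 threshold, and rewires
#' connectivity so the two cells formerly sharing the junction lose one
#' vertex each while the two flanking cells gain it. Vertex and junction
#' counts, and hence the Euler characteristic, are unchanged.
#'
#' Preconditions (violations reject the move without mutating the mesh):
#' the junction is interior with unclamped 3-valent endpoints, both
#' incident cells keep at least 3 vertices, and the four participating
#' cells are distinct. Unless `force = TRUE` the junction must be shorter
#' than the threshold.
#'
#' @param mesh a [TissueMesh-class]
#' @param junction half-edge id (either direction of the pair)
#' @param params a [ModelParams-class] (supplies the threshold)
#' @param force skip the length precondition (test fixtures)
#' @return list with `mesh` (new state), `ok` (logical), and `why`
#'   (rejection reason, "" on success)
#' @export
t1Transition <- function(mesh, junction, params = modelParams(),
                         force = FALSE) {
  junction <- as.integer(junction)
  if (!force) {
    j <- mesh@junctions
    v <- mesh@vertices
    a <- j$origin[junction]; b <- j$origin[j$twin[junction]]
    len <- sqrt((v$x[a] - v$x[b])^2 + (v$y[a] - v$y[b])^2)
    if (len >= params@t1Threshold)
      return(list(mesh = mesh, ok = FALSE,
                  why = "junction not shorter than the T1 threshold"))
  }
  res <- cpp_t1(.meshToList(mesh), junction, 1.02 * params@t1Threshold)
  list(mesh = .listToMesh(res$mesh), ok = res$ok, why = res$why)
}

#' T2 transition (cell collapse for ingression)
#'
#' Removes a cell by collapsing all its vertices into a single new vertex
#' at the cell centroid. For an n-gon this removes n - 1 vertices, n
#' undirected junctions and one face, preserving the Euler
#' characteristic; the new vertex typically has coordination above 3 and
#' should be passed to [resolveVertex()]. Rejected when the cell touches
#' a clamped vertex or the boundary, when a neighbour would drop below 3
#' vertices, or when a neighbour is shared across more than one junction.
#'
#' @param mesh a [TissueMesh-class]
#' @param cell cell id
#' @return list with `mesh`, `ok`, `why`, and `newVertex` (id of the
#'   produced vertex, NA on rejection)
#' @export
collapseCell <- function(mesh, cell) {
  res <- cpp_collapse(.meshToList(mesh), as.integer(cell))
  list(mesh = .listToMesh(res$mesh), ok = res$ok, why = res$why,
       newVertex = if (res$ok) res$newVertex else NA_integer_)
}

#' Resolve a high-coordination vertex
#'
#' Repeatedly splits a vertex of coordination 4 or more into two vertices
#' joined by a new junction of length 1.02 x the T1 threshold, choosing
#' uniformly at random (from the R RNG) among admissible cuts: the two
#' cut faces must be distinct and each side must keep at least two
#' incident junctions. An n-valent vertex resolves in exactly n - 3
#' splits, after which every produced vertex is 3-valent.
#'
#' @param mesh a [TissueMesh-class]
#' @param vertex vertex id
#' @param params a [ModelParams-class]
#' @return list with `mesh` and `splits` (number of splits performed)
#' @export
resolveVertex <- function(mesh, vertex, params = modelParams()) {
  res <- cpp_resolve(.meshToList(mesh), as.integer(vertex),
                     1.02 * params@t1Threshold)
  list(mesh = .listToMesh(res$mesh), splits = res$splits)
}

#' Insert a division edge
#'
#' Cuts a cell along the line through its area centroid perpendicular to
#' `axis` (a unit vector; under Hertwig's rule the cell's long axis).
#' The two crossed junctions are split by new vertices at the
#' intersections (an intersection within `tol` of an existing vertex
#' reuses it), a new junction joins them, and the cell is replaced by two
#' daughters of generation parent + 1 that inherit the parent's kind and
#' targets. Adds 2 vertices, 3 undirected junctions and 1 face,
#' preserving the Euler characteristic. Pathological cuts (not exactly
#' two crossings, or a daughter below 3 vertices) are rejected without
#' mutation.
#'
#' @param mesh a [TissueMesh-class]
#' @param cell cell id
#' @param axis numeric length 2, the division (long) axis
#' @param tol vertex-reuse tolerance in length units
#' @return list with `mesh`, `ok`, `why`, and `daughters` (two cell ids)
#' @export
insertDivisionEdge <- function(mesh, cell, axis, tol = 1e-9) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (!(n > 0)) stop("axis must be a non-zero vector")
  res <- cpp_divide(.meshToList(mesh), as.integer(cell),
                    axis[1] / n, axis[2] / n, tol)
  list(mesh = .listToMesh(res$mesh), ok = res$ok, why = res$why,
       daughters = if (res$ok) res$daughters else c(NA_integer_, NA_integer_))
}

#' Convert encircled cells
#'
#' Any cell whose neighbours are all of the opposite type flips type
#' (intercalations occasionally push a cell fully into the other
#' population). A passive-to-active flip draws a fresh target perimeter
#' from Normal(mu, sigma) with target area `(P0 / p0Active)^2`; an
#' active-to-passive flip resets the fixed passive targets. Flips are
#' determined simultaneously and applied in ascending cell id order.
#'
#' @param mesh a [TissueMesh-class]
#' @param params a [ModelParams-class]
#' @return list with `mesh` and `cells` (ids flipped, possibly empty)
#' @export
convertEncircledCells <- function(mesh, params = modelParams()) {
  res <- cpp_convert_encircled(.meshToList(mesh), .paramsToList(params))
  list(mesh = .listToMesh(res$mesh), cells = res$cells)
}
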