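#' @include AllGenerics.R
NULL

# ---- internal: S4 <-> flat list used by the C++ core ------------------------

.meshToList <- function(mesh) {
  v <- mesh@vertices; j <- mesh@junctions; cl <- mesh@cells
  list(
    vx = v$x, vy = v$y, vclamped = v$clamped, valive = v$alive,
    h_origin = j$origin, h_twin = j$twin, h_next = j$nxt, h_prev = j$prev,
    h_cell = j$cell, h_alive = j$alive,
    c_kind = cl$kind, c_A0 = cl$targetArea, c_P0 = cl$targetPerimeter,
    c_gen = cl$generation, c_alive = cl$alive, c_he = cl$halfedge,
    L = mesh@boxSize, La = mesh@patchSize, time = mesh@time
  )
}

.listToMesh <- function(lst) {
  new("TissueMesh",
    vertices = data.frame(x = lst$vx, y = lst$vy, clamped = lst$vclamped,
                          alive = lst$valive),
    junctions = data.frame(origin = lst$h_origin, twin = lst$h_twin,
                           nxt = lst$h_next, prev = lst$h_prev,
                           cell = lst$h_cell, alive = lst$h_alive),
    cells = data.frame(kind = lst$c_kind, targetArea = lst$c_A0,
                       targetPerimeter = lst$c_P0, generation = lst$c_gen,
                       alive = lst$c_alive, halfedge = lst$c_he),
    boxSize = lst$L, patchSize = lst$La, time = lst$time)
}

.checkCells <- function(mesh, cells) {
  alive <- which(mesh@cells$alive)
  if (is.null(cells)) return(alive)
  cells <- as.integer(cells)
  bad <- cells[!cells %in% alive]
  if (length(bad))
    stop("cells not alive in this mesh: ", paste(bad, collapse = ", "))
  cells
}

# ---- accessors --------------------------------------------------------------

#' @describeIn TissueMesh-accessors number of live cells
#' @export
setMethod("nCells", "TissueMesh", function(x) sum(x@cells$alive))

#' Mesh accessors
#'
#' Sizes, geometry and composition of a [TissueMesh-class].
#' `cellArea`, `cellPerimeter` and `cellCentroid` are the shoelace area,
#' junction-length sum and area centroid of the counterclockwise vertex
#' loop of each requested live cell. `neighbourCount` counts distinct
#' cells sharing at least one junction. With `cells = NULL` all live
#' cells are reported, named by cell id.
#'
#' @param x,mesh a [TissueMesh-class]
#' @param cells integer cell ids, or NULL for every live cell
#' @name TissueMesh-accessors
NULL

#' @describeIn TissueMesh-accessors number of live vertices
#' @export
setMethod("nVertices", "TissueMesh", function(x) sum(x@vertices$alive))

#' @describeIn TissueMesh-accessors number of live undirected junctions
#' @export
setMethod("nJunctions", "TissueMesh",
          function(x) sum(x@junctions$alive) %/% 2L)

#' @describeIn TissueMesh-accessors box side length L
#' @export
setMethod("boxSize", "TissueMesh", function(x) x@boxSize)

#' @describeIn TissueMesh-accessors active patch side length La
#' @export
setMethod("patchSize", "TissueMesh", function(x) x@patchSize)

#' @describeIn TissueMesh-accessors current simulation time
#' @export
setMethod("simTime", "TissueMesh", function(x) x@time)

#' @describeIn TissueMesh-accessors cell kinds as a factor
#'   (active/passive)
#' @export
setMethod("cellKind", "TissueMesh", function(x, cells = NULL) {
  cells <- .checkCells(x, cells)
  structure(factor(c("active", "passive")[x@cells$kind[cells] + 1L],
                   levels = c("active", "passive")), names = cells)
})

#' @describeIn TissueMesh-accessors ids of live active cells
#' @export
setMethod("activeCells", "TissueMesh",
          function(x) which(x@cells$alive & x@cells$kind == 0L))

#' @describeIn TissueMesh-accessors ids of live passive cells
#' @export
setMethod("passiveCells", "TissueMesh",
          function(x) which(x@cells$alive & x@cells$kind == 1L))

#' @describeIn TissueMesh-accessors ids of all live cells
#' @export
setMethod("aliveCells", "TissueMesh", function(x) which(x@cells$alive))

#' @describeIn TissueMesh-accessors signed shoelace areas (positive for
#'   the counterclockwise orientation invariant)
#' @export
setMethod("cellArea", "TissueMesh", function(mesh, cells = NULL) {
  cells <- .checkCells(mesh, cells)
  g <- cpp_cell_geometry(.meshToList(mesh))
  structure(g$area[cells], names = cells)
})

#' @describeIn TissueMesh-accessors perimeters
#' @export
setMethod("cellPerimeter", "TissueMesh", function(mesh, cells = NULL) {
  cells <- .checkCells(mesh, cells)
  g <- cpp_cell_geometry(.meshToList(mesh))
  structure(g$perimeter[cells], names = cells)
})

#' @describeIn TissueMesh-accessors area centroids, one row per cell
#' @export
setMethod("cellCentroid", "TissueMesh", function(mesh, cells = NULL) {
  cells <- .checkCells(mesh, cells)
  g <- cpp_cell_geometry(.meshToList(mesh))
  out <- cbind(x = g$cx[cells], y = g$cy[cells])
  rownames(out) <- cells
  out
})

#' @describeIn TissueMesh-accessors distinct adjacent cells per cell
#' @export
setMethod("neighbourCount", "TissueMesh", function(mesh, cells = NULL) {
  cells <- .checkCells(mesh, cells)
  n <- cpp_neighbour_counts(.meshToList(mesh))
  structure(n[cells], names = cells)
})

#' Junction lengths
#'
#' Length of every live junction, named by the id of the half-edge with
#' the smaller id of each twin pair. Interior junctions appear once.
#'
#' @param mesh a [TissueMesh-class]
#' @param interiorOnly drop junctions bordering the outer face
#' @return named numeric vector
#' @export
junctionLengths <- function(mesh, interiorOnly = FALSE) {
  j <- mesh@junctions
  v <- mesh@vertices
  keep <- j$alive & seq_len(nrow(j)) < j$twin
  if (interiorOnly) keep <- keep & j$cell > 0L & j$cell[j$twin] > 0L
  idx <- which(keep)
  a <- j$origin[idx]
  b <- j$origin[j$twin[idx]]
  structure(sqrt((v$x[a] - v$x[b])^2 + (v$y[a] - v$y[b])^2), names = idx)
}

#' Compact a mesh
#'
#' Drops tombstoned (dead) vertices, junctions and cells and renumbers the
#' survivors densely. Ids change, so event logs referencing the old ids no
#' longer resolve; compaction is meant for long interactive sessions or
#' stress workloads where the tombstone backlog dominates memory, not for
#' mid-run bookkeeping.
#'
#' @param mesh a [TissueMesh-class]
#' @return an equivalent mesh with dense ids
#' @export
compactMesh <- function(mesh) {
  v <- mesh@vertices; j <- mesh@junctions; cl <- mesh@cells
  vmap <- integer(nrow(v)); vmap[v$alive] <- seq_len(sum(v$alive))
  jmap <- integer(nrow(j)); jmap[j$alive] <- seq_len(sum(j$alive))
  cmap <- integer(nrow(cl)); cmap[cl$alive] <- seq_len(sum(cl$alive))
  jn <- j[j$alive, ]
  jn$origin <- vmap[jn$origin]
  jn$twin <- jmap[jn$twin]
  jn$nxt <- jmap[jn$nxt]
  jn$prev <- jmap[jn$prev]
  interior <- jn$cell > 0L   # outer-face id 0 must not index the cell map
  jn$cell[interior] <- cmap[jn$cell[interior]]
  cn <- cl[cl$alive, ]
  cn$halfedge <- jmap[cn$halfedge]
  vn <- v[v$alive, ]
  rownames(vn) <- rownames(jn) <- rownames(cn) <- NULL
  new("TissueMesh", vertices = vn, junctions = jn, cells = cn,
      boxSize = mesh@boxSize, patchSize = mesh@patchSize,
      time = mesh@time)
}

#' Move vertices
#'
#' Low-level geometric edit used to build test configurations (e.g.
#' shrinking a junction below the T1 threshold). Clamped vertices may only
#' be moved when `force = TRUE`.
#'
#' @param mesh a [TissueMesh-class]
#' @param ids vertex ids
#' @param xy two-column matrix of new positions
#' @param force allow moving clamped vertices
#' @return the modified mesh
#' @export
setVertexPositions <- function(mesh, ids, xy, force = FALSE) {
  ids <- as.integer(ids)
  xy <- matrix(xy, ncol = 2)
  if (!force && any(mesh@vertices$clamped[ids]))
    stop("refusing to move clamped vertices (use force = TRUE)")
  mesh@vertices$x[ids] <- xy[, 1]
  mesh@vertices$y[ids] <- xy[, 2]
  mesh
}

# ---- validation -------------------------------------------------------------

#' Structural validation of a tissue mesh
#'
#' Checks the half-edge pointer structure (twin involution, closed
#' next/prev cycles, simple cell polygons), the Euler characteristic of
#' the disk-like tiling (V - E + F = 1), positive cell areas, confluence
#' (live cell areas sum to the area enclosed by the outer boundary within
#' a relative tolerance), and minimum interior vertex degree 3.
#'
#' @param mesh a [TissueMesh-class]
#' @param relTol relative tolerance of the confluence check
#' @return character vector of violations; empty when the mesh is valid
#' @export
setMethod("validateMesh", "TissueMesh", function(mesh, relTol = 1e-6) {
  cpp_validate(.meshToList(mesh), relTol)
})

# ---- snapshot I/O -----------------------------------------------------------

#' Read and write mesh snapshots
#'
#' Self-describing JSON snapshot with a header (box size, patch size,
#' time, optional seed) and three arrays: vertices (id, x, y, clamped),
#' junctions (id, origin, twin, next, cell) and cells (id, kind, A0, P0,
#' generation). Coordinates round-trip at full double precision; `prev`
#' pointers are reconstructed from `next` on read. Only live entries are
#' written; tombstoned ids stay reserved.
#'
#' @param mesh a [TissueMesh-class]
#' @param path file path
#' @param seed optional RNG seed recorded in the header
#' @return `readMeshSnapshot` returns a [TissueMesh-class];
#'   `writeMeshSnapshot` returns `path` invisibly.
#' @export
writeMeshSnapshot <- function(mesh, path, seed = NA) {
  v <- mesh@vertices; j <- mesh@junctions; cl <- mesh@cells
  vi <- which(v$alive); ji <- which(j$alive); ci <- which(cl$alive)
  doc <- list(
    format = "epiVertex-mesh",
    version = 1L,
    header = list(L = mesh@boxSize, La = mesh@patchSize,
                  time = mesh@time, seed = seed),
    vertices = list(id = vi, x = v$x[vi], y = v$y[vi],
                    clamped = v$clamped[vi]),
    junctions = list(id = ji, origin = j$origin[ji], twin = j$twin[ji],
                     next_ = j$nxt[ji], cell = j$cell[ji]),
    cells = list(id = ci, kind = cl$kind[ci], A0 = cl$targetArea[ci],
                 P0 = cl$targetPerimeter[ci],
                 generation = cl$generation[ci])
  )
  # digits = I(17): full significant digits, so doubles round-trip exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname writeMeshSnapshot
#' @export
readMeshSnapshot <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "epiVertex-mesh"))
    stop("not an epiVertex mesh snapshot: ", path)
  nv <- max(doc$vertices$id); nj <- max(doc$junctions$id)
  nc <- max(doc$cells$id)
  v <- data.frame(x = rep(NA_real_, nv), y = NA_real_, clamped = FALSE,
                  alive = FALSE)
  v$x[doc$vertices$id] <- doc$vertices$x
  v$y[doc$vertices$id] <- doc$vertices$y
  v$clamped[doc$vertices$id] <- doc$vertices$clamped
  v$alive[doc$vertices$id] <- TRUE
  j <- data.frame(origin = rep(NA_integer_, nj), twin = NA_integer_,
                  nxt = NA_integer_, prev = NA_integer_,
                  cell = NA_integer_, alive = FALSE)
  j$origin[doc$junctions$id] <- doc$junctions$origin
  j$twin[doc$junctions$id] <- doc$junctions$twin
  j$nxt[doc$junctions$id] <- doc$junctions$next_
  j$cell[doc$junctions$id] <- doc$junctions$cell
  j$alive[doc$junctions$id] <- TRUE
  j$prev[j$nxt[doc$junctions$id]] <- doc$junctions$id
  cl <- data.frame(kind = rep(NA_integer_, nc), targetArea = NA_real_,
                   targetPerimeter = NA_real_, generation = NA_integer_,
                   alive = FALSE, halfedge = NA_integer_)
  cl$kind[doc$cells$id] <- doc$cells$kind
  cl$targetArea[doc$cells$id] <- doc$cells$A0
  cl$targetPerimeter[doc$cells$id] <- doc$cells$P0
  cl$generation[doc$cells$id] <- doc$cells$generation
  cl$alive[doc$cells$id] <- TRUE
  # representative half-edge per cell
  own <- which(j$alive & j$cell > 0L)
  cl$halfedge[j$cell[own]] <- own
  new("TissueMesh", vertices = v, junctions = j, cells = cl,
      boxSize = doc$header$L, patchSize = doc$header$La,
      time = doc$header$time)
}

#' Export a mesh as legacy-VTK polygonal data
#'
#' Writes an ASCII VTK file with one polygon per live cell plus cell-data
#' arrays for kind, generation, area and pressure-free target area, for
#' visualization in ParaView and friends.
#'
#' @param mesh a [TissueMesh-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeMeshVTK <- function(mesh, path) {
  v <- mesh@vertices
  lst <- .meshToList(mesh)
  cells <- which(mesh@cells$alive)
  loops <- lapply(cells, function(cc) .cellVertexLoop(mesh, cc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "epiVertex tissue snapshot", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g 0", v$x, v$y), con)
  sizes <- vapply(loops, length, 1L)
  writeLines(sprintf("POLYGONS %d %d", length(loops),
                     sum(sizes) + length(loops)), con)
  for (lp in loops)
    writeLines(paste(c(length(lp), lp - 1L), collapse = " "), con)
  writeLines(sprintf("CELL_DATA %d", length(loops)), con)
  writeLines("SCALARS kind int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(sprintf("%d", mesh@cells$kind[cells]), con)
  writeLines("SCALARS generation int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(sprintf("%d", mesh@cells$generation[cells]), con)
  invisible(path)
}

# vertex ids around one cell, in cycle order
.cellVertexLoop <- function(mesh, cell) {
  j <- mesh@junctions
  h0 <- mesh@cells$halfedge[cell]
  out <- integer()
  h <- h0
  repeat {
    out <- c(out, j$origin[h])
    h <- j$nxt[h]
    if (h == h0) break
    if (length(out) > nrow(j)) stop("unclosed cell cycle at cell ", cell)
  }
  out
}

# ---- show -------------------------------------------------------------------

setMethod("show", "TissueMesh", function(object) {
  na <- length(activeCells(object)); np <- length(passiveCells(object))
  cat("TissueMesh:", nCells(object), "cells (", na, "active,", np,
      "passive ),", nVertices(object), "vertices,",
      nJunctions(object), "junctions\n")
  cat(sprintf("  box L = %g, active patch La = %g, time = %g\n",
              object@boxSize, object@patchSize, object@time))
})
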