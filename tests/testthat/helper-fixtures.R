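# shared fixtures, all generated in code

unitSquareMesh <- function(...) {
  makeSingleCellMesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), ...)
}

regularPolygonMesh <- function(n, side = 1, ...) {
  # circumradius for the given side length
  R <- side / (2 * sin(pi / n))
  ang <- 2 * pi * (0:(n - 1)) / n
  makeSingleCellMesh(cbind(R * cos(ang), R * sin(ang)), ...)
}

# small relaxed two-population tissue (memoised per seed)
.tissueCache <- new.env()
smallTissue <- function(seed = 11, nCells = 60, boxSize = 12, patchSize = 5,
                        relaxed = FALSE) {
  key <- paste(seed, nCells, boxSize, patchSize, relaxed, sep = "-")
  if (!is.null(.tissueCache[[key]])) return(.tissueCache[[key]])
  cfg <- initConfig(nCells = nCells, boxSize = boxSize,
                    patchSize = patchSize, seed = seed)
  mesh <- assignTypesAndTargets(buildInitialTiling(cfg), modelParams())
  if (relaxed)
    mesh <- stepTissue(mesh, modelParams(), nsteps = 400)$mesh
  .tissueCache[[key]] <- mesh
  mesh
}

# an interior junction of a honeycomb whose four participating cells are
# distinct (accepts the first junction on which a forced T1 succeeds)
firstT1Junction <- function(mesh, params = modelParams()) {
  for (h in as.integer(names(junctionLengths(mesh, interiorOnly = TRUE)))) {
    if (t1Transition(mesh, h, params, force = TRUE)$ok) return(h)
  }
  stop("no T1-able junction in fixture")
}

# same, but preferring the junction nearest the mesh centre so every
# participating cell is an interior cell
centralT1Junction <- function(mesh, params = modelParams()) {
  j <- mesh@junctions; v <- mesh@vertices
  ids <- as.integer(names(junctionLengths(mesh, interiorOnly = TRUE)))
  a <- j$origin[ids]; b <- j$origin[j$twin[ids]]
  mx <- c(mean(v$x[v$alive]), mean(v$y[v$alive]))
  d <- ((v$x[a] + v$x[b]) / 2 - mx[1])^2 + ((v$y[a] + v$y[b]) / 2 - mx[2])^2
  for (h in ids[order(d)]) {
    if (t1Transition(mesh, h, params, force = TRUE)$ok) return(h)
  }
  stop("no T1-able junction in fixture")
}

meshEuler <- function(mesh) {
  nVertices(mesh) - nJunctions(mesh) + nCells(mesh)
}

cellSizes <- function(mesh) {
  epiVertex:::cpp_cell_sizes(epiVertex:::.meshToList(mesh))
}

vertexDegrees <- function(mesh) {
  epiVertex:::cpp_vertex_degrees(epiVertex:::.meshToList(mesh))
}
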