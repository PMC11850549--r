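# the five topological moves as local mesh surgeries

test_that("T1 swaps adjacency: hexagon quartet becomes 5-6-6-7", {
  hx <- makeHexagonalFixture(4, 4)
  p <- modelParams()
  h <- firstT1Junction(hx)
  V0 <- nVertices(hx); E0 <- nJunctions(hx)
  res <- t1Transition(hx, h, p, force = TRUE)
  expect_true(res$ok)
  m <- res$mesh
  expect_length(validateMesh(m), 0)
  sizes <- table(cellSizes(m))
  expect_equal(unname(sizes[c("5", "6", "7")]), c(2, 12, 2),
               ignore_attr = TRUE)
  # vertex and junction counts conserved
  expect_equal(nVertices(m), V0)
  expect_equal(nJunctions(m), E0)
  expect_identical(meshEuler(m), 1L)
  # post-move junction length is exactly 1.02 x threshold
  twin <- m@junctions$twin[h]
  len <- junctionLengths(m)[[as.character(min(h, twin))]]
  expect_equal(len / p@t1Threshold, 1.02, tolerance = 1e-12)
})

test_that("T1 is an involution up to geometry", {
  hx <- makeHexagonalFixture(4, 4)
  p <- modelParams()
  h <- firstT1Junction(hx)
  once <- t1Transition(hx, h, p, force = TRUE)$mesh
  twice <- t1Transition(once, h, p, force = TRUE)$mesh
  # adjacency restored: all cells hexagons again
  expect_equal(unname(table(cellSizes(twice))), 16, ignore_attr = TRUE)
  expect_length(validateMesh(twice), 0)
})

test_that("T1 respects preconditions without mutating", {
  hx <- makeHexagonalFixture(4, 4)
  p <- modelParams()
  h <- firstT1Junction(hx)
  # too long without force
  res <- t1Transition(hx, h, p, force = FALSE)
  expect_false(res$ok)
  expect_match(res$why, "threshold")
  expect_identical(res$mesh@junctions, hx@junctions)
  # boundary junction rejected
  j <- hx@junctions
  bdry <- which(j$alive & j$cell > 0 & j$cell[j$twin] == 0)[1]
  expect_false(t1Transition(hx, bdry, p, force = TRUE)$ok)
})

test_that("cell collapse removes n-1 vertices, n junctions, 1 face", {
  hx <- makeHexagonalFixture(5, 5)
  cen <- cellCentroid(hx)
  mid <- colMeans(cen)
  cc <- as.integer(rownames(cen)[
    which.min((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)])
  n <- cellSizes(hx)[cc]
  V0 <- nVertices(hx); E0 <- nJunctions(hx); F0 <- nCells(hx)
  res <- collapseCell(hx, cc)
  expect_true(res$ok)
  m <- res$mesh
  expect_equal(nVertices(m) - V0, -(n - 1))
  expect_equal(nJunctions(m) - E0, -n)
  expect_equal(nCells(m) - F0, -1)
  expect_identical(meshEuler(m), 1L)
  expect_length(validateMesh(m), 0)
  # new vertex coordination equals the collapsed cell's size
  expect_equal(vertexDegrees(m)[res$newVertex], n)
  # confluence: total area unchanged by the collapse itself
  expect_equal(sum(cellArea(m)), sum(cellArea(hx)), tolerance = 1e-9)
})

test_that("collapse rejects boundary-touching cells", {
  hx <- makeHexagonalFixture(3, 3)
  j <- hx@junctions
  bdryCell <- j$cell[j$alive & j$cell > 0 & j$cell[j$twin] == 0][1]
  expect_false(collapseCell(hx, bdryCell)$ok)
})

test_that("an n-valent vertex resolves in exactly n - 3 splits", {
  set.seed(31)
  p <- modelParams()
  # produce high-coordination vertices by collapsing interior cells of
  # disordered tilings; cell sizes span 4..8
  seen <- integer()
  for (seed in 1:6) {
    mesh <- smallTissue(seed = seed, nCells = 80, boxSize = 14, patchSize = 6)
    sz <- cellSizes(mesh)
    j <- mesh@junctions
    bdry <- unique(j$cell[j$alive & j$cell > 0 & j$cell[j$twin] == 0])
    inner <- setdiff(aliveCells(mesh), bdry)
    # one collapse per distinct cell size, to exercise several coordinations
    for (n in unique(sz[inner])) {
      if (n %in% seen) next
      for (cc in inner[sz[inner] == n]) {
        res <- collapseCell(mesh, cc)
        if (!res$ok) next
        r <- resolveVertex(res$mesh, res$newVertex, p)
        expect_equal(r$splits, n - 3)
        expect_length(validateMesh(r$mesh), 0)
        expect_true(all(vertexDegrees(r$mesh) <= 3, na.rm = TRUE))
        seen <- c(seen, n)
        break
      }
    }
  }
  expect_gte(length(unique(seen)), 3)   # several coordinations exercised
})

test_that("division splits a square into halves and conserves area", {
  sq <- unitSquareMesh()
  res <- insertDivisionEdge(sq, 1, axis = c(1, 0))
  expect_true(res$ok)
  m <- res$mesh
  expect_equal(unname(cellArea(m, res$daughters)), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(m@cells$generation[res$daughters], c(1L, 1L))
  expect_false(m@cells$alive[1])
  expect_length(validateMesh(m), 0)

  # chord cut conserves area exactly on a disordered cell
  mesh <- smallTissue()
  cc <- activeCells(mesh)[1]
  a0 <- cellArea(mesh, cc)
  ax <- longAxis(mesh, cc)
  r2 <- insertDivisionEdge(mesh, cc, ax[1, ])
  expect_true(r2$ok)
  expect_equal(sum(cellArea(r2$mesh, r2$daughters)), unname(a0),
               tolerance = 1e-12)
  expect_identical(meshEuler(r2$mesh), 1L)
})

test_that("division through a regular hexagon gives congruent trapezoids", {
  hx <- regularPolygonMesh(6)
  res <- insertDivisionEdge(hx, 1, axis = c(1, 0))
  expect_true(res$ok)
  a <- cellArea(res$mesh, res$daughters)
  pr <- cellPerimeter(res$mesh, res$daughters)
  expect_equal(a[[1]], a[[2]], tolerance = 1e-12)
  expect_equal(pr[[1]], pr[[2]], tolerance = 1e-12)
  # oracle: half the hexagon area
  expect_equal(unname(a[1]), 3 * sqrt(3) / 4, tolerance = 1e-12)
})

test_that("division adds 2 vertices, 3 junctions, 1 face", {
  mesh <- smallTissue()
  cc <- activeCells(mesh)[2]
  V0 <- nVertices(mesh); E0 <- nJunctions(mesh); F0 <- nCells(mesh)
  res <- insertDivisionEdge(mesh, cc, c(0.6, 0.8))
  expect_true(res$ok)
  expect_equal(nVertices(res$mesh) - V0, 2)
  expect_equal(nJunctions(res$mesh) - E0, 3)
  expect_equal(nCells(res$mesh) - F0, 1)
})

test_that("encircled cells flip type; others do not", {
  p <- modelParams()
  mesh <- smallTissue(seed = 13, nCells = 80, boxSize = 14, patchSize = 6)
  # no encircled cells in a freshly assigned two-block tiling
  res0 <- convertEncircledCells(mesh, p)
  expect_length(res0$cells, 0)
  expect_identical(res0$mesh@cells$kind, mesh@cells$kind)

  # make one passive cell fully surrounded by active cells
  j <- mesh@junctions
  bdry <- unique(j$cell[j$alive & j$cell > 0 & j$cell[j$twin] == 0])
  inner <- setdiff(aliveCells(mesh), bdry)
  target <- inner[1]
  mesh2 <- mesh
  mesh2@cells$kind[aliveCells(mesh2)] <- 0L       # all active...
  mesh2@cells$kind[target] <- 1L                  # ...one passive inside
  set.seed(5)
  res <- convertEncircledCells(mesh2, p)
  expect_identical(res$cells, target)
  expect_identical(res$mesh@cells$kind[target], 0L)
  # fresh targets drawn for the flip
  expect_equal(res$mesh@cells$targetArea[target],
               (res$mesh@cells$targetPerimeter[target] / p@p0Active)^2,
               tolerance = 1e-12)

  # one opposite neighbour blocks the flip
  mesh3 <- mesh2
  # find a neighbour of target and make it passive too
  hes <- which(j$alive & j$cell == target)
  nbCell <- j$cell[j$twin[hes[1]]]
  mesh3@cells$kind[nbCell] <- 1L
  res3 <- convertEncircledCells(mesh3, p)
  expect_false(target %in% res3$cells)
})
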