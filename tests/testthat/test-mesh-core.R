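# geometric queries and structural validation of the half-edge tiling

test_that("cell area, perimeter and centroid match closed forms", {
  sq <- unitSquareMesh()
  expect_equal(unname(cellArea(sq)), 1.0)
  expect_equal(unname(cellPerimeter(sq)), 4.0)
  expect_equal(cellCentroid(sq)[1, ], c(x = 0.5, y = 0.5))

  hx <- regularPolygonMesh(6)
  expect_equal(unname(cellArea(hx)), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(unname(cellPerimeter(hx)), 6.0, tolerance = 1e-12)
  # centred at the origin by construction
  expect_equal(cellCentroid(hx)[1, ], c(x = 0, y = 0),
               tolerance = 1e-12)
})

test_that("area of a random convex polygon matches the fan-triangulation oracle", {
  set.seed(4)
  for (rep in 1:5) {
    ang <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 0.5, 2)
    pts <- cbind(r * cos(ang), r * sin(ang))
    mesh <- makeSingleCellMesh(pts)
    # independent oracle: triangle fan from vertex 1
    fan <- 0
    for (i in 2:6) {
      v1 <- pts[i, ] - pts[1, ]; v2 <- pts[i + 1, ] - pts[1, ]
      fan <- fan + 0.5 * (v1[1] * v2[2] - v1[2] * v2[1])
    }
    expect_equal(unname(cellArea(mesh)), fan, tolerance = 1e-12)
    # isoperimetric inequality
    expect_gte(unname(cellPerimeter(mesh)),
               2 * sqrt(pi * unname(cellArea(mesh))))
  }
})

test_that("centroid of an L-shaped cell matches rectangle decomposition", {
  # 2x1 rectangle plus 1x1 square on top of its left half
  Lshape <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  mesh <- makeSingleCellMesh(Lshape)
  # oracle: area-weighted centroids of the two rectangles
  a1 <- 2; c1 <- c(1, 0.5)       # bottom 2x1
  a2 <- 1; c2 <- c(0.5, 1.5)     # top 1x1
  oracle <- (a1 * c1 + a2 * c2) / (a1 + a2)
  expect_equal(unname(cellCentroid(mesh)[1, ]), unname(oracle),
               tolerance = 1e-12)
  expect_equal(unname(cellArea(mesh)), 3, tolerance = 1e-12)
})

test_that("neighbour counts: honeycomb coordination and Euler mean", {
  hx <- makeHexagonalFixture(3, 3)
  cen <- cellCentroid(hx)
  mid <- colMeans(cen)
  central <- as.integer(rownames(cen)[
    which.min((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)])
  expect_equal(unname(neighbourCount(hx, central)), 6L)

  # interior cells of a large disordered tiling average ~6 neighbours
  # (Euler relation oracle for a mostly-3-valent planar tiling)
  mesh <- smallTissue(seed = 21, nCells = 120, boxSize = 17, patchSize = 7)
  j <- mesh@junctions
  boundaryCells <- unique(j$cell[j$alive & j$cell > 0 & j$cell[j$twin] == 0])
  inner <- setdiff(aliveCells(mesh), boundaryCells)
  expect_equal(mean(neighbourCount(mesh, inner)), 6, tolerance = 0.1)
  # interior cells of a confluent tiling: neighbour count = vertex count
  expect_true(all(neighbourCount(mesh, inner) == cellSizes(mesh)[inner]))
})

test_that("validate flags broken structure and passes healthy meshes", {
  mesh <- smallTissue()
  expect_length(validateMesh(mesh), 0)

  broken <- mesh
  h <- which(broken@junctions$alive)[1]
  broken@junctions$twin[h] <- broken@junctions$twin[h] + 1L
  report <- validateMesh(broken)
  expect_gt(length(report), 0)
  expect_true(any(grepl("twin", report)))
})

test_that("requesting a dead or unknown cell is a structural error", {
  sq <- unitSquareMesh()
  expect_error(cellArea(sq, 99), "not alive")
})

test_that("compaction drops tombstones and preserves the tiling", {
  mesh <- smallTissue(seed = 15, nCells = 80, boxSize = 14, patchSize = 6)
  cen <- cellCentroid(mesh)
  mid <- colMeans(cen)
  cc <- as.integer(rownames(cen)[
    which.min((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)])
  set.seed(8)
  r <- collapseCell(mesh, cc)
  m <- resolveVertex(r$mesh, r$newVertex)$mesh
  m2 <- insertDivisionEdge(m, activeCells(m)[1],
                           longAxis(m, activeCells(m)[1])[1, ])$mesh
  cm <- compactMesh(m2)
  expect_length(validateMesh(cm), 0)
  expect_equal(nrow(cm@cells), nCells(m2))
  expect_equal(nrow(cm@vertices), nVertices(m2))
  expect_true(all(cm@junctions$alive))
  expect_equal(sort(unname(cellArea(cm))), sort(unname(cellArea(m2))),
               tolerance = 1e-12)
  expect_equal(sum(cm@vertices$clamped), sum(m2@vertices$clamped))
})

test_that("junction lengths agree with vertex coordinates", {
  sq <- unitSquareMesh()
  expect_equal(sort(unique(round(junctionLengths(sq), 12))), 1)
  hx <- makeHexagonalFixture(2, 2, side = 0.5)
  expect_equal(unname(junctionLengths(hx)), rep(0.5, nJunctions(hx)),
               tolerance = 1e-12)
})
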