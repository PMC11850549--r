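# Lloyd relaxation, Voronoi tiling construction, type/target assignment

test_that("a single seed relaxes to the box centre", {
  p <- lloydRelax(matrix(c(3, 17), 1), boxSize = 20)
  expect_equal(c(p), c(10, 10), tolerance = 1e-3)
})

test_that("perturbed 2x2 grid seeds return to the exact grid centres", {
  exact <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  set.seed(2)
  p <- lloydRelax(exact + matrix(runif(8, -1, 1), 4), boxSize = 20,
                  tol = 1e-7)
  ord <- order(round(p[, 1], 2), round(p[, 2], 2))
  expect_equal(p[ord, ], exact[order(exact[, 1], exact[, 2]), ],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("relaxed seeds sit at their own tile centroids (stopping rule)", {
  set.seed(5)
  L <- 10
  pts <- cbind(runif(40, 0, L), runif(40, 0, L))
  out <- lloydRelax(pts, L, tol = 1e-5)
  polys <- epiVertex:::cpp_voronoi_polys(out[, 1], out[, 2], L, 2 * L / sqrt(40))
  for (i in seq_len(nrow(out))) {
    po <- polys[[i]]
    n <- nrow(po)
    jj <- c(2:n, 1)
    cr <- po[, 1] * po[jj, 2] - po[jj, 1] * po[, 2]
    a <- sum(cr) / 2
    cen <- c(sum((po[, 1] + po[jj, 1]) * cr), sum((po[, 2] + po[jj, 2]) * cr)) / (6 * a)
    expect_lt(sqrt(sum((cen - out[i, ])^2)), 1e-5 * L * 1.5)
  }
})

test_that("tile areas agree with the deldir oracle on a fixed interior configuration", {
  skip_if_not_installed("deldir")
  # interior seeds, no mirroring effects: plain Voronoi in a window
  set.seed(9)
  L <- 30
  pts <- cbind(runif(12, 10, 20), runif(12, 10, 20))
  polys <- epiVertex:::cpp_voronoi_polys(pts[, 1], pts[, 2], L, cutoff = 0.5)
  areas <- vapply(polys, function(po) {
    n <- nrow(po); jj <- c(2:n, 1)
    sum(po[, 1] * po[jj, 2] - po[jj, 1] * po[, 2]) / 2
  }, 1.0)
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = c(0, L, 0, L))
  oracle <- deldir::tile.list(dd)
  oracleAreas <- vapply(oracle, function(t) t$area, 1.0)
  # deldir snaps vertices at its own internal tolerance (~1e-9 relative
  # to the window), so agreement is to ~1e-7 absolute, not machine level
  expect_equal(areas, unname(oracleAreas), tolerance = 1e-6)
})

test_that("initial tiling is confluent with straight clamped boundaries", {
  cfg <- initConfig(nCells = 200, boxSize = 22, patchSize = 9, seed = 3)
  mesh <- buildInitialTiling(cfg)
  expect_equal(nCells(mesh), 200)
  expect_length(validateMesh(mesh), 0)
  expect_equal(sum(cellArea(mesh)), 22^2, tolerance = 1e-6 * 22^2)
  expect_identical(meshEuler(mesh), 1L)
  # every boundary vertex lies exactly on a wall (snapped, deviation 0)
  j <- mesh@junctions
  outerV <- unique(j$origin[j$alive & j$cell == 0])
  v <- mesh@vertices
  onWall <- v$x[outerV] %in% c(0, 22) | v$y[outerV] %in% c(0, 22)
  expect_true(all(onWall))
  # wall vertices and the first interior ring are clamped
  expect_true(all(v$clamped[outerV]))
  expect_gt(sum(v$clamped), length(outerV))
})

test_that("converged centroidal tilings have uniform cells (CV < 0.25)", {
  for (seed in 1:5) {
    cfg <- initConfig(nCells = 150, boxSize = 19, patchSize = 8, seed = seed)
    a <- cellArea(buildInitialTiling(cfg))
    expect_lt(sd(a) / mean(a), 0.25)
  }
})

test_that("type assignment: patch membership, targets, and binomial count", {
  params <- modelParams(p0Active = 3.60, p0Passive = 3.80)
  # passive targets: A0 = (5.98 / 3.80)^2
  mesh <- smallTissue()
  pas <- passiveCells(mesh)
  expect_equal(unique(mesh@cells$targetPerimeter[pas]), 5.98)
  expect_equal(unique(mesh@cells$targetArea[pas]), (5.98 / 3.80)^2,
               tolerance = 1e-12)
  act <- activeCells(mesh)
  expect_equal(mesh@cells$targetArea[act],
               (mesh@cells$targetPerimeter[act] / 3.60)^2, tolerance = 1e-12)
  # centroid-in-patch rule is exhaustive and exclusive
  expect_equal(sort(c(act, pas)), aliveCells(mesh))

  # sigma = 0: all active targets identical
  cfg <- initConfig(nCells = 80, boxSize = 14, patchSize = 6, seed = 2)
  m0 <- assignTypesAndTargets(buildInitialTiling(cfg),
                              modelParams(targetPerimeterSd = 0))
  expect_equal(unique(m0@cells$targetPerimeter[activeCells(m0)]), 5.98)

  # active count ~ N (La/L)^2 across seeds (binomial oracle)
  counts <- vapply(1:20, function(s) {
    cfg <- initConfig(nCells = 150, boxSize = 19, patchSize = 7.6, seed = s)
    length(activeCells(assignTypesAndTargets(buildInitialTiling(cfg), params)))
  }, 1L)
  expected <- 150 * (7.6 / 19)^2
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
})

test_that("identical seed and config give a bit-identical mesh", {
  cfg <- initConfig(nCells = 60, boxSize = 12, patchSize = 5, seed = 77)
  m1 <- assignTypesAndTargets(buildInitialTiling(cfg), modelParams())
  m2 <- assignTypesAndTargets(buildInitialTiling(cfg), modelParams())
  expect_identical(m1@vertices, m2@vertices)
  expect_identical(m1@junctions, m2@junctions)
  expect_identical(m1@cells, m2@cells)
})

test_that("hexagonal fixture has the critical shape index and validates", {
  hx <- makeHexagonalFixture(3, 4, side = 0.8)
  p <- cellPerimeter(hx) / sqrt(cellArea(hx))
  expect_equal(unname(p), rep(6 / sqrt(3 * sqrt(3) / 2), nCells(hx)),
               tolerance = 1e-9)
  expect_equal(round(p[[1]], 3), 3.722)
  expect_length(validateMesh(hx), 0)
})
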