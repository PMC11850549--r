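# snapshot round-trips, CSV/VTK export, config reading

test_that("mesh snapshots round-trip losslessly at full precision", {
  mesh <- smallTissue(relaxed = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  writeMeshSnapshot(mesh, path, seed = 11)
  back <- readMeshSnapshot(path)
  expect_identical(back@vertices$x, mesh@vertices$x)
  expect_identical(back@vertices$y, mesh@vertices$y)
  expect_identical(back@vertices$clamped, mesh@vertices$clamped)
  expect_identical(back@junctions$origin, mesh@junctions$origin)
  expect_identical(back@junctions$twin, mesh@junctions$twin)
  expect_identical(back@junctions$nxt, mesh@junctions$nxt)
  expect_identical(back@junctions$cell, mesh@junctions$cell)
  expect_identical(back@cells$kind, mesh@cells$kind)
  expect_identical(back@cells$targetArea, mesh@cells$targetArea)
  expect_identical(back@cells$targetPerimeter, mesh@cells$targetPerimeter)
  expect_equal(back@boxSize, mesh@boxSize)
  expect_equal(back@time, mesh@time)
  expect_length(validateMesh(back), 0)
  # prev pointers reconstructed consistently
  expect_identical(back@junctions$prev[back@junctions$alive],
                   mesh@junctions$prev[mesh@junctions$alive])
})

test_that("snapshots of post-event meshes keep tombstoned ids reserved", {
  mesh <- smallTissue(seed = 15, nCells = 80, boxSize = 14, patchSize = 6)
  cen <- cellCentroid(mesh)
  mid <- colMeans(cen)
  cc <- as.integer(rownames(cen)[
    which.min((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)])
  set.seed(3)
  m <- collapseCell(mesh, cc)
  m <- resolveVertex(m$mesh, m$newVertex)$mesh
  path <- withr::local_tempfile(fileext = ".json")
  writeMeshSnapshot(m, path)
  back <- readMeshSnapshot(path)
  expect_false(back@cells$alive[cc])
  expect_equal(aliveCells(back), aliveCells(m))
  expect_length(validateMesh(back), 0)
  expect_equal(sum(cellArea(back)), sum(cellArea(m)), tolerance = 1e-12)
})

test_that("VTK export writes one polygon per live cell", {
  hx <- makeHexagonalFixture(2, 2)
  path <- withr::local_tempfile(fileext = ".vtk")
  writeMeshVTK(hx, path)
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^DATASET POLYDATA$", txt)))
  polyLine <- txt[grepl("^POLYGONS ", txt)]
  expect_equal(as.integer(strsplit(polyLine, " ")[[1]][2]), nCells(hx))
})

test_that("run configuration files map exact keys onto the config objects", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    n_cells = 250, box_size = 25, patch_size = 10, lloyd_tol = 5e-5,
    clamp_rings = 1, p0_active = 3.6, p0_passive = 3.8,
    target_perimeter_mean = 5.98, target_perimeter_sd = 0.3, seed = 7,
    alpha = 8, beta = 6, growth_rate = 2e-3, t_rel = 50, t_end = 400
  ), auto_unbox = TRUE, digits = I(12)), path)
  cfg <- readRunConfig(path)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(cfg@init@nCells, 250)
  expect_equal(cfg@init@patchSize, 10)
  expect_equal(cfg@init@seed, 7)
  expect_equal(cfg@params@p0Active, 3.6)
  expect_equal(cfg@params@growthRate, 2e-3)
  expect_equal(cfg@schedule@endTime, 400)
  # defaults fill unstated keys
  expect_equal(cfg@params@areaModulus, 3.0)
  expect_equal(cfg@init@mirrorCutoff, 2 * 25 / sqrt(250))
})

test_that("observable and event CSVs round-trip through read.csv", {
  cfg <- simulationConfig(
    init = initConfig(nCells = 100, boxSize = 16, patchSize = 7, seed = 9),
    params = modelParams(),
    schedule = runSchedule(endTime = 150))
  res <- runSimulation(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeObservablesCsv(res, p1)
  writeEventsCsv(res, p2)
  obs <- utils::read.csv(p1)
  expect_equal(nrow(obs), nrow(res@series))
  expect_equal(obs$fN, res@series$fN, tolerance = 1e-12)
  ev <- utils::read.csv(p2)
  expect_equal(nrow(ev), nrow(res@events))
})
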