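# measured quantities: fractional changes, shape index, pressures,
# neighbour distributions, steady-state summaries

test_that("fractional changes normalise correctly for both references", {
  cfg <- simulationConfig(
    init = initConfig(nCells = 100, boxSize = 16, patchSize = 7, seed = 9),
    params = modelParams(),
    schedule = runSchedule(endTime = 150))
  res <- runSimulation(cfg)
  fr <- fractionalChanges(res, "relaxed")
  f0 <- fractionalChanges(res, "initial")
  expect_equal(fr$fN[1], 1)   # at t = 0 counts equal both references
  expect_equal(f0$fN[1], 1)
  expect_equal(f0$fA[1], 1)
  # f_N insensitive to the reference: no count change during relaxation
  expect_equal(fr$fN, f0$fN, tolerance = 1e-12)
  # f_A differs by passive relaxation of the active area
  expect_false(isTRUE(all.equal(fr$fA, f0$fA)))
})

test_that("realised shape index reproduces the regular-polygon constants", {
  hx <- makeHexagonalFixture(3, 3)
  si <- realisedShapeIndex(hx)
  expect_equal(round(si[["mean"]], 3), 3.722)
  expect_equal(si[["sd"]], 0, tolerance = 1e-9)

  sq <- unitSquareMesh()
  expect_equal(realisedShapeIndex(sq)[["mean"]], 4.0, tolerance = 1e-12)

  pent <- regularPolygonMesh(5)
  expect_equal(round(realisedShapeIndex(pent)[["mean"]], 2), 3.81)
})

test_that("mean pressures match a brute-force per-cell oracle", {
  p <- modelParams()
  mesh <- smallTissue(relaxed = TRUE)
  mp <- meanPressures(mesh, p)
  a <- cellArea(mesh)
  ids <- as.integer(names(a))
  press <- -p@areaModulus * (a - mesh@cells$targetArea[ids])
  act <- ids %in% activeCells(mesh)
  expect_equal(mp[["active"]], mean(press[act]), tolerance = 1e-12)
  expect_equal(mp[["passive"]], mean(press[!act]), tolerance = 1e-12)

  # uniform compression: shrink targets... set A0 = A + d everywhere
  d <- 0.07
  m2 <- mesh
  m2@cells$targetArea[ids] <- a + d
  mp2 <- meanPressures(m2, p)
  expect_equal(unname(mp2), rep(p@areaModulus * d, 2), tolerance = 1e-9)
})

test_that("neighbour distribution is a normalized histogram", {
  hx <- makeHexagonalFixture(5, 5)
  j <- hx@junctions
  bdry <- unique(j$cell[j$alive & j$cell > 0 & j$cell[j$twin] == 0])
  inner <- setdiff(aliveCells(hx), bdry)
  # restrict to interior cells: all hexagons
  hx@cells$kind[bdry] <- 1L   # make boundary passive; actives all interior
  fr <- neighbourDistribution(hx)
  expect_equal(sum(fr), 1)
  expect_equal(fr[["6"]], 1)

  mesh <- smallTissue(relaxed = TRUE)
  fr2 <- neighbourDistribution(mesh)
  expect_equal(sum(fr2), 1, tolerance = 1e-12)
  expect_true(all(fr2 >= 0))
})

test_that("a T1 among four hexagons moves the quartet to P5 = P7 = 1/4", {
  hx <- makeHexagonalFixture(5, 5)
  h <- centralT1Junction(hx)
  m <- t1Transition(hx, h, modelParams(), force = TRUE)$mesh
  # the four participating cells: two pentagons, two heptagons
  sz <- cellSizes(m)
  quartet <- which(sz != 6)
  expect_length(quartet, 4)
  expect_equal(sort(sz[quartet]), c(5, 5, 7, 7))
  # interior cells: neighbour count tracks the vertex count
  expect_equal(unname(neighbourCount(m, quartet[sz[quartet] == 5])),
               c(5, 5))
  expect_equal(unname(neighbourCount(m, quartet[sz[quartet] == 7])),
               c(7, 7))
})

test_that("steady-state summary averages constants and linear series exactly", {
  # constant series: mean equals the constant, sd 0
  n <- 101
  series <- data.frame(time = seq(0, 500, length.out = n), fN = 1.25,
                       fA = 1.1, meanPressureActive = 0.4,
                       meanPressurePassive = 0.38, shapeIndexMean = 3.8,
                       shapeIndexSd = 0.05, nActive = 50)
  for (cn in c(paste0("n", 3:12), "n13plus")) series[[cn]] <- 0L
  series$n6 <- 50L
  ss <- steadyStateSummary(series, tStart = 0, window = 500)
  expect_equal(ss@fN, 1.25)
  expect_equal(ss@fNSd, 0)
  expect_equal(ss@neighbourFractions[["6"]], 1)
  expect_equal(sum(ss@neighbourFractions), 1)

  # linear series: mean equals the midpoint value
  series$fN <- seq(1, 2, length.out = n)
  ss2 <- steadyStateSummary(series, tStart = 0, window = 500)
  expect_equal(ss2@fN, 1.5, tolerance = 1e-12)

  # window too short is an error
  expect_error(steadyStateSummary(series, tStart = 499.99, window = 0.001),
               "fewer than 2")
})

test_that("hexagon fraction falls from initial to steady state in a run", {
  cfg <- simulationConfig(
    init = initConfig(nCells = 150, boxSize = 19, patchSize = 8, seed = 2),
    params = modelParams(),
    schedule = runSchedule(endTime = 250))
  res <- runSimulation(cfg)
  s <- res@series
  first <- s[1, ]
  lastW <- s[s$time >= 200, ]
  p6init <- first$n6 / first$nActive
  p6end <- mean(lastW$n6 / lastW$nActive)
  p5init <- first$n5 / first$nActive
  p5end <- mean(lastW$n5 / lastW$nActive)
  expect_lt(p6end, p6init)
  expect_gt(p5end, p5init)
})
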