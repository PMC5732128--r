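test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(as.vector(allocateHistories(c(1, 1), 10)), c(5L, 5L))
  expect_equal(as.vector(allocateHistories(c(0.7, 0.3), 3)), c(2L, 1L))
  set.seed(30)
  for (i in seq_len(1e3)) {
    f <- runif(sample(2:50, 1))
    budget <- sample(1:1e4, 1)
    h <- allocateHistories(f, budget)
    expect_equal(sum(h), budget)
    expect_true(all(h >= 0))
  }
  expect_error(allocateHistories(c(0, 0), 10), "> 0")
})

test_that("history maps follow the activity estimate proportionally", {
  g <- voxelGrid(15, 4)
  act <- makeSphere(g, volume = 2, activity = 5)
  h <- allocateHistories(act, 1e5)
  expect_equal(sum(h), 1e5)
  inside <- values(act) > 0
  expect_true(all(h[!inside] == 0))
  expect_lt(max(abs(h[inside] - 1e5 / sum(inside))), 1)
})

test_that("matched measured and simulated projections are a fixed point", {
  g <- voxelGrid(15, 4)
  geom <- threeUnitGeometry()
  truth <- makeSphere(g, volume = 4, activity = 2)
  budget <- 5e4
  h <- allocateHistories(truth, budget)
  seed <- 101
  measured <- forwardProject(h, 2, 60, geom, grid = g,
                             config = simulationConfig(nHistories = budget,
                                                       seed = seed))
  state <- reconstructionState(truth, h)
  upd <- emUpdate(state, measured, geom,
                  config = reconstructionConfig(historiesPerIteration = budget,
                                                seed = seed),
                  iterationSeed = seed)
  expect_equal(values(activityEstimate(upd)), values(truth),
               tolerance = 1e-10)
})

test_that("a single-voxel system converges to p/a in one update", {
  g <- voxelGrid(1, 4)
  geom <- axialGeometry()
  budget <- 2e4
  seed <- 55
  truth <- activityMap(g, array(2, c(1, 1, 1)))
  h <- allocateHistories(truth, budget)
  measured <- forwardProject(h, 2, 60, geom, grid = g,
                             config = simulationConfig(nHistories = budget,
                                                       seed = seed))
  # start far from the solution
  start <- activityMap(g, array(0.5, c(1, 1, 1)))
  state <- reconstructionState(start, allocateHistories(start, budget))
  upd <- emUpdate(state, measured, geom,
                  config = reconstructionConfig(historiesPerIteration = budget,
                                                seed = seed),
                  iterationSeed = seed)
  expect_equal(totalActivity(upd), 2, tolerance = 1e-10)
})

test_that("updates preserve non-negativity and reject shape mismatches", {
  g <- voxelGrid(9, 4)
  geom <- threeUnitGeometry()
  truth <- makeSphere(g, volume = 2, activity = 1)
  h <- allocateHistories(truth, 1e4)
  measured <- forwardProject(h, 1, 60, geom, grid = g,
                             config = simulationConfig(nHistories = 1e4,
                                                       seed = 2))
  state <- reconstructionState(truth, h)
  upd <- emUpdate(state, measured, geom,
                  config = reconstructionConfig(historiesPerIteration = 1e4),
                  iterationSeed = 3)
  expect_true(all(values(activityEstimate(upd)) >= 0))
  bad <- projectionSet(array(1, c(32, 32, 5)))
  expect_error(emUpdate(state, bad, geom), "shape")
})

test_that("reconstruction is reproducible and respects zero iterations", {
  g <- voxelGrid(15, 4)
  geom <- threeUnitGeometry()
  truth <- makeSphere(g, volume = 4, activity = 1)
  h <- allocateHistories(truth, 3e4)
  measured <- forwardProject(h, 1, 60, geom, grid = g,
                             config = simulationConfig(nHistories = 3e4,
                                                       seed = 5))
  cfg <- reconstructionConfig(nIterations = 3, historiesPerIteration = 2e4,
                              seed = 9)
  a <- reconstruct(measured, geom, grid = g, config = cfg)
  b <- reconstruct(measured, geom, grid = g, config = cfg)
  expect_identical(values(activityEstimate(a$state)),
                   values(activityEstimate(b$state)))
  expect_equal(nrow(a$log), 3)
  # zero iterations: the uniform initial estimate comes back
  z <- reconstruct(measured, geom, grid = g,
                   config = reconstructionConfig(nIterations = 0,
                                                 historiesPerIteration = 1e4))
  v <- values(activityEstimate(z$state))
  expect_equal(sum(v), 1, tolerance = 1e-12)   # initialTotalActivity default
  expect_equal(length(unique(v[v > 0])), 1)    # uniform over the support
  expect_equal(z$state@iteration, 0L)
})

test_that("per-iteration total activity settles on noise-free data", {
  g <- voxelGrid(15, 4)
  geom <- threeUnitGeometry()
  truth <- makeSphere(g, volume = 4, activity = 2)
  h <- allocateHistories(truth, 2e5)
  measured <- forwardProject(h, 2, 60, geom, grid = g,
                             config = simulationConfig(nHistories = 2e5,
                                                       seed = 6))
  rec <- reconstruct(measured, geom, grid = g,
                     config = reconstructionConfig(nIterations = 12,
                                                   historiesPerIteration = 1e5,
                                                   seed = 6))
  tot <- rec$log$totalActivity
  # increments shrink as the estimate converges
  early <- abs(tot[2] - tot[1])
  late <- abs(tot[12] - tot[11])
  expect_lt(late, early)
  expect_equal(tot[12], 2, tolerance = 0.1)
})
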