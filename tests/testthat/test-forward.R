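test_that("forced-direction weight matches the closed-form solid angle", {
  u <- pinholeUnit(theta = 0, phi = 0, R = 150, apertureDiameter = 5)
  set.seed(1)
  fs <- forcedDirectionSample(c(0, 0, 0), u)   # emission 150 mm away
  expect_equal(fs$weight, (1 - 150 / sqrt(150^2 + 10^2)) / 2,
               tolerance = 1e-12)
  expect_equal(fs$weight, 1.108e-3, tolerance = 1e-3)
  expect_equal(sqrt(sum(fs$direction^2)), 1, tolerance = 1e-12)
  # vanishing aperture: weight tends to zero
  u0 <- pinholeUnit(R = 150, apertureDiameter = 1e-6)
  expect_lt(forcedDirectionSample(c(0, 0, 0), u0)$weight, 1e-14)
  expect_error(forcedDirectionSample(pinholeAxis(u) * u@R, u), "coincides")
})

test_that("Compton kinematics follow the closed-form energy relation", {
  expect_equal(comptonEnergy(140.5, pi), 140.5 / (1 + 281 / 511),
               tolerance = 1e-12)
  expect_equal(comptonEnergy(140.5, pi), 90.66, tolerance = 1e-3)
  expect_equal(comptonEnergy(140.5, 0), 140.5)
})

test_that("slab survival matches Beer-Lambert within 3 sigma", {
  g <- voxelGrid(20, 4)
  d <- uniformWater(g)
  n <- 1e5
  tr <- tracePhotons(n, c(-39.9, 0, 0), c(1, 0, 0), 140.5, d, seed = 5)
  p <- mean(tr$alive & tr$nScatter == 0)
  mu <- massAttenuation(physicsTables(), 140.5, "water", "total")
  expected <- exp(-mu * 7.99)  # 79.9 mm of water, mu in 1/cm
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("layered slabs attenuate as the product of exponentials", {
  g <- voxelGrid(20, 4)
  vals <- array(0, rep(20, 3))
  vals[6:10, , ] <- 1      # 20 mm water
  vals[14:17, , ] <- 0.5   # 16 mm half-density
  d <- densityMap(g, vals)
  n <- 1e5
  tr <- tracePhotons(n, c(-39.9, 0, 0), c(1, 0, 0), 140.5, d, seed = 6)
  p <- mean(tr$alive & tr$nScatter == 0)
  mu <- massAttenuation(physicsTables(), 140.5, "water", "total")
  expected <- exp(-mu * 2) * exp(-mu * 0.5 * 1.6)
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("photons cross a zero-density phantom unchanged", {
  g <- voxelGrid(20, 4)
  d <- densityMap(g, array(0, rep(20, 3)))
  tr <- tracePhotons(100, c(0, 0, 0), c(0, 0, 1), 140.5, d, seed = 2)
  expect_true(all(tr$alive))
  expect_true(all(tr$energy == 140.5))
  expect_true(all(tr$nScatter == 0))
  expect_true(all(tr$direction[, 3] == 1))
})

test_that("aperture transmission follows the knife-edge model", {
  u <- pinholeUnit(theta = 0, phi = 0)
  pin <- pinholeAxis(u) * u@R
  # ray through the aperture centre
  expect_equal(pinholeTransmission(c(0, 0, 0), c(0, 0, 1), u), 1)
  # 1 mm outside the aperture edge, penetration disabled
  missDir <- c(3.5, 0, u@R) / sqrt(3.5^2 + u@R^2)
  expect_equal(pinholeTransmission(c(0, 0, 0), missDir, u, FALSE), 0)
  # with penetration on, transmission decreases monotonically with miss
  miss <- seq(2.6, 6, by = 0.5)
  tr <- vapply(miss, function(x) {
    d <- c(x, 0, u@R) / sqrt(x^2 + u@R^2)
    pinholeTransmission(c(0, 0, 0), d, u, TRUE)
  }, numeric(1))
  expect_true(all(diff(tr) < 0))
  expect_true(all(tr > 0 & tr < 1))
})

test_that("point-source counts match the analytic pinhole sensitivity", {
  n <- 2e5
  # on-axis source: normal incidence
  g1 <- voxelGrid(1, 0.4)
  act1 <- activityMap(g1, array(1, c(1, 1, 1)))
  geom1 <- axialGeometry()
  ps1 <- forwardProject(allocateHistories(act1, n), 1, 60, geom1, grid = g1,
                        config = simulationConfig(nHistories = n, seed = 9))
  exp1 <- 1e6 * 60 * 0.885 * pinholeSensitivity(c(0, 0, 0),
                                                units3c(geom1)[[1]])
  expect_lt(abs(sum(counts(ps1)) / exp1 - 1), 0.01)
  # off-axis source: oblique incidence, cos^3 falloff
  g2 <- voxelGrid(41, 2)
  src <- c(30, 0, 0)
  act2 <- makeSphere(g2, center = src, volume = 1e-4, activity = 1)
  ps2 <- forwardProject(allocateHistories(act2, n), 1, 60, geom1, grid = g2,
                        config = simulationConfig(nHistories = n, seed = 9))
  exp2 <- 1e6 * 60 * 0.885 * pinholeSensitivity(src, units3c(geom1)[[1]])
  alpha <- acos(sum((pinholeAxis(units3c(geom1)[[1]]) * 180 - src) *
                      pinholeAxis(units3c(geom1)[[1]])) /
                  sqrt(sum((pinholeAxis(units3c(geom1)[[1]]) * 180 - src)^2)))
  expect_gt(alpha, 0.1)  # genuinely oblique
  expect_lt(abs(sum(counts(ps2)) / exp2 - 1), 0.015)
})

test_that("expected counts are linear in activity and stable in histories", {
  g <- voxelGrid(15, 4)
  act <- makeSphere(g, volume = 2, activity = 1)
  geom <- threeUnitGeometry()
  h <- allocateHistories(act, 2e4)
  cfg <- simulationConfig(nHistories = 2e4, seed = 4)
  a <- sum(counts(forwardProject(h, 1, 60, geom, grid = g, config = cfg)))
  b <- sum(counts(forwardProject(h, 2, 60, geom, grid = g, config = cfg)))
  expect_equal(b, 2 * a)  # exactly: weights are linear in activity
  h2 <- allocateHistories(act, 4e4)
  cfg2 <- simulationConfig(nHistories = 4e4, seed = 4)
  c2 <- sum(counts(forwardProject(h2, 1, 60, geom, grid = g, config = cfg2)))
  expect_lt(abs(c2 / a - 1), 0.05)
})

test_that("forced-direction and analog estimators agree within 3 sigma", {
  g <- voxelGrid(9, 4)
  act <- makeSphere(g, volume = 2, activity = 1)
  geom <- axialGeometry()
  nF <- 5e4; nA <- 4e6
  forced <- forwardProject(allocateHistories(act, nF), 1, 60, geom,
                           grid = g,
                           config = simulationConfig(nHistories = nF,
                                                     seed = 13))
  analog <- forwardProject(allocateHistories(act, nA), 1, 60, geom,
                           grid = g,
                           config = simulationConfig(nHistories = nA,
                                                     seed = 14),
                           analog = TRUE)
  tf <- sum(counts(forced)); ta <- sum(counts(analog))
  # analog detection is rare (p ~ 5e-5): Poisson-dominated error
  pHit <- ta / (1e6 * 60 * 0.885)
  sigma <- ta / sqrt(nA * pHit)
  expect_lt(abs(tf - ta), 3 * sigma)
})

test_that("detected weight never exceeds emitted weight", {
  g <- voxelGrid(15, 4)
  act <- makeSphere(g, volume = 2, activity = 1)
  geom <- defaultArcGeometry(5)
  ps <- forwardProject(allocateHistories(act, 1e4), 1, 60, geom, grid = g,
                       config = simulationConfig(nHistories = 1e4, seed = 1))
  expect_lt(sum(counts(ps)), 1e6 * 60 * 0.885)
})

test_that("identical seed and configuration reproduce projections bit for bit", {
  g <- voxelGrid(15, 4)
  act <- makeSphere(g, volume = 2, activity = 1.3)
  geom <- threeUnitGeometry()
  d <- uniformWater(g)
  h <- allocateHistories(act, 2e4)
  cfg <- simulationConfig(nHistories = 2e4, seed = 77)
  a <- forwardProject(h, 1.3, 60, geom, density = d, config = cfg)
  b <- forwardProject(h, 1.3, 60, geom, density = d, config = cfg)
  expect_identical(counts(a), counts(b))
})

test_that("energy spectra show the photopeak and object scatter", {
  g <- voxelGrid(21, 4)
  act <- makeSphere(g, volume = 2, activity = 1)
  geom <- axialGeometry()
  h <- allocateHistories(act, 5e4)
  cfg <- simulationConfig(nHistories = 5e4, seed = 8)
  # vacuum, ideal resolution: every detected count in the photopeak bin
  specAir <- recordSpectrum(h, 1, 60, geom, grid = g, config = cfg)
  expect_equal(sum(specAir$counts[specAir$energy != 140]), 0)
  # with a wide-open window, histogram total equals the window-less total
  psWide <- forwardProject(h, 1, 60, geom, grid = g, config = cfg,
                           energyWindow = c(0, 249))
  expect_equal(sum(attr(psWide, "spectrum")), sum(counts(psWide)))
  # water-filled object scatters: larger sub-photopeak fraction than air
  specWater <- recordSpectrum(h, 1, 60, geom, density = uniformWater(g),
                              config = cfg)
  fracBelow <- function(s) sum(s$counts[s$energy < 130]) / sum(s$counts)
  expect_gt(fracBelow(specWater), fracBelow(specAir))
})

test_that("Poisson sampling draws integer counts reproducibly", {
  g <- voxelGrid(9, 4)
  act <- makeSphere(g, volume = 2, activity = 1)
  geom <- axialGeometry()
  h <- allocateHistories(act, 1e4)
  cfg <- simulationConfig(nHistories = 1e4, seed = 5, poissonSampling = TRUE)
  a <- forwardProject(h, 1, 60, geom, grid = g, config = cfg)
  b <- forwardProject(h, 1, 60, geom, grid = g, config = cfg)
  expect_identical(counts(a), counts(b))
  expect_true(all(counts(a) == round(counts(a))))
})
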