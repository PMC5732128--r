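test_that("the grid-size heuristic honours its printed bounds", {
  expect_equal(gridSize(0), 62L)
  expect_equal(gridSize(1e12), 2L)
  # 10 cm -> 10 points per side
  expect_equal(gridSize(100), 10L)
  # non-increasing in distance, always within [2, 62]
  d <- seq(0, 1000, by = 0.25)
  ng <- gridSize(d)
  expect_true(all(diff(ng) <= 0))
  expect_true(all(ng >= 2L & ng <= 62L))
  expect_error(gridSize(-1), ">= 0")
})

test_that("sampling grids scale with magnification and stay centred", {
  u <- pinholeUnit(theta = 0, phi = 0, R = 100, H = 100)
  # voxel at z' = R/2: M = 2, so a 4-mm voxel spreads over 8 mm
  sg <- buildSamplingGrid(c(0, 0, 50), u, m = 4)
  expect_equal(sg@width, 8)
  expect_equal(sg@center, c(0, 0))
  expect_true(all(abs(sg@points[, 1]) <= 4 + 1e-12))
  expect_true(all(abs(sg@points[, 2]) <= 4 + 1e-12))
  expect_equal(nrow(sg@points), sg@nGrid^2)
  # off-axis voxel: grid centred on the mirrored intercept
  sg2 <- buildSamplingGrid(c(10, -5, 50), u, m = 4)
  expect_equal(sg2@center, c(-20, 10))
})

test_that("back-projection of unit projections is 1 for interior voxels", {
  g <- smallGrid(9, 4)
  geom <- threeUnitGeometry()
  s <- sensitivityMap(geom, g)
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
})

test_that("normalization combines units by their sampling-point counts", {
  g <- voxelGrid(1, 4)
  # two units at different distances: different N_grid
  u1 <- pinholeUnit(theta = 0, phi = 0, R = 180, H = 120)
  u2 <- pinholeUnit(theta = pi / 2, phi = 0, R = 120, H = 120)
  geom <- cameraGeometry(list(u1, u2), 190)
  n1 <- gridSize(180); n2 <- gridSize(120)
  expect_true(n1 != n2)
  r1 <- 0.7; r2 <- 1.9
  ratios <- array(0, c(32, 32, 2))
  ratios[, , 1] <- r1
  ratios[, , 2] <- r2
  bp <- backproject(ratios, geom, g)
  expect_equal(bpVolume(bp)[1, 1, 1],
               (n1^2 * r1 + n2^2 * r2) / (n1^2 + n2^2), tolerance = 1e-12)
  expect_equal(bpDenominator(bp)[1, 1, 1], n1^2 + n2^2)
})

test_that("all-zero projections back-project to an all-zero volume", {
  g <- smallGrid(9, 4)
  geom <- threeUnitGeometry()
  z <- array(0, c(32, 32, 3))
  expect_true(all(bpVolume(backproject(z, geom, g)) == 0))
})

test_that("back-projection is linear in the projection values", {
  g <- smallGrid(7, 6)
  geom <- threeUnitGeometry()
  set.seed(20)
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(runif(32 * 32 * 3), c(32, 32, 3))
  va <- bpVolume(backproject(a, geom, g))
  vb <- bpVolume(backproject(b, geom, g))
  vab <- bpVolume(backproject(2 * a + 3 * b, geom, g))
  expect_lt(max(abs(vab - (2 * va + 3 * vb))), 1e-10)
})

test_that("back-projection matches the brute-force per-point oracle", {
  g <- smallGrid(9, 4)
  geom <- threeUnitGeometry()
  set.seed(21)
  ratios <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (denom in c("all", "detected")) {
    bp <- backproject(ratios, geom, g, denominator = denom)
    oracle <- oracleBackproject(ratios, geom, g, denominator = denom)
    expect_equal(bpVolume(bp), oracle$volume, tolerance = 1e-12)
    expect_equal(bpDenominator(bp), oracle$denominator, tolerance = 1e-12)
  }
})

test_that("the back-projector ignores aperture, attenuation and tilt", {
  # the stated approximations: no attenuation/scatter, infinitesimal
  # aperture, incidence-independent efficiency -> results cannot depend on
  # aperture diameter, collimator attenuation or detector tilt
  g <- smallGrid(9, 4)
  set.seed(22)
  ratios <- array(runif(32 * 32 * 2), c(32, 32, 2))
  mk <- function(ap, mu, tilt) cameraGeometry(list(
    pinholeUnit(theta = 0, apertureDiameter = ap, collimatorMu = mu,
                detectorTilt = tilt),
    pinholeUnit(theta = pi / 3, apertureDiameter = ap, collimatorMu = mu,
                detectorTilt = tilt)), 190)
  a <- bpVolume(backproject(ratios, mk(5, 3.7, 0), g))
  b <- bpVolume(backproject(ratios, mk(0.1, 99, 0.2), g))
  expect_identical(a, b)
})

test_that("sensitivity flags voxels invisible to every unit", {
  # single unit: voxels far off-axis project off the detector
  g <- voxelGrid(35, 12)  # 420-mm extent, wider than the detector's view
  geom <- axialGeometry()
  s <- sensitivityMap(geom, g)
  expect_true(any(s == 0))
  expect_true(any(s == 1))
  expect_true(all(s >= 0 & s <= 1))
  # with the 'detected' denominator, values stay in [0, 1] too
  ones <- array(1, c(32, 32, 1))
  sd2 <- bpVolume(backproject(ones, geom, g, denominator = "detected"))
  expect_true(all(sd2 %in% c(0, 1)))
})

test_that("voxels behind a pinhole contribute nothing for that unit", {
  # a voxel at z' > R for the axial unit but visible to a lateral unit
  u1 <- axialUnit(R = 50, H = 100)            # pinhole plane at z = 50
  u2 <- pinholeUnit(theta = pi / 2, R = 500, H = 120)
  geom <- cameraGeometry(list(u1, u2), 800)
  g <- voxelGrid(9, 20)  # voxel centres out to +/-80 mm
  bp <- backproject(array(1, c(32, 32, 2)), geom, g)
  den <- bpDenominator(bp)
  cc <- axisCoords(g)
  behind <- which(cc > 50)
  expect_gt(length(behind), 0)
  # on-axis voxels behind the axial pinhole sit at z' = 0 for the lateral
  # unit (distance R), so only that unit's N_grid^2 points remain
  for (iz in behind)
    expect_equal(den[5, 5, iz], gridSize(u2@R)^2)
  # in front of the axial pinhole both units contribute
  infront <- which(cc < 50 & cc > -50)
  expect_true(all(den[5, 5, infront] > gridSize(u2@R)^2))
})
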