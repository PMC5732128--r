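test_that("spherical VOIs follow the voxel-centre rule", {
  g <- voxelGrid(35, 4)
  # the TARC rule: physical diameter of a 9-mL sphere plus 8 mm
  d9 <- 2 * sphereRadius(9)
  expect_equal(d9 + 8, 33.8, tolerance = 1e-3)
  phys <- sphericalVOIMask(g, c(0, 0, 0), d9)
  tarc <- sphericalVOIMask(g, c(0, 0, 0), d9 + 8)
  expect_true(all(tarc[phys]))          # strict superset
  expect_gt(sum(tarc), sum(phys))
  # sub-voxel VOI degenerates to the nearest voxel
  tiny <- sphericalVOIMask(g, c(10, 2, -6), 0.5)
  expect_equal(sum(tiny), 1)
})

test_that("recovery coefficients are exact ratios with TARC >= ARC", {
  g <- voxelGrid(35, 4)
  truth <- makeSphere(g, volume = 9, activity = 2)
  d9 <- 2 * sphereRadius(9)
  phys <- sphericalVOIMask(g, c(0, 0, 0), d9)
  rc <- recoveryCoefficient(truth, phys, 2, "physical")
  expect_equal(rc$coefficient, 1)       # generating mask recovers exactly
  tarc <- recoveryCoefficient(truth, sphericalVOIMask(g, c(0, 0, 0), d9 + 8),
                              2, "plus-8-mm")
  expect_gte(tarc$coefficient, rc$coefficient)
  expect_error(recoveryCoefficient(truth, array(FALSE, rep(35, 3)), 1),
               "empty")
})

test_that("plane distances are exact for ideal delta-peak volumes", {
  g <- voxelGrid(35, 4)
  maps <- makePointSourceGrid(g, 3, 20)
  pos <- attr(maps, "positions")
  vols <- lapply(maps, values)
  res <- planeDistanceAnalysis(vols, pos, g)
  expect_equal(nrow(res), 6)            # 2 pairs x 3 axes
  expect_true(all(res$meanDistance == 20))
  expect_true(all(res$sdDistance == 0))
  # uniform one-voxel shift leaves the distances unchanged
  shifted <- lapply(vols, function(v) {
    out <- array(0, dim(v)); out[2:35, , ] <- v[1:34, , ]; out
  })
  res2 <- planeDistanceAnalysis(shifted, pos, g)
  expect_equal(res2$meanDistance, res$meanDistance)
  expect_error(planeDistanceAnalysis(vols[1:3], pos, g), "one volume")
})

test_that("the Gaussian post-filter preserves interior activity", {
  g <- voxelGrid(35, 4)
  v <- values(makeSphere(g, volume = 2, activity = 1.5))
  f <- gaussianFilter3d(v, sigma = 1, kernelSize = 7)
  expect_equal(sum(f), 1.5, tolerance = 1e-9)
  expect_lt(max(f), max(v))             # smoothing
  expect_error(gaussianFilter3d(v, kernelSize = 6), "is not TRUE")
})

test_that("the Butterworth filter has unit DC gain and -3 dB at cut-off", {
  # constant volume is unchanged
  v <- array(2.5, rep(16, 3))
  expect_equal(butterworthFilter(v, 0.5, 2, voxel = 4), v, tolerance = 1e-10)
  # a pure cosine at the cut-off frequency drops by 1/sqrt(2); use a 5-mm
  # voxel so 0.5 cycles/cm falls on an exact DFT bin (k = 8 of 16 mm^-1...)
  N <- 32; m <- 5
  x <- (seq_len(N) - 1 - (N - 1) / 2) * m / 10  # cm
  vol <- array(rep(cos(2 * pi * 0.5 * x), times = N * N), rep(N, 3))
  filt <- butterworthFilter(vol, cutoff = 0.5, order = 2, voxel = m)
  expect_equal(max(abs(filt)) / max(abs(vol)), 1 / sqrt(2), tolerance = 1e-6)
  # interior source: total preserved to 0.1%
  g <- voxelGrid(32, 4)
  sp <- values(makeSphere(g, volume = 4, activity = 1))
  expect_equal(sum(butterworthFilter(sp, 0.5, 2, voxel = 4)), 1,
               tolerance = 1e-3)
})

test_that("maximum-intensity projections behave as a lattice maximum", {
  v <- array(0, c(5, 5, 5))
  v[2, 3, 4] <- 7
  expect_equal(max(mip(v, 3)), 7)
  expect_equal(sum(mip(v, 3) > 0), 1)
  a <- array(runif(125), c(5, 5, 5)); b <- array(runif(125), c(5, 5, 5))
  expect_equal(mip(pmax(a, b), 1), pmax(mip(a, 1), mip(b, 1)))
  expect_equal(mip(array(3, c(4, 4, 4)), 2), matrix(3, 4, 4))
})

test_that("binary dilation grows masks as expected", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  d <- dilateMask(m, 3)
  expect_equal(sum(d), 27)
  expect_true(all(d[m]))
  full <- array(TRUE, c(5, 5, 5))
  expect_equal(dilateMask(full, 3), full)
})

test_that("line profiles average the stated rows", {
  v <- array(3, c(21, 21, 21))
  expect_equal(lineProfile(v, rowCenter = 10, axis = 1), rep(3, 21))
  # single nonzero row contributes 1/7 of its value
  v2 <- array(0, c(21, 21, 21))
  v2[, 10, 11] <- 14
  expect_equal(lineProfile(v2, rowCenter = 10, axis = 1, slice = 11),
               rep(2, 21))
  expect_error(lineProfile(v, rowCenter = 2, axis = 1), "out of bounds")
  # cardiac shell: two wall peaks with a ventricular trough between
  g <- voxelGrid(70, 4)
  ph <- makeCardiacPhantom(g)
  conc <- values(ph$activity)
  izApex <- 25   # transaxial slice through the shell below the base plane
  prof <- lineProfile(conc, rowCenter = 36, axis = 1, slice = izApex)
  mid <- prof[30:41]
  expect_lt(min(mid), max(prof) / 2)    # trough at the cavity
  left <- which.max(prof[1:35]); right <- 35 + which.max(prof[36:70])
  expect_gt(right - left, 5)            # two separated wall peaks
})
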