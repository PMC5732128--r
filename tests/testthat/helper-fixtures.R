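# Shared small fixtures, built in code.

smallGrid <- function(N = 9, m = 4) voxelGrid(N, m)

# three-unit arc used by back-projector oracles
threeUnitGeometry <- function() defaultArcGeometry(3)

# a single unit looking down +z
axialUnit <- function(...) pinholeUnit(theta = 0, phi = 0, ...)

axialGeometry <- function(...) cameraGeometry(list(axialUnit(...)), 190)

uniformWater <- function(grid) {
  densityMap(grid, array(1, rep(gridN(grid), 3L)))
}

# Brute-force per-voxel, per-point back-projection oracle built from the
# R-level geometry primitives (independent of the C++ kernel). Pixel binning
# uses plain floor arithmetic.
oracleBackproject <- function(ratios, geometry, grid, denominator = "all") {
  N <- gridN(grid)
  m <- voxelSize(grid)
  cc <- axisCoords(grid)
  vol <- array(0, rep(N, 3L))
  den <- array(0, rep(N, 3L))
  units <- units3c(geometry)
  for (ix in seq_len(N)) for (iy in seq_len(N)) for (iz in seq_len(N)) {
    pt <- c(cc[ix], cc[iy], cc[iz])
    num <- 0; dd <- 0
    for (k in seq_along(units)) {
      u <- units[[k]]
      p <- rotateToPinholeFrame(pt, u@theta, u@phi)
      if (p[3] >= u@R) next
      sg <- buildSamplingGrid(pt, u, m)
      nPix <- u@nPix
      col <- floor(sg@points[, 1] / u@pixelPitch + nPix / 2)
      row <- floor(sg@points[, 2] / u@pixelPitch + nPix / 2)
      on <- col >= 0 & col < nPix & row >= 0 & row < nPix
      if (any(on))
        num <- num + sum(ratios[cbind(row[on] + 1, col[on] + 1, k)])
      dd <- dd + if (denominator == "all") sg@nGrid^2 else sum(on)
    }
    vol[ix, iy, iz] <- if (dd > 0) num / dd else 0
    den[ix, iy, iz] <- dd
  }
  list(volume = vol, denominator = den)
}
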