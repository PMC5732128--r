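## Voxelized phantom generators. All generators are deterministic and decide
## voxel membership by voxel-centre inclusion (no partial-volume weighting).

.AIR_DENSITY <- 0.00129   # g/cm^3
.WATER_DENSITY <- 1.0

# voxel-centre coordinate arrays (mm), each shaped N^3
.coordArrays <- function(grid) {
  cc <- axisCoords(grid)
  N <- grid@N
  list(x = array(rep(cc, times = N * N), dim = c(N, N, N)),
       y = array(rep(rep(cc, each = N), times = N), dim = c(N, N, N)),
       z = array(rep(cc, each = N * N), dim = c(N, N, N)))
}

#' Uniform activity sphere
#'
#' Places a sphere of the given volume and total activity; voxels whose
#' centres lie inside the radius \code{(3V / 4 pi)^(1/3)} share the activity
#' uniformly, so the map total equals the requested activity exactly. A
#' sphere smaller than one voxel degenerates to a single-voxel source at the
#' voxel nearest the centre.
#'
#' @param grid a [VoxelGrid-class]
#' @param center sphere centre, world mm 3-vector
#' @param volume sphere volume (mL)
#' @param activity total activity (MBq)
#' @return an [ActivityMap-class]
#' @export
makeSphere <- function(grid, center = c(0, 0, 0), volume = 9, activity = 1) {
  radius <- sphereRadius(volume)
  half <- grid@N * grid@m / 2
  if (any(abs(center) + radius > half))
    stop("sphere extends outside the grid")
  co <- .coordArrays(grid)
  inside <- (co$x - center[1])^2 + (co$y - center[2])^2 +
    (co$z - center[3])^2 <= radius^2
  vals <- array(0, dim = rep(grid@N, 3L))
  if (!any(inside)) {
    idx <- vapply(seq_len(3L), function(a)
      which.min(abs(axisCoords(grid) - center[a])), integer(1))
    vals[idx[1], idx[2], idx[3]] <- activity
  } else {
    vals[inside] <- activity / sum(inside)
  }
  activityMap(grid, vals)
}

#' Sphere radius from volume
#' @param volume sphere volume (mL)
#' @return radius (mm)
#' @export
sphereRadius <- function(volume) 10 * (3 * volume / (4 * pi))^(1 / 3)

#' Six-sphere set in an elliptical torso
#'
#' Six spheres (0.5, 1, 2, 4, 8 and 16 mL) at a common activity
#' concentration, arranged at equal angles on a ring inside an
#' elliptical-cylinder torso whose axis runs along z. The ring lies in a
#' plane tilted about the x-axis (mimicking a cardiac short-axis mounting
#' plane). Sphere interiors are always water-equivalent; the remaining torso
#' volume is water or air according to \code{waterFilled}.
#'
#' @param grid a [VoxelGrid-class]
#' @param concentration activity concentration (MBq/mL)
#' @param waterFilled logical; fill the torso with water
#' @param ringRadius radius of the sphere-centre ring (mm)
#' @param tilt tilt of the mounting plane about the x-axis (radians)
#' @param torsoSemiAxes c(x, y) semi-axes of the torso ellipse (mm)
#' @return list(activity = [ActivityMap-class], density = [DensityMap-class],
#'   spheres = data.frame of per-sphere volume, activity, centre)
#' @export
makeNemaSpheresInTorso <- function(grid, concentration = 4.1,
                                   waterFilled = TRUE, ringRadius = 50,
                                   tilt = pi / 4,
                                   torsoSemiAxes = c(150, 100)) {
  volumes <- c(0.5, 1, 2, 4, 8, 16)
  ang <- (seq_along(volumes) - 1) * 2 * pi / length(volumes)
  ct <- cos(tilt); st <- sin(tilt)
  centers <- t(vapply(ang, function(a) {
    p <- c(ringRadius * cos(a), ringRadius * sin(a), 0)
    c(p[1], ct * p[2], st * p[2])   # rotate ring plane about the x-axis
  }, numeric(3)))
  co <- .coordArrays(grid)
  N <- grid@N
  act <- array(0, dim = rep(N, 3L))
  dens <- array(.AIR_DENSITY, dim = rep(N, 3L))
  mat <- array(0L, dim = rep(N, 3L))
  inTorso <- (co$x / torsoSemiAxes[1])^2 + (co$y / torsoSemiAxes[2])^2 <= 1
  if (waterFilled) {
    dens[inTorso] <- .WATER_DENSITY
    mat[inTorso] <- 1L
  }
  for (i in seq_along(volumes)) {
    r <- sphereRadius(volumes[i])
    inside <- (co$x - centers[i, 1])^2 + (co$y - centers[i, 2])^2 +
      (co$z - centers[i, 3])^2 <= r^2
    if (!any(inside)) stop("sphere ", i, " contains no voxel centre")
    act[inside] <- act[inside] + concentration * volumes[i] / sum(inside)
    dens[inside] <- .WATER_DENSITY
    mat[inside] <- 1L
  }
  list(activity = activityMap(grid, act),
       density = new("DensityMap", grid = grid, values = dens, material = mat),
       spheres = data.frame(volume = volumes,
                            activity = concentration * volumes,
                            x = centers[, 1], y = centers[, 2],
                            z = centers[, 3]))
}

#' Cubic grid of point sources
#'
#' One single-voxel source per position of an \code{n x n x n} cubic grid
#' with the given spacing, centred on the origin. Each source position is
#' assigned to the nearest voxel centre.
#'
#' @param grid a [VoxelGrid-class]
#' @param nPerSide points per cube side
#' @param spacing point spacing (mm)
#' @param activity activity per source (MBq)
#' @return list of [ActivityMap-class], with attribute \code{positions}
#'   (matrix of true source coordinates, mm, one row per map)
#' @export
makePointSourceGrid <- function(grid, nPerSide = 5L, spacing = 20,
                                activity = 1) {
  offs <- (seq_len(nPerSide) - 1 - (nPerSide - 1) / 2) * spacing
  half <- grid@N * grid@m / 2
  if (max(abs(offs)) >= half) stop("point grid does not fit inside the grid")
  pos <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  cc <- axisCoords(grid)
  maps <- lapply(seq_len(nrow(pos)), function(i) {
    vals <- array(0, dim = rep(grid@N, 3L))
    idx <- vapply(seq_len(3L), function(a)
      which.min(abs(cc - pos[i, a])), integer(1))
    vals[idx[1], idx[2], idx[3]] <- activity
    activityMap(grid, vals)
  })
  attr(maps, "positions") <- pos
  maps
}

#' Cardiac shell phantom
#'
#' A half-ellipsoid myocardial shell of fixed wall thickness around a
#' water-filled ventricular cavity, mounted in the elliptical torso. The
#' cavity is a half-ellipsoid of transverse width 38.0 mm; the shell wall is
#' 10.3 mm thick, and the shell length is solved numerically so the
#' continuum shell volume equals \code{shellVolume} mL. Activity is uniform
#' over the shell.
#'
#' @param grid a [VoxelGrid-class]
#' @param myocardialActivity total shell activity (MBq)
#' @param torsoWater logical; water-filled torso
#' @param wallThickness myocardial wall thickness (mm)
#' @param cavityWidth ventricular cavity width (mm)
#' @param shellVolume target shell volume (mL)
#' @param torsoSemiAxes c(x, y) torso ellipse semi-axes (mm)
#' @return list(activity, density, shellMask, cavityMask,
#'   shellVolume (analytic, mL), concentration (MBq/mL))
#' @export
makeCardiacPhantom <- function(grid, myocardialActivity = 21.1,
                               torsoWater = FALSE, wallThickness = 10.3,
                               cavityWidth = 38.0, shellVolume = 120,
                               torsoSemiAxes = c(150, 100)) {
  aIn <- cavityWidth / 2
  aOut <- aIn + wallThickness
  # continuum volume of the half-ellipsoid shell, mm^3, as a function of the
  # inner long semi-axis c (outer long semi-axis c + wallThickness)
  shellVol <- function(cIn)
    (2 * pi / 3) * (aOut^2 * (cIn + wallThickness) - aIn^2 * cIn)
  target <- shellVolume * 1000
  cIn <- uniroot(function(c) shellVol(c) - target,
                 lower = 1, upper = 1000)$root
  cOut <- cIn + wallThickness
  co <- .coordArrays(grid)
  N <- grid@N
  # long axis along z, apex toward -z, base plane at z = 0
  lower <- co$z <= 0
  inOuter <- lower &
    (co$x / aOut)^2 + (co$y / aOut)^2 + (co$z / cOut)^2 <= 1
  inInner <- lower &
    (co$x / aIn)^2 + (co$y / aIn)^2 + (co$z / cIn)^2 <= 1
  shell <- inOuter & !inInner
  act <- array(0, dim = rep(N, 3L))
  act[shell] <- myocardialActivity / sum(shell)
  dens <- array(.AIR_DENSITY, dim = rep(N, 3L))
  mat <- array(0L, dim = rep(N, 3L))
  inTorso <- (co$x / torsoSemiAxes[1])^2 + (co$y / torsoSemiAxes[2])^2 <= 1
  if (torsoWater) {
    dens[inTorso] <- .WATER_DENSITY
    mat[inTorso] <- 1L
  }
  dens[shell | inInner] <- .WATER_DENSITY
  mat[shell | inInner] <- 1L
  list(activity = activityMap(grid, act),
       density = new("DensityMap", grid = grid, values = dens, material = mat),
       shellMask = shell, cavityMask = inInner,
       shellVolume = shellVol(cIn) / 1000,
       concentration = myocardialActivity / (shellVol(cIn) / 1000))
}

#' Convert a linear attenuation map to densities
#'
#' Rescales a 140.5-keV (or other reference energy) linear attenuation map
#' to mass densities by dividing by the mass attenuation coefficient of
#' water at that energy: density = mu / (mu/rho)_water. Linear and monotone.
#'
#' @param muMap 3-D array of linear attenuation coefficients (1/mm)
#' @param grid a [VoxelGrid-class]
#' @param referenceEnergy energy of the attenuation map (keV)
#' @param tables optional [PhysicsTables-class]
#' @return a [DensityMap-class]
#' @export
densityFromAttenuation <- function(muMap, grid, referenceEnergy = 140.5,
                                   tables = physicsTables()) {
  if (any(muMap < 0)) stop("attenuation coefficients must be >= 0")
  muRho <- massAttenuation(tables, referenceEnergy, "water", "total")
  dens <- (muMap * 10) / muRho    # 1/mm -> 1/cm, then / (cm^2/g)
  densityMap(grid, dens)
}
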