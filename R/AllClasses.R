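#' @useDynLib pinholeMC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx fft rpois runif sd uniroot
#' @importFrom utils write.csv packageVersion
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Voxel grids and volumes
## ---------------------------------------------------------------------------

#' Cubic voxel grid
#'
#' An \code{N x N x N} cubic grid of voxels with side length \code{m}
#' millimetres. The grid is centred on the world origin: the world coordinate
#' of the centre of voxel with 0-based index \code{i} along an axis is
#' \code{(i - (N - 1)/2) * m}. All world coordinates in the package are in
#' millimetres, right-handed.
#'
#' @slot N integer, voxels per side (>= 1)
#' @slot m numeric, voxel side length in mm (> 0)
#' @export
setClass("VoxelGrid", representation(N = "integer", m = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
    return("N must be a single integer >= 1")
  if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 0)
    return("m must be a single positive number (mm)")
  TRUE
})

#' @param N voxels per side
#' @param m voxel side length (mm)
#' @rdname VoxelGrid-class
#' @export
voxelGrid <- function(N, m) new("VoxelGrid", N = as.integer(N), m = as.numeric(m))

#' Activity volume (MBq per voxel)
#'
#' A voxelized activity distribution. \code{values} holds the activity in MBq
#' contained in each voxel (not a concentration), so \code{sum(values(x))} is
#' the total activity of the source.
#'
#' @slot grid a [VoxelGrid-class]
#' @slot values 3-D numeric array, MBq per voxel, all >= 0
#' @export
setClass("ActivityMap", representation(grid = "VoxelGrid", values = "array"))

setValidity("ActivityMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || any(d != object@grid@N))
    return("values must be an N x N x N array matching the grid")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("activity values must be finite and >= 0")
  TRUE
})

#' @param grid a [VoxelGrid-class]
#' @param values 3-D array of per-voxel activity (MBq)
#' @rdname ActivityMap-class
#' @export
activityMap <- function(grid, values) {
  if (is.null(dim(values))) dim(values) <- rep(grid@N, 3L)
  new("ActivityMap", grid = grid, values = values)
}

#' Density volume (g/cm^3 per voxel) with material labels
#'
#' Mass density per voxel, plus a material label used to select mass
#' attenuation coefficient tables. Label codes: 0 = air, 1 = water,
#' 2 = other (treated as water-like coefficients scaled by density).
#'
#' @slot grid a [VoxelGrid-class]
#' @slot values 3-D numeric array of densities (g/cm^3), >= 0
#' @slot material 3-D integer array of material codes
#' @export
setClass("DensityMap",
         representation(grid = "VoxelGrid", values = "array", material = "array"))

setValidity("DensityMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || any(d != object@grid@N))
    return("values must be an N x N x N array matching the grid")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("densities must be finite and >= 0")
  if (!identical(dim(object@material), d))
    return("material labels must have the same shape as values")
  if (any(!(object@material %in% c(0L, 1L, 2L))))
    return("material codes must be 0 (air), 1 (water) or 2 (other)")
  TRUE
})

#' @param grid a [VoxelGrid-class]
#' @param values densities (g/cm^3)
#' @param material integer material codes (same shape); default all air
#' @rdname DensityMap-class
#' @export
densityMap <- function(grid, values, material = NULL) {
  if (is.null(dim(values))) dim(values) <- rep(grid@N, 3L)
  if (is.null(material)) {
    material <- array(0L, dim = dim(values))
    material[values > 0.1] <- 1L   # default: anything denser than ~air is water
  }
  storage.mode(material) <- "integer"
  new("DensityMap", grid = grid, values = values, material = material)
}

## ---------------------------------------------------------------------------
## Camera geometry
## ---------------------------------------------------------------------------

#' Single pinhole-detector unit
#'
#' One pinhole aperture with its detector plane. The pinhole axis is the line
#' from the source-volume origin through the pinhole centre; its direction is
#' given by a polar angle \code{theta} (rotation about the x-axis) and an
#' azimuthal angle \code{phi} (rotation about the y-axis), with
#' \code{theta = phi = 0} pointing along +z. The pinhole centre sits at
#' distance \code{R} from the origin along the axis; the detector plane is
#' perpendicular to the axis at a further distance \code{H} behind the
#' pinhole.
#'
#' @slot theta polar angle of the pinhole axis (radians)
#' @slot phi azimuthal angle of the pinhole axis (radians)
#' @slot R origin-to-pinhole distance (mm)
#' @slot H pinhole-to-detector distance (mm)
#' @slot apertureDiameter pinhole opening diameter (mm)
#' @slot nPix detector pixels per side
#' @slot pixelPitch detector element size (mm)
#' @slot detectorTilt angle between detector normal and pinhole axis
#'   (radians; 0 = perpendicular; honoured by the forward model only)
#' @slot collimatorMu linear attenuation coefficient of the aperture material
#'   at the photopeak energy (1/mm); used only by the forward model's
#'   knife-edge penetration option
#' @export
setClass("PinholeUnit",
         representation(theta = "numeric", phi = "numeric", R = "numeric",
                        H = "numeric", apertureDiameter = "numeric",
                        nPix = "integer", pixelPitch = "numeric",
                        detectorTilt = "numeric", collimatorMu = "numeric"))

setValidity("PinholeUnit", function(object) {
  if (object@R <= 0 || object@H <= 0) return("R and H must be > 0")
  if (object@apertureDiameter < 0) return("apertureDiameter must be >= 0")
  if (object@nPix < 1L) return("nPix must be >= 1")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@collimatorMu < 0) return("collimatorMu must be >= 0")
  TRUE
})

#' @param theta,phi pinhole-axis angles (radians)
#' @param R,H origin-to-pinhole and pinhole-to-detector distances (mm)
#' @param apertureDiameter pinhole diameter (mm)
#' @param nPix detector pixels per side
#' @param pixelPitch detector element size (mm)
#' @param detectorTilt detector tilt (radians)
#' @param collimatorMu aperture material attenuation (1/mm)
#' @rdname PinholeUnit-class
#' @export
pinholeUnit <- function(theta = 0, phi = 0, R = 180, H = 120,
                        apertureDiameter = 5, nPix = 32L,
                        pixelPitch = 78.7 / 32, detectorTilt = 0,
                        collimatorMu = 3.7) {
  new("PinholeUnit", theta = as.numeric(theta), phi = as.numeric(phi),
      R = as.numeric(R), H = as.numeric(H),
      apertureDiameter = as.numeric(apertureDiameter), nPix = as.integer(nPix),
      pixelPitch = as.numeric(pixelPitch), detectorTilt = as.numeric(detectorTilt),
      collimatorMu = as.numeric(collimatorMu))
}

#' Multi-pinhole camera geometry
#'
#' An ordered list of [PinholeUnit-class] objects; the list order defines the
#' projection index \code{k = 0 .. K-1}. \code{fovDiameter} is the diameter
#' (mm) of the spherical field of view reconstructable by the static
#' geometry; it bounds the support of the initial ML-EM estimate.
#'
#' @slot units list of [PinholeUnit-class]
#' @slot fovDiameter spherical field-of-view diameter (mm)
#' @export
setClass("CameraGeometry",
         representation(units = "list", fovDiameter = "numeric"))

setValidity("CameraGeometry", function(object) {
  if (length(object@units) < 1L) return("need at least one pinhole unit")
  if (!all(vapply(object@units, is, logical(1), "PinholeUnit")))
    return("units must all be PinholeUnit objects")
  if (object@fovDiameter <= 0) return("fovDiameter must be > 0")
  TRUE
})

#' @param units list of [PinholeUnit-class]
#' @param fovDiameter spherical FOV diameter (mm)
#' @rdname CameraGeometry-class
#' @export
cameraGeometry <- function(units, fovDiameter = 190) {
  new("CameraGeometry", units = units, fovDiameter = as.numeric(fovDiameter))
}

## ---------------------------------------------------------------------------
## Projections
## ---------------------------------------------------------------------------

#' Projection set
#'
#' Detector count images for all K pinhole-detector units, stored as an
#' \code{nPix x nPix x K} array \code{counts[row, col, k]} where \code{row}
#' bins the detector y-coordinate and \code{col} the x-coordinate. Values are
#' expected counts (or Poisson-sampled counts when sampling was requested).
#'
#' @slot counts nPix x nPix x K numeric array, >= 0
#' @slot acquisitionTime acquisition time (s)
#' @slot energyWindow c(low, high) accepted energy window (keV)
#' @slot historiesUsed number of Monte Carlo histories behind the counts
#'   (0 when not simulation-derived)
#' @export
setClass("ProjectionSet",
         representation(counts = "array", acquisitionTime = "numeric",
                        energyWindow = "numeric", historiesUsed = "numeric"))

setValidity("ProjectionSet", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L) return("counts must be an nPix x nPix x K array")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    return("counts must be finite and >= 0")
  if (object@acquisitionTime <= 0) return("acquisitionTime must be > 0")
  if (length(object@energyWindow) != 2L ||
      object@energyWindow[1] > object@energyWindow[2])
    return("energyWindow must be c(low, high) with low <= high")
  TRUE
})

#' @param counts nPix x nPix x K array
#' @param acquisitionTime seconds
#' @param energyWindow c(low, high) keV
#' @param historiesUsed MC histories used to form the counts
#' @rdname ProjectionSet-class
#' @export
projectionSet <- function(counts, acquisitionTime = 600,
                          energyWindow = c(126.45, 154.55),
                          historiesUsed = 0) {
  new("ProjectionSet", counts = counts,
      acquisitionTime = as.numeric(acquisitionTime),
      energyWindow = as.numeric(energyWindow),
      historiesUsed = as.numeric(historiesUsed))
}

## ---------------------------------------------------------------------------
## Simulation / reconstruction configuration and state
## ---------------------------------------------------------------------------

#' Monte Carlo simulation configuration
#'
#' @slot nHistories photon histories per forward projection
#' @slot seed master RNG seed (per-history counter-based substreams are
#'   derived from it, so results are independent of execution order)
#' @slot maxScatterOrder maximum number of Compton scatters before a photon
#'   is dropped
#' @slot penetrationEnabled model knife-edge penetration next to the aperture
#' @slot energyResolutionFWHM detector energy resolution, percent FWHM at
#'   140.5 keV (0 = ideal)
#' @slot poissonSampling draw Poisson counts from the expected counts
#' @slot photonsPerDecay photons emitted per decay (branching fraction)
#' @export
setClass("SimulationConfig",
         representation(nHistories = "numeric", seed = "integer",
                        maxScatterOrder = "integer",
                        penetrationEnabled = "logical",
                        energyResolutionFWHM = "numeric",
                        poissonSampling = "logical",
                        photonsPerDecay = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@nHistories < 1) return("nHistories must be >= 1")
  if (object@maxScatterOrder < 0) return("maxScatterOrder must be >= 0")
  if (object@energyResolutionFWHM < 0)
    return("energyResolutionFWHM must be >= 0")
  if (object@photonsPerDecay <= 0) return("photonsPerDecay must be > 0")
  TRUE
})

#' @param nHistories photon histories
#' @param seed integer master seed
#' @param maxScatterOrder maximum Compton scatter order
#' @param penetrationEnabled logical
#' @param energyResolutionFWHM percent FWHM at 140.5 keV
#' @param poissonSampling logical
#' @param photonsPerDecay photons per decay (default 0.885 for 99mTc 140.5 keV)
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(nHistories = 1e5, seed = 1L, maxScatterOrder = 5L,
                             penetrationEnabled = FALSE,
                             energyResolutionFWHM = 0,
                             poissonSampling = FALSE,
                             photonsPerDecay = 0.885) {
  new("SimulationConfig", nHistories = as.numeric(nHistories),
      seed = as.integer(seed), maxScatterOrder = as.integer(maxScatterOrder),
      penetrationEnabled = isTRUE(penetrationEnabled),
      energyResolutionFWHM = as.numeric(energyResolutionFWHM),
      poissonSampling = isTRUE(poissonSampling),
      photonsPerDecay = as.numeric(photonsPerDecay))
}

#' Dual-matrix ML-EM configuration
#'
#' @slot nIterations number of ML-EM iterations
#' @slot historiesPerIteration Monte Carlo history budget per forward step
#' @slot seed integer master seed; iteration i uses seed + i
#' @slot ratioEpsilon guard for the measured/simulated pixel ratio, as a
#'   fraction of the mean nonzero simulated pixel value
#' @slot initialTotalActivity total MBq of the uniform first estimate
#' @slot postFilter "none", "gaussian" or "butterworth"
#' @export
setClass("ReconstructionConfig",
         representation(nIterations = "integer",
                        historiesPerIteration = "numeric", seed = "integer",
                        ratioEpsilon = "numeric",
                        initialTotalActivity = "numeric",
                        postFilter = "character"))

setValidity("ReconstructionConfig", function(object) {
  if (object@nIterations < 0) return("nIterations must be >= 0")
  if (object@historiesPerIteration < 1)
    return("historiesPerIteration must be >= 1")
  if (object@ratioEpsilon <= 0) return("ratioEpsilon must be > 0")
  if (object@initialTotalActivity <= 0)
    return("initialTotalActivity must be > 0")
  if (!object@postFilter %in% c("none", "gaussian", "butterworth"))
    return("postFilter must be none, gaussian or butterworth")
  TRUE
})

#' @param nIterations iterations
#' @param historiesPerIteration MC budget per iteration
#' @param seed master seed
#' @param ratioEpsilon ratio guard fraction
#' @param initialTotalActivity MBq of the uniform start estimate
#' @param postFilter post-reconstruction filter name
#' @rdname ReconstructionConfig-class
#' @export
reconstructionConfig <- function(nIterations = 20L,
                                 historiesPerIteration = 1e5, seed = 1L,
                                 ratioEpsilon = 0.1,
                                 initialTotalActivity = 1,
                                 postFilter = "none") {
  new("ReconstructionConfig", nIterations = as.integer(nIterations),
      historiesPerIteration = as.numeric(historiesPerIteration),
      seed = as.integer(seed), ratioEpsilon = as.numeric(ratioEpsilon),
      initialTotalActivity = as.numeric(initialTotalActivity),
      postFilter = as.character(postFilter))
}

#' Reconstruction state: paired float and integer source datasets
#'
#' The source estimate is stored twice: as floating-point activity in MBq per
#' voxel (the authoritative dataset) and as an integer history map whose
#' entries sum exactly to the per-iteration Monte Carlo history budget. The
#' integer map drives photon emission in the forward step, which is what ties
#' simulated counts to absolute activity and makes the reconstruction
#' calibration-free.
#'
#' @slot activity an [ActivityMap-class] (MBq per voxel)
#' @slot historyMap integer array, same shape, summing to the history budget
#' @slot iteration iterations completed
#' @export
setClass("ReconstructionState",
         representation(activity = "ActivityMap", historyMap = "array",
                        iteration = "integer"))

setValidity("ReconstructionState", function(object) {
  if (!identical(dim(object@historyMap), dim(object@activity@values)))
    return("historyMap shape must match the activity map")
  if (any(object@historyMap < 0)) return("history counts must be >= 0")
  TRUE
})

#' @param activity an [ActivityMap-class]
#' @param historyMap integer history array
#' @param iteration iterations completed
#' @rdname ReconstructionState-class
#' @export
reconstructionState <- function(activity, historyMap, iteration = 0L) {
  storage.mode(historyMap) <- "integer"
  new("ReconstructionState", activity = activity, historyMap = historyMap,
      iteration = as.integer(iteration))
}
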