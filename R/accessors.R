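## Generics and accessors. Slot access stays internal; user code goes through
## these.

#' Per-voxel values of a volume
#' @param x an ActivityMap or DensityMap
#' @return 3-D numeric array
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "ActivityMap", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "DensityMap", function(x) x@values)

#' Voxel grid of an object
#' @param x object carrying a grid
#' @return a [VoxelGrid-class]
#' @export
setGeneric("grid3d", function(x) standardGeneric("grid3d"))

#' @rdname grid3d
#' @export
setMethod("grid3d", "ActivityMap", function(x) x@grid)

#' @rdname grid3d
#' @export
setMethod("grid3d", "DensityMap", function(x) x@grid)

#' @rdname grid3d
#' @export
setMethod("grid3d", "ReconstructionState", function(x) x@activity@grid)

#' Grid dimensions
#' @param x a [VoxelGrid-class] or object carrying one
#' @return voxels per side
#' @export
gridN <- function(x) {
  if (!is(x, "VoxelGrid")) x <- grid3d(x)
  x@N
}

#' @rdname gridN
#' @return voxel side length (mm)
#' @export
voxelSize <- function(x) {
  if (!is(x, "VoxelGrid")) x <- grid3d(x)
  x@m
}

#' World coordinates of voxel centres along one axis
#'
#' 0-based voxel index \code{i} maps to world coordinate
#' \code{(i - (N - 1)/2) * m} mm; the grid is centred on the origin.
#'
#' @param grid a [VoxelGrid-class]
#' @return numeric vector of length N (mm)
#' @export
axisCoords <- function(grid) {
  (seq_len(grid@N) - 1 - (grid@N - 1) / 2) * grid@m
}

#' Total activity of a map (MBq)
#' @param x an [ActivityMap-class] or [ReconstructionState-class]
#' @export
setGeneric("totalActivity", function(x) standardGeneric("totalActivity"))

#' @rdname totalActivity
#' @export
setMethod("totalActivity", "ActivityMap", function(x) sum(x@values))

#' @rdname totalActivity
#' @export
setMethod("totalActivity", "ReconstructionState",
          function(x) sum(x@activity@values))

#' Activity estimate of a reconstruction
#' @param x a [ReconstructionState-class]
#' @return the float [ActivityMap-class] dataset
#' @export
activityEstimate <- function(x) x@activity

#' Integer history map of a reconstruction
#' @param x a [ReconstructionState-class]
#' @return integer array summing to the history budget
#' @export
historyMap <- function(x) x@historyMap

#' Pinhole units of a camera
#' @param x a [CameraGeometry-class]
#' @return list of [PinholeUnit-class]
#' @export
units3c <- function(x) x@units

#' Number of pinhole-detector units
#' @param x a [CameraGeometry-class]
#' @export
nUnits <- function(x) length(x@units)

#' Field-of-view diameter (mm)
#' @param x a [CameraGeometry-class]
#' @export
fovDiameter <- function(x) x@fovDiameter

#' Projection counts array
#' @param x a [ProjectionSet-class]
#' @return nPix x nPix x K array
#' @export
counts <- function(x) x@counts

#' Acquisition time (s)
#' @param x a [ProjectionSet-class]
#' @export
acquisitionTime <- function(x) x@acquisitionTime

#' Energy window (keV)
#' @param x a [ProjectionSet-class]
#' @return c(low, high)
#' @export
energyWindow <- function(x) x@energyWindow

## show methods -------------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d^3 voxels, %.3g mm side (extent %.4g mm)\n",
              object@N, object@m, object@N * object@m))
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf("ActivityMap: %d^3 voxels x %.3g mm, total %.6g MBq, %d active voxels\n",
              object@grid@N, object@grid@m, sum(object@values),
              sum(object@values > 0)))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d^3 voxels x %.3g mm, density range [%.4g, %.4g] g/cm^3\n",
              object@grid@N, object@grid@m, min(object@values), max(object@values)))
})

setMethod("show", "PinholeUnit", function(object) {
  cat(sprintf("PinholeUnit: theta=%.4g deg phi=%.4g deg R=%.4g mm H=%.4g mm aperture=%.3g mm, %dx%d pixels @ %.4g mm\n",
              object@theta * 180 / pi, object@phi * 180 / pi, object@R,
              object@H, object@apertureDiameter, object@nPix, object@nPix,
              object@pixelPitch))
})

setMethod("show", "CameraGeometry", function(object) {
  cat(sprintf("CameraGeometry: %d pinhole-detector units, FOV %.4g mm\n",
              length(object@units), object@fovDiameter))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@counts)
  cat(sprintf("ProjectionSet: %d projections of %dx%d pixels, %.4g s, window [%.4g, %.4g] keV, total %.6g counts\n",
              d[3], d[1], d[2], object@acquisitionTime,
              object@energyWindow[1], object@energyWindow[2],
              sum(object@counts)))
})

setMethod("show", "ReconstructionState", function(object) {
  cat(sprintf("ReconstructionState: iteration %d, total %.6g MBq, %g histories allocated\n",
              object@iteration, sum(object@activity@values),
              sum(object@historyMap)))
})
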