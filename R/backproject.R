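## Analytical ray-tracing back-projector. Probabilities b_ij are derived
## voxel-by-voxel: each voxel's detector intercept is spread over a
## distance-dependent sampling grid of N_grid x N_grid points covering a
## G_D x G_D square (G_D = m * M), and the per-pixel point counts are
## normalized by the total number of sample points over all K projections.
## The back-projector deliberately ignores attenuation, scatter, the finite
## aperture and the incidence-angle dependence of sensitivity; the
## mismatched accurate/approximate pair is what makes this a dual-matrix
## reconstruction.

#' Heuristic sampling-grid size
#'
#' Number of grid points per side as a function of the voxel-to-pinhole
#' distance: \code{floor(2 + 60 / (1 + dist^0.8) + 0.5)}, with the distance
#' expressed in centimetres (configurable via \code{scale}, the factor that
#' converts mm to the formula's unit). The value is 62 at zero distance and
#' falls monotonically to 2.
#'
#' @param distance voxel-to-pinhole distance R - z' (mm)
#' @param scale conversion from mm to the formula's distance unit
#'   (default 0.1: centimetres)
#' @return integer grid points per side, in [2, 62]
#' @export
gridSize <- function(distance, scale = 0.1) {
  if (any(distance < 0)) stop("distance must be >= 0")
  as.integer(floor(2 + 60 / (1 + (distance * scale)^0.8) + 0.5))
}

#' Detector sampling grid for one voxel and unit
#'
#' @slot nGrid points per side
#' @slot width grid width G_D (mm)
#' @slot center c(xd, yd) detector intercept (mm)
#' @slot points nGrid^2 x 2 matrix of plane coordinates (mm)
#' @export
setClass("SamplingGrid",
         representation(nGrid = "integer", width = "numeric",
                        center = "numeric", points = "matrix"))

setValidity("SamplingGrid", function(object) {
  if (object@nGrid < 2L || object@nGrid > 62L)
    return("nGrid must lie in [2, 62]")
  if (object@width <= 0) return("width must be > 0")
  half <- object@width / 2 + 1e-12
  if (any(abs(object@points[, 1] - object@center[1]) > half) ||
      any(abs(object@points[, 2] - object@center[2]) > half))
    return("points must lie within the grid square")
  TRUE
})

setMethod("show", "SamplingGrid", function(object) {
  cat(sprintf("SamplingGrid: %d x %d points over %.4g mm centred at (%.4g, %.4g)\n",
              object@nGrid, object@nGrid, object@width, object@center[1],
              object@center[2]))
})

#' Build the sampling grid for a voxel
#'
#' Projects the voxel centre to the detector plane, sizes the grid from the
#' voxel-to-pinhole distance and lays out a cell-centred \code{nGrid x
#' nGrid} lattice over the \code{mM x mM} square around the intercept.
#'
#' @param voxelCenter world coordinates of the voxel centre (mm)
#' @param unit a [PinholeUnit-class]
#' @param m voxel side length (mm)
#' @param scale distance-unit conversion passed to [gridSize]
#' @return a [SamplingGrid-class]
#' @export
buildSamplingGrid <- function(voxelCenter, unit, m, scale = 0.1) {
  ic <- projectToDetector(voxelCenter, unit)
  dist <- unit@R - ic@rotated[3]
  ng <- gridSize(dist, scale)
  width <- m * ic@magnification
  offs <- ((seq_len(ng) - 0.5) / ng - 0.5) * width
  pts <- as.matrix(expand.grid(x = ic@xd + offs, y = ic@yd + offs))
  new("SamplingGrid", nGrid = ng, width = width,
      center = c(ic@xd, ic@yd), points = unname(pts))
}

#' Back-projection result
#'
#' @slot volume per-voxel back-projected value (dimensionless)
#' @slot denominatorMap per-voxel total number of sample points
#' @export
setClass("BackprojectionResult",
         representation(volume = "array", denominatorMap = "array"))

setMethod("show", "BackprojectionResult", function(object) {
  cat(sprintf("BackprojectionResult: %s volume, value range [%.4g, %.4g]\n",
              paste(dim(object@volume), collapse = "x"),
              min(object@volume), max(object@volume)))
})

#' @rdname BackprojectionResult-class
#' @param x a BackprojectionResult
#' @export
bpVolume <- function(x) x@volume

#' @rdname BackprojectionResult-class
#' @export
bpDenominator <- function(x) x@denominatorMap

#' Ray-tracing back-projection
#'
#' For every voxel, accumulates over all K units the projection values at
#' the sampling-grid points (off-detector points contribute zero) and
#' divides by the total number of sample points over all units the voxel
#' can project through (z' < R). Uses none of: the density map, the
#' aperture diameter, the incidence angle.
#'
#' @param projections a [ProjectionSet-class] or a bare nPix x nPix x K
#'   array of projection-space values (e.g. measured/simulated ratios)
#' @param geometry a [CameraGeometry-class]
#' @param grid a [VoxelGrid-class]
#' @param scale distance-unit conversion for [gridSize]
#' @param denominator "all" counts every sample point of every usable unit
#'   (the printed normalization); "detected" counts only points landing on
#'   active detector area
#' @return a [BackprojectionResult-class]
#' @export
backproject <- function(projections, geometry, grid, scale = 0.1,
                        denominator = c("all", "detected")) {
  denominator <- match.arg(denominator)
  vals <- if (is(projections, "ProjectionSet")) projections@counts else projections
  d <- dim(vals)
  nPix <- geometry@units[[1]]@nPix
  if (length(d) != 3L || d[1] != nPix || d[2] != nPix ||
      d[3] != length(geometry@units))
    stop("projection shape does not match the geometry")
  res <- .backprojectCpp(as.numeric(vals), .geomMatrix(geometry), grid@N,
                         grid@m, scale,
                         if (denominator == "all") 0L else 1L)
  new("BackprojectionResult", volume = res$volume,
      denominatorMap = res$denominator)
}

#' Sensitivity map of the back-projector
#'
#' Per-voxel sum of back-projection probabilities, Sum_i b_ij, equal to the
#' back-projection of unit-valued projections. It is 1 for voxels whose
#' sampling grids fall entirely on active detector area, in (0, 1]
#' elsewhere, and 0 for voxels invisible to every unit (flagged for
#' exclusion from ML-EM updates). Iteration-independent, so it is computed
#' once per geometry and grid.
#'
#' @param geometry a [CameraGeometry-class]
#' @param grid a [VoxelGrid-class]
#' @param scale distance-unit conversion for [gridSize]
#' @return 3-D array of sensitivities in [0, 1]
#' @export
sensitivityMap <- function(geometry, grid, scale = 0.1) {
  nPix <- geometry@units[[1]]@nPix
  ones <- array(1, dim = c(nPix, nPix, length(geometry@units)))
  bpVolume(backproject(ones, geometry, grid, scale))
}
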