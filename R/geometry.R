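## Coordinate transforms between source space and the pinhole/detector frames.
##
## Each pinhole-detector unit defines a rotated frame in which the z'-axis is
## parallel to the pinhole axis. A source point is rotated into that frame,
## then projected through the (idealized, infinitesimal) pinhole onto the
## detector plane by mirroring and magnification.

#' Rotation matrix into the pinhole frame
#'
#' The composite rotation about the y-axis (azimuth \code{phi}) and x-axis
#' (polar \code{theta}) that maps world coordinates into a frame whose
#' z'-axis is parallel to the pinhole axis. The pinhole-axis direction in
#' world coordinates is \code{c(-sin(phi), cos(phi) sin(theta),
#' cos(phi) cos(theta))}, i.e. the third row of the returned matrix; it maps
#' to +z'.
#'
#' @param theta polar angle (radians)
#' @param phi azimuthal angle (radians)
#' @return 3 x 3 proper rotation matrix
#' @export
pinholeRotation <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)
  matrix(c(cp,  sp * st, sp * ct,
           0,   ct,     -st,
           -sp, cp * st, cp * ct),
         nrow = 3, byrow = TRUE)
}

#' Pinhole axis direction in world coordinates
#' @param unit a [PinholeUnit-class]
#' @return unit 3-vector
#' @export
pinholeAxis <- function(unit) {
  c(-sin(unit@phi),
    cos(unit@phi) * sin(unit@theta),
    cos(unit@phi) * cos(unit@theta))
}

#' Rotate a source point into the pinhole frame
#'
#' @param point 3-vector, world coordinates (mm)
#' @param theta,phi pinhole-axis angles (radians)
#' @return 3-vector (x', y', z') in the pinhole frame (mm)
#' @export
rotateToPinholeFrame <- function(point, theta, phi) {
  stopifnot(length(point) == 3L, all(is.finite(point)))
  as.numeric(pinholeRotation(theta, phi) %*% point)
}

#' Pinhole magnification factor
#'
#' M = H / (R - z') for a source point at axial coordinate z' in the pinhole
#' frame. Only points strictly in front of the pinhole plane (z' < R) have a
#' defined magnification.
#'
#' @param zPrime axial coordinate in the pinhole frame (mm)
#' @param R origin-to-pinhole distance (mm)
#' @param H pinhole-to-detector distance (mm)
#' @return dimensionless magnification (> 0)
#' @export
magnification <- function(zPrime, R, H) {
  if (any(zPrime >= R))
    stop("degenerate voxel: z' >= R (point at or behind the pinhole plane)")
  H / (R - zPrime)
}

#' Detector-plane intercept of a source point
#'
#' A focal line from the source point through the pinhole centre intercepts
#' the detector plane at (x_d, y_d) = (-M x', -M y'): the image is mirrored
#' and magnified. Detector-plane coordinates are measured from the pinhole
#' axis intercept, in the rotated frame.
#'
#' @slot xd,yd intercept coordinates on the detector plane (mm)
#' @slot magnification dimensionless M
#' @slot rotated (x', y', z') source point in the pinhole frame (mm)
#' @export
setClass("DetectorIntercept",
         representation(xd = "numeric", yd = "numeric",
                        magnification = "numeric", rotated = "numeric"))

setValidity("DetectorIntercept", function(object) {
  if (object@magnification <= 0) return("magnification must be > 0")
  if (length(object@rotated) != 3L) return("rotated must be a 3-vector")
  TRUE
})

setMethod("show", "DetectorIntercept", function(object) {
  cat(sprintf("DetectorIntercept: (%.4g, %.4g) mm, M = %.4g\n",
              object@xd, object@yd, object@magnification))
})

#' Project a source point to the detector plane of a unit
#'
#' Perspective projection through an infinitesimal pinhole: the point is
#' rotated into the pinhole frame, then mapped to the detector plane by
#' mirroring and magnification.
#'
#' @param point 3-vector, world coordinates (mm)
#' @param unit a [PinholeUnit-class]
#' @return a [DetectorIntercept-class]
#' @export
projectToDetector <- function(point, unit) {
  p <- rotateToPinholeFrame(point, unit@theta, unit@phi)
  M <- magnification(p[3], unit@R, unit@H)
  new("DetectorIntercept", xd = -M * p[1], yd = -M * p[2],
      magnification = M, rotated = p)
}

#' Detector pixel index for a detector-plane coordinate
#'
#' Maps detector-plane coordinates to a 0-based (row, col) bin of the
#' \code{nPix x nPix} grid centred on the pinhole-axis intercept. Bins are
#' half-open \code{[lower, upper)}: a coordinate exactly on a shared pixel
#' edge belongs to the pixel whose lower edge it is. With \code{nPix = 32}
#' the origin (0, 0) falls in pixel (16, 16). Coordinates outside the active
#' area return the off-detector flag \code{NA}.
#'
#' @param xd,yd detector-plane coordinates (mm); \code{yd} selects the row,
#'   \code{xd} the column
#' @param unit a [PinholeUnit-class]
#' @return integer c(row, col), 0-based, or c(NA, NA) when off-detector
#' @export
detectorPixelIndex <- function(xd, yd, unit) {
  n <- unit@nPix
  col <- floor(xd / unit@pixelPitch + n / 2)
  row <- floor(yd / unit@pixelPitch + n / 2)
  if (col < 0 || col >= n || row < 0 || row >= n)
    return(c(row = NA_integer_, col = NA_integer_))
  c(row = as.integer(row), col = as.integer(col))
}

#' Synthetic multi-pinhole arc geometry
#'
#' Places K pinhole axes at equally spaced polar angles spanning 180 degrees
#' in the transaxial (y-z) plane (theta varies from -90 to +90 degrees,
#' phi = 0), all with common R, H and aperture, and 32 x 32 detector pixels
#' of pitch 78.7/32 mm. This is a configurable stand-in for a curved static
#' cardiac camera; it is deterministic.
#'
#' @param K number of units (>= 1); K = 1 gives a single unit on the +z axis
#' @param R origin-to-pinhole distance (mm)
#' @param H pinhole-to-detector distance (mm)
#' @param aperture pinhole diameter (mm)
#' @param nPix detector pixels per side
#' @param pixelPitch detector element size (mm)
#' @param fov field-of-view diameter (mm)
#' @return a [CameraGeometry-class]
#' @export
defaultArcGeometry <- function(K = 19L, R = 180, H = 120, aperture = 5,
                               nPix = 32L, pixelPitch = 78.7 / 32,
                               fov = 190) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  thetas <- if (K == 1L) 0 else seq(-pi / 2, pi / 2, length.out = K)
  units <- lapply(thetas, function(th)
    pinholeUnit(theta = th, phi = 0, R = R, H = H,
                apertureDiameter = aperture, nPix = nPix,
                pixelPitch = pixelPitch))
  cameraGeometry(units, fovDiameter = fov)
}

## geometry config file -----------------------------------------------------

#' Write a camera geometry to a flat text config
#'
#' One \code{key = value} line per field, with per-unit keys prefixed
#' \code{unit.<k>.}; angles in degrees, distances in mm.
#'
#' @param geometry a [CameraGeometry-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeCameraGeometry <- function(geometry, path) {
  lines <- c("# pinholeMC camera geometry",
             sprintf("n_units = %d", length(geometry@units)),
             sprintf("fov_mm = %.10g", geometry@fovDiameter))
  for (k in seq_along(geometry@units)) {
    u <- geometry@units[[k]]
    pre <- sprintf("unit.%d.", k)
    lines <- c(lines,
               sprintf("%stheta_deg = %.10g", pre, u@theta * 180 / pi),
               sprintf("%sphi_deg = %.10g", pre, u@phi * 180 / pi),
               sprintf("%sR_mm = %.10g", pre, u@R),
               sprintf("%sH_mm = %.10g", pre, u@H),
               sprintf("%saperture_mm = %.10g", pre, u@apertureDiameter),
               sprintf("%sn_pix = %d", pre, u@nPix),
               sprintf("%spitch_mm = %.10g", pre, u@pixelPitch),
               sprintf("%stilt_deg = %.10g", pre, u@detectorTilt * 180 / pi),
               sprintf("%scollimator_mu = %.10g", pre, u@collimatorMu))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a camera geometry config written by [writeCameraGeometry]
#' @param path config file
#' @return a [CameraGeometry-class]
#' @export
readCameraGeometry <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[grepl("=", raw, fixed = TRUE) & !grepl("^\\s*#", raw)]
  keys <- trimws(sub("=.*$", "", raw))
  vals <- trimws(sub("^[^=]*=", "", raw))
  getv <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("missing geometry key: ", key)
      return(default)
    }
    as.numeric(vals[i])
  }
  K <- as.integer(getv("n_units"))
  units <- lapply(seq_len(K), function(k) {
    pre <- sprintf("unit.%d.", k)
    pinholeUnit(theta = getv(paste0(pre, "theta_deg")) * pi / 180,
                phi = getv(paste0(pre, "phi_deg")) * pi / 180,
                R = getv(paste0(pre, "R_mm")),
                H = getv(paste0(pre, "H_mm")),
                apertureDiameter = getv(paste0(pre, "aperture_mm")),
                nPix = as.integer(getv(paste0(pre, "n_pix"))),
                pixelPitch = getv(paste0(pre, "pitch_mm")),
                detectorTilt = getv(paste0(pre, "tilt_deg"), 0) * pi / 180,
                collimatorMu = getv(paste0(pre, "collimator_mu"), 3.7))
  })
  cameraGeometry(units, fovDiameter = getv("fov_mm", 190))
}
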