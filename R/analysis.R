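## Quantification and image-quality analyses: spherical VOIs, activity
## recovery coefficients, the point-source spatial-integrity procedure,
## line profiles, post-filters, MIPs.

#' Spherical volume-of-interest mask
#'
#' Voxel-centre-inclusion mask of a sphere. A diameter smaller than one
#' voxel degenerates to the single voxel nearest the centre.
#'
#' @param grid a [VoxelGrid-class]
#' @param center sphere centre, world mm
#' @param diameter VOI diameter (mm)
#' @return logical 3-D array
#' @export
sphericalVOIMask <- function(grid, center = c(0, 0, 0), diameter) {
  stopifnot(diameter > 0)
  co <- .coordArrays(grid)
  mask <- (co$x - center[1])^2 + (co$y - center[2])^2 +
    (co$z - center[3])^2 <= (diameter / 2)^2
  if (!any(mask)) {
    cc <- axisCoords(grid)
    idx <- vapply(seq_len(3L), function(a)
      which.min(abs(cc - center[a])), integer(1))
    mask[idx[1], idx[2], idx[3]] <- TRUE
  }
  mask
}

#' Activity recovery coefficient
#'
#' ARC = A_E / A_R, the masked-volume activity estimate over the reference
#' activity. With the VOI diameter equal to the physical sphere diameter
#' this is the ARC; with 8 mm (two voxel sides) added to the diameter it is
#' the total activity recovery coefficient (TARC), which also collects
#' counts displaced by the finite spatial resolution.
#'
#' @param volume an [ActivityMap-class] or bare 3-D array (MBq per voxel)
#' @param mask logical VOI mask
#' @param reference reference activity A_R (MBq)
#' @param voiKind label: "physical", "plus-8-mm" or "twice-diameter"
#' @return one-row data.frame with columns \code{AE}, \code{AR},
#'   \code{coefficient}, \code{voiKind}
#' @export
recoveryCoefficient <- function(volume, mask, reference,
                                voiKind = c("physical", "plus-8-mm",
                                            "twice-diameter")) {
  voiKind <- match.arg(voiKind)
  stopifnot(reference > 0)
  v <- if (is(volume, "ActivityMap")) values(volume) else volume
  if (!any(mask)) stop("empty VOI mask")
  ae <- sum(v[mask])
  data.frame(AE = ae, AR = reference, coefficient = ae / reference,
             voiKind = voiKind)
}

# zero-padded array shift by integer offsets
.shift3 <- function(a, dx, dy, dz) {
  N <- dim(a)
  out <- array(0, dim = N)
  sx <- max(1, 1 + dx):min(N[1], N[1] + dx)
  sy <- max(1, 1 + dy):min(N[2], N[2] + dy)
  sz <- max(1, 1 + dz):min(N[3], N[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

#' Truncated 3-D Gaussian filter
#'
#' Separable Gaussian kernel with standard deviation \code{sigma} voxels,
#' truncated to a \code{kernelSize^3} support and renormalized to unit sum
#' (renormalization preserves total activity for interior sources).
#'
#' @param volume 3-D array
#' @param sigma standard deviation in voxels
#' @param kernelSize odd kernel side length
#' @return filtered array
#' @export
gaussianFilter3d <- function(volume, sigma = 1, kernelSize = 7L) {
  stopifnot(kernelSize %% 2 == 1)
  half <- (kernelSize - 1) / 2
  offs <- -half:half
  k1 <- exp(-offs^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  out <- array(0, dim = dim(volume))
  for (i in seq_along(offs))
    for (j in seq_along(offs))
      for (l in seq_along(offs)) {
        w <- k1[i] * k1[j] * k1[l]
        out <- out + w * .shift3(volume, offs[i], offs[j], offs[l])
      }
  out
}

#' Radially symmetric 3-D Butterworth low-pass filter
#'
#' Frequency-domain gain \code{1 / sqrt(1 + (f / fc)^(2 n))} applied to the
#' 3-D FFT of the volume, with \code{f} the radial spatial frequency in
#' cycles/cm. \code{fc} is the -3 dB cut-off frequency of this gain
#' definition. DC gain is 1, so the volume mean is preserved.
#'
#' @param volume 3-D array
#' @param cutoff cut-off frequency (1/cm)
#' @param order filter order n
#' @param voxel voxel side length (mm)
#' @return filtered array
#' @export
butterworthFilter <- function(volume, cutoff = 0.5, order = 2, voxel = 4) {
  stopifnot(cutoff > 0)
  N <- dim(volume)
  d <- voxel / 10  # cm per voxel
  fr <- lapply(N, function(n) (((0:(n - 1) + floor(n / 2)) %% n) -
                                 floor(n / 2)) / (n * d))
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
  gain <- 1 / sqrt(1 + (sqrt(f2) / cutoff)^(2 * order))
  Re(fft(fft(volume) * gain, inverse = TRUE)) / prod(N)
}

#' Maximum-intensity projection
#'
#' @param volume 3-D array
#' @param axis axis to project along (1, 2 or 3)
#' @return 2-D matrix of per-ray maxima
#' @export
mip <- function(volume, axis = 3L) {
  apply(volume, setdiff(1:3, axis), max)
}

#' Binary dilation of a voxel mask
#'
#' @param mask logical 3-D array
#' @param kernelSize odd cubic kernel side length
#' @return dilated logical array (superset of the input)
#' @export
dilateMask <- function(mask, kernelSize = 3L) {
  stopifnot(kernelSize %% 2 == 1)
  half <- (kernelSize - 1) / 2
  out <- array(FALSE, dim = dim(mask))
  for (dx in -half:half)
    for (dy in -half:half)
      for (dz in -half:half)
        out <- out | (.shift3(mask, dx, dy, dz) > 0)
  out
}

#' Averaged line profile
#'
#' Mean of \code{nRows} adjacent rows centred at \code{rowCenter}, taken in
#' a 2-D slice of the volume. The profile runs along \code{axis}; rows are
#' indexed along the remaining in-plane axis.
#'
#' @param volume 3-D array
#' @param rowCenter centre row index (1-based, along the in-plane axis
#'   perpendicular to the profile)
#' @param axis axis the profile runs along (1, 2 or 3)
#' @param slice slice index along \code{sliceAxis}
#' @param sliceAxis axis perpendicular to the extracted slice
#' @param nRows number of rows averaged (odd)
#' @return numeric profile vector
#' @export
lineProfile <- function(volume, rowCenter, axis = 1L, slice = NULL,
                        sliceAxis = 3L, nRows = 7L) {
  stopifnot(nRows %% 2 == 1, axis != sliceAxis)
  if (is.null(slice)) slice <- ceiling(dim(volume)[sliceAxis] / 2)
  idx <- list(TRUE, TRUE, TRUE)
  idx[[sliceAxis]] <- slice
  img <- do.call(`[`, c(list(volume), idx))  # 2-D slice, in-plane axes in order
  inPlane <- sort(setdiff(1:3, sliceAxis))
  half <- (nRows - 1) / 2
  rows <- (rowCenter - half):(rowCenter + half)
  rowDim <- if (axis == inPlane[1]) 2L else 1L
  if (min(rows) < 1 || max(rows) > dim(img)[rowDim])
    stop("rows out of bounds")
  if (axis == inPlane[1]) {
    rowMeans(img[, rows, drop = FALSE])
  } else {
    colMeans(img[rows, , drop = FALSE])
  }
}

#' Spatial-integrity analysis of reconstructed point-source grids
#'
#' For each reconstructed volume: applies a truncated 3-D Gaussian filter
#' (sigma = 1 voxel, 7x7x7 kernel), locates the maximum-value voxel, groups
#' the source positions into planes of the true measurement grid, averages
#' the located coordinates within each plane, and reports the mean distance
#' between adjacent planes (in mm) together with the standard deviation of
#' the per-point adjacent differences.
#'
#' @param reconstructions list of [ActivityMap-class] or 3-D arrays, one
#'   per source position
#' @param positions matrix of true source positions (mm), one row per
#'   reconstruction (as attached by [makePointSourceGrid])
#' @param grid a [VoxelGrid-class]
#' @param filterSigma Gaussian sigma in voxels (NULL skips filtering)
#' @param kernelSize Gaussian kernel side length
#' @return data.frame with columns \code{axis} ("x", "y", "z"),
#'   \code{pair} (adjacent plane pair label), \code{meanDistance} (mm) and
#'   \code{sdDistance} (mm)
#' @export
planeDistanceAnalysis <- function(reconstructions, positions, grid,
                                  filterSigma = 1, kernelSize = 7L) {
  vols <- lapply(reconstructions, function(v)
    if (is(v, "ActivityMap")) values(v) else v)
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("volumes have mismatched shapes")
  if (nrow(positions) != length(vols))
    stop("need one volume per source position")
  peaks <- t(vapply(vols, function(v) {
    if (!is.null(filterSigma)) v <- gaussianFilter3d(v, filterSigma, kernelSize)
    idx <- arrayInd(which.max(v), dim(v))
    as.numeric(idx)
  }, numeric(3)))
  axes <- c("x", "y", "z")
  out <- list()
  for (a in 1:3) {
    planeVals <- sort(unique(positions[, a]))
    if (length(planeVals) < 2) next
    members <- lapply(planeVals, function(pv) which(positions[, a] == pv))
    # pair up points across adjacent planes by their true in-plane coords
    other <- setdiff(1:3, a)
    keyOf <- function(i) paste(positions[i, other], collapse = "/")
    for (pp in seq_len(length(planeVals) - 1)) {
      i1 <- members[[pp]]; i2 <- members[[pp + 1]]
      m1 <- mean(peaks[i1, a]); m2 <- mean(peaks[i2, a])
      k1 <- vapply(i1, keyOf, ""); k2 <- vapply(i2, keyOf, "")
      match12 <- match(k1, k2)
      dpt <- (peaks[i2[match12], a] - peaks[i1, a]) * grid@m
      out[[length(out) + 1]] <- data.frame(
        axis = axes[a], pair = sprintf("%d-%d", pp, pp + 1),
        meanDistance = (m2 - m1) * grid@m,
        sdDistance = stats::sd(dpt))
    }
  }
  do.call(rbind, out)
}
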