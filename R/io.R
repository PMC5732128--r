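## File formats: Interfile-3.0-style text header + raw binary for
## projection sets, raw float32 + text sidecar for volumes, and JSON
## reproducibility manifests. Binary data are little-endian throughout,
## with the byte order recorded in the headers.

.interfileKnownKeys <- c(
  "interfile", "imaging modality", "number format",
  "number of bytes per pixel", "imagedata byte order", "matrix size [1]",
  "matrix size [2]", "number of projections", "scaling factor (mm/pixel) [1]",
  "scaling factor (mm/pixel) [2]", "image duration (sec)",
  "energy window lower level [1]", "energy window upper level [1]",
  "number of histories", "name of data file", "end of interfile")

#' Write a projection set in Interfile-style format
#'
#' Writes a text header (\code{key := value} records) and a companion raw
#' little-endian float32 binary holding the count images in
#' row-fastest, projection-slowest order.
#'
#' @param projections a [ProjectionSet-class]
#' @param path header file path; the data file uses the same stem with
#'   extension \code{.img}
#' @return invisibly, the header path
#' @export
writeProjections <- function(projections, path) {
  stem <- sub("\\.[^./]*$", "", path)
  dataPath <- paste0(stem, ".img")
  d <- dim(projections@counts)
  hdr <- c(
    "!INTERFILE :=",
    "!imaging modality := nucmed",
    "!number format := float",
    "!number of bytes per pixel := 4",
    "imagedata byte order := LITTLEENDIAN",
    sprintf("!matrix size [1] := %d", d[1]),
    sprintf("!matrix size [2] := %d", d[2]),
    sprintf("!number of projections := %d", d[3]),
    sprintf("image duration (sec) := %.10g", projections@acquisitionTime),
    sprintf("energy window lower level [1] := %.10g",
            projections@energyWindow[1]),
    sprintf("energy window upper level [1] := %.10g",
            projections@energyWindow[2]),
    sprintf("number of histories := %.10g", projections@historiesUsed),
    sprintf("!name of data file := %s", basename(dataPath)),
    "!END OF INTERFILE :=")
  writeLines(hdr, path)
  con <- file(dataPath, "wb")
  on.exit(close(con))
  writeBin(as.numeric(projections@counts), con, size = 4,
           endian = "little")
  invisible(path)
}

# parse "key := value" lines; '!' prefixes stripped, ';' comment lines and
# case differences tolerated
.parseInterfile <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(;|$)", raw)]
  hit <- grepl(":=", raw, fixed = TRUE)
  raw <- raw[hit]
  keys <- tolower(trimws(sub("^\\s*!?", "", sub(":=.*$", "", raw))))
  vals <- trimws(sub("^.*?:=", "", raw))
  names(vals) <- keys
  vals
}

#' Read a projection set written by [writeProjections]
#'
#' Malformed headers and header/binary size mismatches raise errors naming
#' the offending key; unknown header keys are ignored with a warning.
#'
#' @param path header file path
#' @return a [ProjectionSet-class]
#' @export
readProjections <- function(path) {
  kv <- .parseInterfile(path)
  unknown <- setdiff(names(kv), .interfileKnownKeys)
  if (length(unknown) > 0)
    warning("ignoring unknown header keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  look <- function(key) if (key %in% names(kv)) kv[[key]] else NULL
  need <- function(key) {
    v <- look(key)
    if (is.null(v)) stop("malformed header: missing key '", key, "'")
    v
  }
  n1 <- as.integer(need("matrix size [1]"))
  n2 <- as.integer(need("matrix size [2]"))
  K <- as.integer(need("number of projections"))
  if (any(is.na(c(n1, n2, K))))
    stop("malformed header: non-numeric matrix size / number of projections")
  dataPath <- file.path(dirname(path), need("name of data file"))
  if (!file.exists(dataPath)) stop("data file not found: ", dataPath)
  expected <- as.numeric(n1) * n2 * K
  sz <- file.info(dataPath)$size
  if (sz != expected * 4)
    stop("size mismatch for 'name of data file': expected ", expected * 4,
         " bytes from matrix size keys, found ", sz)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = expected, size = 4, endian = "little")
  cnt <- array(vals, dim = c(n1, n2, K))
  projectionSet(cnt,
                acquisitionTime = as.numeric(look("image duration (sec)") %||% 1),
                energyWindow = c(
                  as.numeric(look("energy window lower level [1]") %||% 0),
                  as.numeric(look("energy window upper level [1]") %||% Inf)),
                historiesUsed = as.numeric(look("number of histories") %||% 0))
}

#' Write a volume as raw float32 plus a text sidecar
#'
#' @param volume an [ActivityMap-class] or [DensityMap-class]
#' @param path data file path (e.g. \code{vol.img}); the sidecar uses the
#'   same stem with extension \code{.hdr}
#' @return invisibly, the path
#' @export
writeVolume <- function(volume, path) {
  stem <- sub("\\.[^./]*$", "", path)
  unitTag <- if (is(volume, "ActivityMap")) "MBq" else "g/cm3"
  grid <- grid3d(volume)
  writeLines(c(sprintf("N = %d", grid@N),
               sprintf("m_mm = %.10g", grid@m),
               sprintf("units = %s", unitTag),
               "format = float32",
               "byte_order = little"),
             paste0(stem, ".hdr"))
  con <- file(paste0(stem, ".img"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(values(volume)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a volume written by [writeVolume]
#'
#' @param path data file path (stem resolves the \code{.hdr} sidecar)
#' @return an [ActivityMap-class] (units MBq) or [DensityMap-class]
#'   (units g/cm3)
#' @export
readVolume <- function(path) {
  stem <- sub("\\.[^./]*$", "", path)
  hdrPath <- paste0(stem, ".hdr")
  if (!file.exists(hdrPath)) stop("missing sidecar header: ", hdrPath)
  raw <- readLines(hdrPath, warn = FALSE)
  raw <- raw[grepl("=", raw, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", raw))
  vals <- trimws(sub("^[^=]*=", "", raw))
  N <- as.integer(vals[match("N", keys)])
  m <- as.numeric(vals[match("m_mm", keys)])
  unitTag <- vals[match("units", keys)]
  dataPath <- paste0(stem, ".img")
  expected <- as.numeric(N)^3
  if (file.info(dataPath)$size != expected * 4)
    stop("size mismatch: sidecar N = ", N, " implies ", expected * 4,
         " bytes, data file has ", file.info(dataPath)$size)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  v <- array(readBin(con, "numeric", n = expected, size = 4,
                     endian = "little"), dim = rep(N, 3L))
  v[v < 0] <- 0  # clamp float32 round-off
  grid <- voxelGrid(N, m)
  if (identical(unitTag, "g/cm3")) densityMap(grid, v)
  else activityMap(grid, v)
}

#' Write a reproducibility manifest
#'
#' JSON record of all run parameters, the master seed, and package and R
#' versions, written beside a command's outputs.
#'
#' @param params named list of parameters
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeManifest <- function(params, path) {
  params$package <- as.character(utils::packageVersion("pinholeMC"))
  params$rversion <- as.character(getRversion())
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
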