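#' Calibrated voxel volume
#'
#' Container for a 3D grayscale micro-CT-like image whose values are
#' hydroxyapatite-calibrated densities (mg HA/cm^3).  The third array index is
#' the scan (and loading) axis.  Voxel indices are 0-based in the coordinate
#' convention: the center of voxel `(i, j, k)` (1-based array index) sits at
#' `origin + (c(i, j, k) - 0.5) * voxel_size` micrometers.
#'
#' @param data 3D numeric array of calibrated density (mg HA/cm^3).
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @param origin physical offset of the array corner, micrometers (length 3).
#' @param calibration list with `slope` and `intercept` mapping raw
#'   attenuation to mg HA/cm^3; identity by default.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                         calibration = list(slope = 1, intercept = 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometers)")
  if (!all(is.finite(data))) stop("`data` must be finite everywhere")
  if (calibration$slope <= 0) stop("calibration slope must be > 0")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin), calibration = calibration),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.3g um isotropic\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  density range %.1f .. %.1f mg HA/cm^3\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# physical coordinates (um) of voxel centers along one axis
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size
}

#' Write / read a voxel volume as raw float32 with a JSON sidecar
#'
#' The raw block is little-endian float32 in column-major (x fastest) order;
#' the sidecar records shape, voxel size and calibration so the pair is
#' self-describing.
#'
#' @param vol a [voxel_volume()].
#' @param path output path for the `.raw` file; the sidecar is written next
#'   to it with extension `.json`.
#' @return `write_volume_raw` returns `path` invisibly; `read_volume_raw`
#'   returns a [voxel_volume()].
#' @export
write_volume_raw <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  side <- sub("\\.raw$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(shape = dim(vol$data), voxel_size_um = vol$voxel_size,
         origin_um = vol$origin, calibration = vol$calibration),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(path) {
  side <- sub("\\.raw$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  voxel_volume(array(v, dim = meta$shape), meta$voxel_size_um,
               origin = meta$origin_um %||% c(0, 0, 0),
               calibration = as.list(meta$calibration))
}

#' Write / read a voxel volume in MetaImage (.mha) format
#'
#' Single-file MetaImage with an uncompressed little-endian float32 block,
#' readable by ITK-based tools.
#'
#' @inheritParams write_volume_raw
#' @export
write_volume_mha <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  hdr <- paste0(
    "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
    "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    sprintf("Offset = %g %g %g\n", vol$origin[1], vol$origin[2], vol$origin[3]),
    "CenterOfRotation = 0 0 0\nAnatomicalOrientation = RAI\n",
    sprintf("ElementSpacing = %g %g %g\n",
            vol$voxel_size, vol$voxel_size, vol$voxel_size),
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    "ElementType = MET_FLOAT\nElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_volume_mha
#' @export
read_volume_mha <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  # header ends at the newline terminating the ElementDataFile line
  hdr_end <- NA_integer_
  start <- 1L
  hdr <- character()
  for (p in nl) {
    line <- rawToChar(bytes[start:(p - 1L)])
    hdr <- c(hdr, line)
    start <- p + 1L
    if (grepl("^ElementDataFile", line)) { hdr_end <- p; break }
  }
  if (is.na(hdr_end)) stop("malformed MetaImage header")
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  d <- as.integer(strsplit(get_field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get_field("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(get_field("Offset"), " +")[[1]])
  if (get_field("ElementType") != "MET_FLOAT")
    stop("only MET_FLOAT MetaImage volumes are supported")
  v <- readBin(bytes[(hdr_end + 1L):length(bytes)], "numeric",
               n = prod(d), size = 4L, endian = "little")
  voxel_volume(array(v, dim = d), sp[1], origin = off)
}
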