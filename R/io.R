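# Volume I/O: NIfTI (via RNifti) with a JSON sidecar carrying the label ->
# optical-property table, plus a raw little-endian float binary fallback.
# Conventions: 0-based voxel indices in metadata, positions in mm at voxel
# centers, arrays stored in column-major ("F"/R) order.

#' Write a phantom to disk (NIfTI label grid + JSON property sidecar)
#'
#' @param phantom an \code{mc_phantom}
#' @param path output path ending in \code{.nii}
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "mc_phantom"))
  arr <- phantom$label_grid + 0L
  attr(arr, "pixdim") <- rep(phantom$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(voxel_size_mm = phantom$voxel_size,
         grid_shape = dim(phantom$label_grid),
         properties = phantom$properties),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phantom written by \code{\link{write_phantom}}
#' @param path path to the \code{.nii} label grid
#' @export
read_phantom <- function(path) {
  if (!file.exists(path)) stop("phantom volume not found: ", path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("phantom property sidecar not found: ", side)
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  grid <- array(as.integer(img), dim = dim(img))
  structure(list(label_grid = grid,
                 properties = as.data.frame(meta$properties),
                 voxel_size = meta$voxel_size_mm),
            class = "mc_phantom")
}

#' Write a fluence volume as NIfTI float with a JSON sidecar
#' @param vol a \code{fluence_volume}
#' @param path output path ending in \code{.nii}
#' @export
write_fluence <- function(vol, path) {
  stopifnot(inherits(vol, "fluence_volume"))
  arr <- vol$values
  attr(arr, "pixdim") <- rep(vol$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(voxel_size_mm = vol$voxel_size, grid_shape = dim(vol$values),
         photon_count = vol$photon_count, seed = vol$seed,
         time_gate_ns = vol$time_gate_ns),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fluence volume written by \code{\link{write_fluence}}
#' @param path path to the \code{.nii} file
#' @export
read_fluence <- function(path) {
  if (!file.exists(path)) stop("fluence volume not found: ", path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  img <- RNifti::readNifti(path)
  fluence_volume(array(as.numeric(img), dim = dim(img)),
                 voxel_size = meta$voxel_size_mm %||% RNifti::pixdim(img)[1],
                 photon_count = meta$photon_count %||% NA_real_,
                 seed = meta$seed %||% NA_integer_,
                 time_gate_ns = meta$time_gate_ns %||% NA_real_)
}

#' Write a raw little-endian float32 volume with a JSON sidecar
#' @param values 3D numeric array
#' @param path output path (sidecar written as \code{path.json})
#' @param voxel_size voxel edge length in mm
#' @export
write_raw_volume <- function(values, path, voxel_size = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(shape = dim(values), dtype = "float32",
         voxel_size_mm = voxel_size, order = "F"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw volume written by \code{\link{write_raw_volume}}
#' @param path path to the raw binary
#' @export
read_raw_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  array(vals, dim = meta$shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
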