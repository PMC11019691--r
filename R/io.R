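# TIFF + JSON-sidecar I/O. Images travel as 32-bit float multi-page TIFF
# (see tiff_io.R for the codec); the sidecar carries voxel sizes and
# frame-order metadata.

#' Write an image stack as multi-page float TIFF with a JSON sidecar
#'
#' @param stack `ny x nx` matrix or `ny x nx x n` array.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param voxel Optional voxel sizes `c(z, y, x)` in nm, stored in the
#'   sidecar.
#' @param metadata Optional named list of extra metadata (e.g. the frame
#'   index order) stored verbatim in the sidecar.
#' @param format `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, voxel = NULL, metadata = list(),
                             format = "float32") {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff_write(pages, path, format = format)
  side <- list(format = format, n_pages = dim(stack)[3],
               dim = dim(stack), metadata = metadata)
  if (!is.null(voxel)) side$voxel_nm <- as.list(psf_voxel(voxel))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_tiff_stack()]
#'
#' @param path TIFF path. A missing sidecar triggers a warning and
#'   defaults (no voxel sizes, empty metadata).
#' @return `ny x nx x n` array with attributes `voxel` (named nm vector or
#'   `NULL`) and `metadata`.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  pages <- tiff_read(path)
  side_path <- paste0(path, ".json")
  voxel <- NULL; metadata <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$voxel_nm)) voxel <- unlist(side$voxel_nm)
    metadata <- side$metadata
  } else {
    warning("missing sidecar ", side_path, "; no voxel sizes available")
  }
  arr <- simplify2array(pages)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  attr(arr, "voxel") <- voxel
  attr(arr, "metadata") <- metadata
  arr
}

#' Persist a raw acquisition to disk
#'
#' Writes the camera frames as one multi-page TIFF (frame order:
#' timepoint-major, then z-step, orientation, phase — phase fastest) and
#' a JSON sidecar holding the full configuration, the frame index table
#' and the simulation ground truth.
#'
#' @param raw A `raw_acquisition`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @return The directory, invisibly.
#' @export
write_acquisition <- function(raw, dir, name = "raw") {
  stopifnot(inherits(raw, "raw_acquisition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff_stack(raw$frames, file.path(dir, paste0(name, ".tif")),
                   voxel = c(z = raw$mf$dz, y = raw$cfg$px_sample,
                             x = raw$cfg$px_sample),
                   metadata = list(frame_order = "timepoint,zstep,orientation,phase",
                                   index = raw$index))
  cfgs <- list(cfg = unclass(raw$cfg), pat = unclass(raw$pat),
               mf = unclass(raw$mf), cam = unclass(raw$cam),
               timing = unclass(raw$timing), widefield = raw$widefield,
               ground_truth = list(jitter = raw$ground_truth$jitter,
                                   plane_z = raw$ground_truth$plane_z,
                                   phantom_label = raw$ground_truth$phantom_label))
  jsonlite::write_json(cfgs, file.path(dir, paste0(name, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize a tile map or shift set to JSON
#'
#' @param x A `tile_map` or the `shifts` matrix of
#'   [subpixel_align_stack()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_registration_json <- function(x, path) {
  obj <- if (inherits(x, "tile_map")) {
    list(type = "tile_map", origin = x$origin, offset = x$offset,
         tile_px = x$tile_px, z_offsets = x$z_offsets,
         reference = x$reference)
  } else list(type = "shift_set", shifts = x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tile map serialized by [write_registration_json()]
#'
#' @param path JSON path.
#' @return A `tile_map` object.
#' @export
read_tile_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "tile_map")) stop("not a tile_map JSON")
  structure(list(origin = matrix(obj$origin, ncol = 2,
                                 dimnames = list(NULL, c("row", "col"))),
                 offset = matrix(obj$offset, ncol = 2,
                                 dimnames = list(NULL, c("row", "col"))),
                 tile_px = obj$tile_px, z_offsets = obj$z_offsets,
                 reference = obj$reference),
            class = "tile_map")
}
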