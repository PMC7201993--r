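#' Volume file input/output (NIfTI-1)
#'
#' Binary masks are written as unsigned 8-bit NIfTI volumes, probability and
#' statistic maps as 32-bit float. The voxel size is stored in the header
#' (pixdim); all analysis happens in voxel index space, so the affine written
#' is the diagonal scaling by the voxel size.
#'
#' @param vol logical/integer (mask) or numeric (map) 3-D array.
#' @param grid a [volume_grid()].
#' @param path output file; use `.nii` for uncompressed (byte-reproducible)
#'   output or `.nii.gz` for compressed.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(vol) || !identical(dim(vol), as.integer(grid$shape)))
    stop("volume dimensions do not match the grid")
  binary <- is.logical(vol) ||
    (is.numeric(vol) && all(as.vector(vol) %in% c(0, 1)))
  dt <- if (binary) "uint8" else "float"
  storage.mode(vol) <- if (binary) "integer" else "double"
  attr(vol, "pixdim") <- grid$voxel_size_mm
  img <- RNifti::asNifti(vol, datatype = dt)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return `read_volume_nifti`: list with `vol` (array) and `grid`.
#' @param orientation axis orientation to attach to the grid (the analysis
#'   convention; header orientation is not reinterpreted).
#' @export
read_volume_nifti <- function(path, orientation = c("R", "A", "S")) {
  img <- RNifti::readNifti(path)
  vol <- array(as.vector(img), dim = dim(img))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  grid <- volume_grid(dim(img), abs(pd[1:3]), orientation)
  list(vol = vol, grid = grid)
}

#' Read / write lesion masks as NIfTI
#'
#' `write_mask_nifti` stores the binary voxels as uint8; `read_mask_nifti`
#' reconstructs a [lesion_mask()] (metadata comes from the arguments, not the
#' header). Round-tripping a mask through a `.nii` file is exact.
#'
#' @param mask a [lesion_mask()].
#' @param path NIfTI file path.
#' @inheritParams read_volume_nifti
#' @inheritParams lesion_mask
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_volume_nifti(mask$voxels, mask$grid, path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, subject_id = "subject",
                            group = NA_character_, side = "right",
                            orientation = c("R", "A", "S")) {
  x <- read_volume_nifti(path, orientation)
  lesion_mask(x$vol != 0, x$grid, subject_id = subject_id, group = group,
              side = side)
}
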