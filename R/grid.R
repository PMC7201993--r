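#' Define the shared sampling grid for all volumes
#'
#' A `volume_grid` describes the discrete lattice every map in an analysis
#' lives on: the number of voxels per axis, the voxel size in millimetres and
#' the anatomical orientation of the axes. All volumes in a study (lesions,
#' disconnectome maps, statistic maps, atlases) must share one grid; maps are
#' stored and compared in voxel index space, and any template affine is
#' carried as metadata only.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0). A standard 2 mm isotropic template grid is `c(2, 2, 2)`.
#' @param orientation character vector of length 3 giving the anatomical
#'   direction of increasing index on each axis, one of `"R"`, `"L"` (left-
#'   right), `"A"`, `"P"` (posterior-anterior), `"S"`, `"I"` (inferior-
#'   superior). Exactly one axis must be labelled `"R"` or `"L"` so that
#'   hemisphere flipping is well defined. Default `c("R","A","S")` (RAS).
#'
#' @return an object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(91, 109, 91), c(2, 2, 2))
#' voxel_volume(g) # 8 mm^3
volume_grid <- function(shape, voxel_size_mm = c(1, 1, 1),
                        orientation = c("R", "A", "S")) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("`shape` must be 3 integers, all >= 1")
  if (length(voxel_size_mm) != 3L || anyNA(voxel_size_mm) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers")
  orientation <- toupper(as.character(orientation))
  valid <- c("R", "L", "A", "P", "S", "I")
  if (length(orientation) != 3L || !all(orientation %in% valid))
    stop("`orientation` must be 3 axis labels from R/L/A/P/S/I")
  if (sum(orientation %in% c("R", "L")) != 1L)
    stop("exactly one axis must be the left-right axis (label R or L)")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         orientation = orientation),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm, orientation %s\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              paste(x$orientation, collapse = "")))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param grid a [volume_grid()].
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$voxel_size_mm)
}

#' Index of the left-right axis of a grid
#' @param grid a [volume_grid()].
#' @return integer in 1:3, the axis along which hemisphere flipping mirrors.
#' @export
lr_axis <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  which(grid$orientation %in% c("R", "L"))
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    identical(a$orientation, b$orientation)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

# Coerce a volume argument (3-D array or lesion_mask) to a logical array on
# the expected grid; used by every operation taking "a binary volume".
as_binary_array <- function(x, grid = NULL, what = "volume") {
  if (inherits(x, "lesion_mask")) {
    if (!is.null(grid)) check_same_grid(x$grid, grid, what)
    return(x$voxels)
  }
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a 3-D array or a lesion_mask", what))
  if (!is.null(grid) && !identical(dim(x), as.integer(grid$shape)))
    stop(sprintf("%s dimensions do not match the grid", what))
  v <- x
  if (!is.logical(v)) {
    u <- unique(as.vector(v))
    if (!all(u %in% c(0, 1)))
      stop(sprintf("%s is not binary (values other than 0/1 found)", what))
    v <- array(as.logical(v), dim = dim(v))
  }
  v
}
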