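#' Create a lesion mask on a grid
#'
#' Wraps one subject's binary lesion volume together with its metadata. The
#' lesion volume in mm^3 is derived on construction as
#' (number of lesioned voxels) x (voxel volume).
#'
#' @param voxels logical (or 0/1) 3-D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param subject_id subject identifier string.
#' @param group group label (e.g. `"AHP"` or `"HP"`).
#' @param side lesion hemisphere, `"left"`, `"right"` or `"bilateral"`.
#' @return an object of class `lesion_mask` with fields `grid`, `voxels`,
#'   `subject_id`, `group`, `side` and `volume_mm3`.
#' @export
lesion_mask <- function(voxels, grid, subject_id = "subject", group = NA_character_,
                        side = c("right", "left", "bilateral")) {
  stopifnot(inherits(grid, "volume_grid"))
  side <- match.arg(side)
  v <- as_binary_array(voxels, grid, "lesion mask")
  m <- structure(
    list(grid = grid, voxels = v, subject_id = as.character(subject_id),
         group = as.character(group), side = side, volume_mm3 = NA_real_),
    class = "lesion_mask"
  )
  m$volume_mm3 <- lesion_volume(m)
  m
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s (group %s, side %s): %d voxels, %.1f mm^3\n",
              x$subject_id, x$group, x$side, sum(x$voxels), x$volume_mm3))
  invisible(x)
}

#' Lesion volume in cubic millimetres
#'
#' Counts lesioned voxels and multiplies by the voxel volume.
#'
#' @param mask a [lesion_mask()] or a binary 3-D array (then `grid` required).
#' @param grid optional [volume_grid()] when `mask` is a bare array.
#' @return non-negative scalar, lesion volume in mm^3.
#' @export
#' @examples
#' g <- volume_grid(c(4, 4, 4), c(2, 2, 2))
#' a <- array(0L, c(4, 4, 4)); a[1:10] <- 1L
#' lesion_volume(a, g) # 10 voxels x 8 mm^3 = 80
lesion_volume <- function(mask, grid = NULL) {
  if (inherits(mask, "lesion_mask")) {
    v <- mask$voxels
    grid <- mask$grid
  } else {
    if (is.null(grid)) stop("`grid` required when `mask` is a bare array")
    v <- as_binary_array(mask, grid, "lesion mask")
  }
  sum(v) * voxel_volume(grid)
}

#' Downsample a binary mask to a coarser grid
#'
#' Aggregates each block of source voxels into one target voxel, e.g. from a
#' 1 mm to a 2 mm isotropic template grid. A target voxel is lesioned iff the
#' occupied fraction of its source block reaches `min_fraction` (default 0.5,
#' ties lesioned): the majority rule is volume-preserving in expectation.
#'
#' @param mask a [lesion_mask()].
#' @param factor integer (scalar or length 3) downsampling factor per axis;
#'   the target voxel size is `factor` times the source voxel size. The source
#'   shape need not be an exact multiple: trailing partial blocks are judged
#'   by the occupied fraction of a full block.
#' @param min_fraction occupied fraction at or above which the target voxel is
#'   lesioned; in (0, 1].
#' @return a [lesion_mask()] on the coarser grid.
#' @export
downsample_mask <- function(mask, factor = 2L, min_fraction = 0.5) {
  stopifnot(inherits(mask, "lesion_mask"))
  f <- as.integer(round(factor))
  if (length(f) == 1L) f <- rep(f, 3L)
  if (length(f) != 3L || anyNA(f) || any(f < 1L))
    stop("`factor` must be positive integers")
  fac <- as.numeric(factor)
  if (length(fac) == 1L) fac <- rep(fac, 3L)
  if (any(abs(fac - f) > 1e-8))
    stop("`factor` must be an integer ratio of target to source voxel size")
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("`min_fraction` must be in (0, 1]")
  src <- mask$grid
  out_shape <- as.integer(ceiling(src$shape / f))
  tgt <- volume_grid(out_shape, src$voxel_size_mm * f, src$orientation)
  block <- prod(f)
  # block index of every source voxel along each axis
  ix <- (seq_len(src$shape[1]) - 1L) %/% f[1]
  iy <- (seq_len(src$shape[2]) - 1L) %/% f[2]
  iz <- (seq_len(src$shape[3]) - 1L) %/% f[3]
  bi <- ix[slice.index(mask$voxels, 1)] +
    out_shape[1] * (iy[slice.index(mask$voxels, 2)] +
                      out_shape[2] * iz[slice.index(mask$voxels, 3)])
  counts <- numeric(prod(out_shape))
  tab <- tapply(as.numeric(mask$voxels), bi, sum)
  counts[as.integer(names(tab)) + 1L] <- tab
  out <- array(counts / block >= min_fraction, dim = out_shape)
  lesion_mask(out, tgt, subject_id = mask$subject_id, group = mask$group,
              side = mask$side)
}

#' Flip a left-hemisphere lesion to the right hemisphere
#'
#' Mirrors the mask about the grid's central plane on the left-right axis when
#' `side == "left"`, and is the identity for right-sided masks. For an odd
#' axis length the central slice is its own mirror image. Flipping twice
#' restores the original mask, and the lesion volume is preserved exactly.
#'
#' @param mask a [lesion_mask()] whose grid identifies the left-right axis.
#' @return a [lesion_mask()] with `side = "right"`.
#' @export
flip_to_right <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (mask$side == "right") return(mask)
  if (mask$side == "bilateral")
    stop("cannot flip a bilateral mask: hemisphere is ambiguous")
  ax <- lr_axis(mask$grid)
  if (length(ax) != 1L)
    stop("grid orientation does not identify a unique left-right axis")
  idx <- rep(list(quote(expr = )), 3L)
  idx[[ax]] <- rev(seq_len(mask$grid$shape[ax]))
  v <- do.call(`[`, c(list(mask$voxels), idx, list(drop = FALSE)))
  lesion_mask(v, mask$grid, subject_id = mask$subject_id, group = mask$group,
              side = "right")
}
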