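#' Voxelwise frequency (overlap) map of binary volumes
#'
#' Sums binary masks voxel by voxel: the value at a voxel is the number of
#' subjects whose mask covers it. Used both for lesion overlap maps and, on
#' thresholded disconnectome maps, for disconnection overlap maps.
#'
#' @param masks list of [lesion_mask()] objects and/or binary 3-D arrays, all
#'   on the same grid.
#' @param grid the common [volume_grid()]; may be omitted when at least one
#'   element of `masks` is a `lesion_mask`.
#' @return an object of class `frequency_map` with fields `grid`, `counts`
#'   (integer array) and `n_subjects`.
#' @export
frequency_map <- function(masks, grid = NULL) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("`masks` must be a non-empty list")
  if (is.null(grid)) {
    for (m in masks) if (inherits(m, "lesion_mask")) { grid <- m$grid; break }
    if (is.null(grid)) stop("`grid` required when no mask carries one")
  }
  counts <- array(0L, dim = grid$shape)
  for (m in masks) {
    v <- as_binary_array(m, grid, "mask")
    counts <- counts + v
  }
  structure(list(grid = grid, counts = counts, n_subjects = length(masks)),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> %d subjects, max overlap %d, %s grid\n",
              x$n_subjects, max(x$counts),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Group consensus map at a fractional overlap threshold
#'
#' Voxels covered by at least a given fraction of the group, e.g. the 75%
#' consensus map of a disconnection frequency map marks locations where 75%
#' of the patients show the same disconnection. The integer inclusion
#' threshold is `ceiling(fraction * n_subjects)` under the default (strictest)
#' rule, or `floor(...)` when `rule = "floor"`.
#'
#' @param freq a [frequency_map()].
#' @param fraction required fraction of subjects, in (0, 1].
#' @param rule how the fractional threshold is turned into a subject count.
#' @return logical 3-D array.
#' @export
#' @examples
#' # with 28 subjects, 75% consensus requires ceiling(0.75 * 28) = 21
consensus_map <- function(freq, fraction = 0.75, rule = c("ceiling", "floor")) {
  stopifnot(inherits(freq, "frequency_map"))
  rule <- match.arg(rule)
  if (!(fraction > 0 && fraction <= 1))
    stop("`fraction` must be in (0, 1]")
  k <- if (rule == "ceiling") ceiling(fraction * freq$n_subjects - 1e-9)
       else floor(fraction * freq$n_subjects + 1e-9)
  k <- max(1L, as.integer(k))
  freq$counts >= k
}
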