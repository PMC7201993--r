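# Per-subject disconnectome probability maps from a normative streamline
# panel: the lesion is registered to each control's native space, the
# streamlines passing through it are selected, their visitation map is
# binarized and carried back to template space, and the per-control maps are
# averaged into a probability of disconnection in [0, 1].

# Resample a binary template-space volume into native space (or back):
# for each output voxel, map its center through `mat` and take the nearest
# source voxel (floor of the continuous coordinate). Pull-based, so the
# result has no holes and is monotone in the input.
resample_binary <- function(vol, mat, shape) {
  out_idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 0.5,
                                   y = seq_len(shape[2]) - 0.5,
                                   z = seq_len(shape[3]) - 0.5))
  src <- floor(apply_affine(mat, out_idx)) + 1L
  ok <- src[, 1] >= 1 & src[, 2] >= 1 & src[, 3] >= 1 &
    src[, 1] <= dim(vol)[1] & src[, 2] <= dim(vol)[2] & src[, 3] <= dim(vol)[3]
  vals <- logical(nrow(src))
  vals[ok] <- vol[src[ok, , drop = FALSE]]
  array(vals, dim = shape)
}

#' Select the streamlines of one control that pass through a lesion
#'
#' The template-space lesion is registered to the control's native space via
#' the control's affine, and a streamline is selected iff any of its segments
#' passes through a lesioned native-space voxel (digital-line segment-voxel
#' traversal).
#'
#' @param lesion a [lesion_mask()] on the panel's template grid.
#' @param control one element of `panel$controls`.
#' @param grid the panel's [volume_grid()].
#' @return logical vector, one entry per streamline of the control.
#' @export
select_streamlines <- function(lesion, control, grid) {
  stopifnot(inherits(lesion, "lesion_mask"))
  check_same_grid(lesion$grid, grid, "lesion and panel")
  validate_control(control)
  native_lesion <- resample_binary(lesion$voxels, solve(control$transform),
                                   grid$shape)
  .sl_select_cpp(control$streamlines, as.vector(native_lesion),
                 as.integer(grid$shape))
}

#' Binary visitation map of a streamline set, in template space
#'
#' Marks every native-space voxel traversed by any streamline, then carries
#' the binary map back to the template grid through the inverse of the
#' control's transform (nearest-voxel assignment).
#'
#' @param streamlines list of n-by-3 matrices in native voxel coordinates.
#' @param transform the control's 4x4 template->native affine.
#' @param grid the template [volume_grid()].
#' @param control_id identifier carried on the result.
#' @return object of class `visitation_map`: fields `grid`, `visited`
#'   (logical array on the template grid), `control_id`.
#' @export
visitation_map <- function(streamlines, transform, grid,
                           control_id = "control") {
  stopifnot(inherits(grid, "volume_grid"))
  if (abs(det(transform)) < 1e-12) stop("singular transform")
  native <- array(.sl_visit_cpp(streamlines, as.integer(grid$shape)),
                  dim = grid$shape)
  visited <- resample_binary(native, transform, grid$shape)
  structure(list(grid = grid, visited = visited, control_id = control_id),
            class = "visitation_map")
}

#' Disconnectome probability map of one lesion
#'
#' For each control of the panel, selects the streamlines passing through the
#' lesion, builds their binarized template-space visitation map, and averages
#' the maps over controls: the value at a voxel is the fraction of controls
#' in whom a streamline passing through the lesion traverses that voxel —
#' interpreted as the probability of disconnection, in \[0, 1\].
#'
#' With `weighted = TRUE` the per-control contribution is instead the
#' streamline-count visitation map normalized by its maximum (a graded
#' alternative to binarization); the default follows the binarized
#' convention.
#'
#' @param lesion a [lesion_mask()] on the panel's template grid.
#' @param panel a [make_panel()] result (non-empty).
#' @param weighted logical; see Details.
#' @return object of class `disconnectome_map`: fields `grid`, `probability`
#'   (array in \[0,1\]), `subject_id`, `n_controls`.
#' @export
disconnectome_map <- function(lesion, panel, weighted = FALSE) {
  stopifnot(inherits(panel, "tractogram_panel"))
  if (length(panel$controls) < 1L) stop("panel is empty")
  grid <- panel$grid
  acc <- array(0, dim = grid$shape)
  for (ct in panel$controls) {
    sel <- select_streamlines(lesion, ct, grid)
    if (!any(sel)) next
    if (!weighted) {
      vm <- visitation_map(ct$streamlines[sel], ct$transform, grid,
                           ct$control_id)
      acc <- acc + vm$visited
    } else {
      counts <- array(0, dim = grid$shape)
      for (s in which(sel)) {
        v <- array(.sl_visit_cpp(ct$streamlines[s], as.integer(grid$shape)),
                   dim = grid$shape)
        counts <- counts + v
      }
      tmpl <- resample_numeric(counts, ct$transform, grid$shape)
      if (max(tmpl) > 0) acc <- acc + tmpl / max(tmpl)
    }
  }
  structure(
    list(grid = grid, probability = acc / length(panel$controls),
         subject_id = lesion$subject_id, n_controls = length(panel$controls)),
    class = "disconnectome_map")
}

resample_numeric <- function(vol, mat, shape) {
  out_idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 0.5,
                                   y = seq_len(shape[2]) - 0.5,
                                   z = seq_len(shape[3]) - 0.5))
  src <- floor(apply_affine(mat, out_idx)) + 1L
  ok <- src[, 1] >= 1 & src[, 2] >= 1 & src[, 3] >= 1 &
    src[, 1] <= dim(vol)[1] & src[, 2] <= dim(vol)[2] & src[, 3] <= dim(vol)[3]
  vals <- numeric(nrow(src))
  vals[ok] <- vol[src[ok, , drop = FALSE]]
  array(vals, dim = shape)
}

#' @export
print.disconnectome_map <- function(x, ...) {
  cat(sprintf(
    "<disconnectome_map> %s: %d controls, %d voxels with p > 0 (max %.2f)\n",
    x$subject_id, x$n_controls, sum(x$probability > 0), max(x$probability)))
  invisible(x)
}

#' Threshold a disconnectome map into a binary disconnection mask
#'
#' A voxel is retained iff its probability of disconnection is strictly above
#' the cutoff (default 0.5: a tract is considered involved when its
#' probability exceeds 50%). Set `strict = FALSE` for an inclusive `>=`
#' comparison; `cutoff = 0` retains every voxel with nonzero probability.
#'
#' @param map a [disconnectome_map()].
#' @param cutoff probability cutoff in \[0, 1).
#' @param strict logical, strict (`>`) vs inclusive (`>=`) comparison.
#' @return logical 3-D array.
#' @export
threshold_disconnectome <- function(map, cutoff = 0.5, strict = TRUE) {
  stopifnot(inherits(map, "disconnectome_map"))
  if (!(cutoff >= 0 && cutoff < 1))
    stop("`cutoff` must be in [0, 1)")
  if (strict) map$probability > cutoff else map$probability >= cutoff
}
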