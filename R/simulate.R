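# Synthetic lesion cohorts, with controllable size/location distributions and
# an optional planted disconnection effect. One global seed hierarchically
# derives per-subject seeds, so subsetting a cohort does not reshuffle others.

# Derive a child seed from a parent seed and stream indices; stays < 2^31.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 48271 + i * 7919 + j * 104729 + 1) %%
               2147483629)
}

#' Specify a synthetic two-group lesion cohort
#'
#' Defines the conditions a simulated cohort is drawn under: group sizes, the
#' grid, per-group lesion size distributions (voxel counts) and per-group
#' focus regions from which lesions grow. Defaults emulate a case/control
#' stroke-lesion study: unequal group sizes (28 vs 35), a control group with
#' substantially larger and more variable lesions, all case lesions in the
#' right hemisphere while roughly half of the control lesions start on the
#' left (and are flipped to the right before analysis).
#'
#' @param n_per_group integer pair, subjects per group (each >= 2).
#' @param grid a [volume_grid()].
#' @param size_mean,size_sd numeric pairs: mean and sd of the lesion voxel
#'   count per group.
#' @param focus per-group list of `list(center=, spread=)` in voxel
#'   coordinates; lesion seed points are drawn around `center` with sd
#'   `spread`. Default: deep right-hemisphere foci, slightly more dorsal for
#'   group 1.
#' @param groups character pair of group labels.
#' @param prop_left numeric pair, probability a subject's lesion is placed in
#'   the left hemisphere (mirrored focus) and labelled `side = "left"`.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(28L, 35L),
                        grid = volume_grid(c(24, 24, 24), c(2, 2, 2)),
                        size_mean = c(110, 300), size_sd = c(60, 180),
                        focus = NULL, groups = c("AHP", "HP"),
                        prop_left = c(0, 16 / 35), seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 2L))
    stop("`n_per_group` must be two integers >= 2")
  stopifnot(inherits(grid, "volume_grid"))
  if (any(size_mean <= 0) || any(size_sd < 0))
    stop("size distributions must be positive")
  if (is.null(focus)) {
    s <- grid$shape
    focus <- list(
      list(center = c(0.68, 0.55, 0.62) * s, spread = 0.10 * s),
      list(center = c(0.66, 0.50, 0.45) * s, spread = 0.08 * s)
    )
  }
  structure(
    list(n_per_group = n_per_group, grid = grid,
         size_mean = as.numeric(size_mean), size_sd = as.numeric(size_sd),
         focus = focus, groups = as.character(groups),
         prop_left = as.numeric(prop_left), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Grow a connected blob of `size` voxels by random boundary accretion
# (random-walk dilation) from a start voxel. 6-connected by construction.
grow_blob <- function(shape, start, size) {
  if (size > prod(shape))
    stop("requested lesion of ", size, " voxels exceeds the grid (",
         prod(shape), " voxels)")
  vox <- array(FALSE, dim = shape)
  start <- pmin(pmax(as.integer(round(start)), 1L), shape)
  vox[start[1], start[2], start[3]] <- TRUE
  frontier <- neighbors6(matrix(start, 1L), shape)
  n_now <- 1L
  while (n_now < size) {
    keep <- !vox[frontier]
    frontier <- frontier[keep, , drop = FALSE]
    if (nrow(frontier) == 0L) stop("blob growth ran out of room")
    pick <- sample.int(nrow(frontier), 1L)
    v <- frontier[pick, ]
    frontier <- frontier[-pick, , drop = FALSE]
    vox[v[1], v[2], v[3]] <- TRUE
    n_now <- n_now + 1L
    frontier <- rbind(frontier, neighbors6(matrix(v, 1L), shape))
  }
  vox
}

neighbors6 <- function(ijk, shape) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  out <- ijk[rep(seq_len(nrow(ijk)), each = 6L), , drop = FALSE] +
    offs[rep(seq_len(6L), nrow(ijk)), ]
  ok <- out[, 1] >= 1 & out[, 2] >= 1 & out[, 3] >= 1 &
    out[, 1] <= shape[1] & out[, 2] <= shape[2] & out[, 3] <= shape[3]
  out[ok, , drop = FALSE]
}

#' Generate a synthetic lesion cohort
#'
#' Draws per-subject lesion sizes from the per-group normal distributions
#' (rounded, floored at 1 voxel) and grows each lesion as a connected blob by
#' random boundary accretion from a seed point near the group's focus region.
#' Left-sided subjects get the focus mirrored across the left-right midline.
#' Bit-reproducible under a fixed seed; each subject has its own derived seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of [lesion_mask()] objects (group 1 subjects first).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  shape <- spec$grid$shape
  ax <- lr_axis(spec$grid)
  masks <- list()
  idx <- 0L
  for (g in 1:2) {
    for (i in seq_len(spec$n_per_group[g])) {
      idx <- idx + 1L
      sd_sub <- derive_seed(spec$seed, idx)
      set.seed(sd_sub)
      size <- max(1L, as.integer(round(rnorm(1, spec$size_mean[g],
                                             spec$size_sd[g]))))
      left <- runif(1) < spec$prop_left[g]
      center <- rnorm(3, spec$focus[[g]]$center, spec$focus[[g]]$spread)
      if (left) center[ax] <- shape[ax] + 1 - center[ax]
      vox <- grow_blob(shape, center, size)
      masks[[idx]] <- lesion_mask(
        vox, spec$grid,
        subject_id = sprintf("%s_%02d", spec$groups[g], i),
        group = spec$groups[g], side = if (left) "left" else "right")
    }
  }
  masks
}

#' Plant a group-specific disconnection effect
#'
#' Translates each lesion of the target group, with probability `strength`,
#' so that it covers a voxel on the template-space course of one bundle of
#' the normative panel. This creates a true group difference in disconnection
#' of that bundle, usable for parameter-recovery checks; with `strength = 0`
#' the cohort is returned unchanged.
#'
#' @param cohort list of [lesion_mask()] from [make_cohort()].
#' @param panel a [tractogram_panel()] from [make_panel()].
#' @param target_bundle bundle index (or name) within the panel.
#' @param strength probability in \[0, 1\] that a target-group lesion is
#'   moved onto the bundle.
#' @param group group label whose lesions receive the effect; default the
#'   first group present in the cohort.
#' @param seed integer seed.
#' @return the modified cohort (same order, same subjects).
#' @export
plant_effect <- function(cohort, panel, target_bundle = 1L, strength = 1,
                         group = NULL, seed = 1L) {
  stopifnot(inherits(panel, "tractogram_panel"))
  if (!(strength >= 0 && strength <= 1))
    stop("`strength` must be in [0, 1]")
  if (is.character(target_bundle))
    target_bundle <- match(target_bundle, vapply(panel$bundles, `[[`, "",
                                                 "name"))
  if (is.na(target_bundle) || target_bundle < 1L ||
      target_bundle > length(panel$bundles))
    stop("`target_bundle` not present in the panel")
  if (strength == 0) return(cohort)
  if (is.null(group)) group <- cohort[[1]]$group
  shape <- panel$grid$shape
  course <- bundle_course(panel, target_bundle)
  cv <- which(course, arr.ind = TRUE)
  if (nrow(cv) == 0L) stop("target bundle has an empty template course")
  for (i in seq_along(cohort)) {
    m <- cohort[[i]]
    if (!identical(m$group, group)) next
    set.seed(derive_seed(seed, i, 17L))
    if (runif(1) >= strength) next
    les <- which(m$voxels, arr.ind = TRUE)
    ctr <- colMeans(les)
    # lesioned voxel nearest the centroid: guaranteed to be in the mask
    anchor <- les[which.min(rowSums((les - rep(ctr, each = nrow(les)))^2)), ]
    ok <- FALSE
    for (try in 1:50) {
      target <- cv[sample.int(nrow(cv), 1L), ]
      shift <- target - anchor
      mins <- apply(les, 2, min) + shift
      maxs <- apply(les, 2, max) + shift
      shift <- shift + pmax(0L, 1L - mins) - pmax(0L, maxs - shape)
      moved <- les + rep(shift, each = nrow(les))
      vox <- array(FALSE, dim = shape)
      vox[moved] <- TRUE
      if (any(vox & course)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place lesion of subject ", m$subject_id,
           " onto the target bundle (lesion too large for the grid?)")
    cohort[[i]] <- lesion_mask(vox, m$grid, subject_id = m$subject_id,
                               group = m$group, side = m$side)
  }
  cohort
}

#' Template-space visitation course of one bundle
#'
#' Union of the voxels traversed by the bundle's template streamlines.
#'
#' @inheritParams plant_effect
#' @return logical 3-D array on the panel grid.
#' @export
bundle_course <- function(panel, target_bundle = 1L) {
  stopifnot(inherits(panel, "tractogram_panel"))
  sel <- which(panel$bundle_of == target_bundle)
  vis <- .sl_visit_cpp(panel$template_streamlines[sel],
                       as.integer(panel$grid$shape))
  array(vis, dim = panel$grid$shape)
}
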