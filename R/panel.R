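# Normative tractogram panels: per-control streamline sets with per-control
# template<->native affine transforms, standing in for tractography from a
# panel of healthy controls.

# Apply a 4x4 affine to an n-by-3 matrix of points.
apply_affine <- function(mat, pts) {
  stopifnot(is.matrix(mat), all(dim(mat) == c(4L, 4L)))
  h <- cbind(pts, 1) %*% t(mat)
  h[, 1:3, drop = FALSE]
}

# Small random affine: rotation (<= max_deg, random axis) about the grid
# center plus a translation (<= max_tr voxels per axis). Template -> native.
random_small_affine <- function(shape, max_deg, max_tr) {
  ang <- runif(1, -max_deg, max_deg) * pi / 180
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  tr <- runif(3, -max_tr, max_tr)
  ctr <- shape / 2
  mat <- diag(4)
  mat[1:3, 1:3] <- R
  mat[1:3, 4] <- ctr - R %*% ctr + tr
  mat
}

# Sample a point uniformly in a ball.
runif_ball <- function(center, radius) {
  repeat {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) return(center + radius * p)
  }
}

# Resample a polyline to (approximately) fixed arc-length step.
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums(diff(pts)^2))
  len <- sum(seg)
  if (len == 0) return(pts[c(1, nrow(pts)), , drop = FALSE])
  n_out <- max(2L, as.integer(ceiling(len / step)) + 1L)
  s_at <- c(0, cumsum(seg))
  s_new <- seq(0, len, length.out = n_out)
  out <- matrix(0, n_out, 3L)
  for (c in 1:3) out[, c] <- approx(s_at, pts[, c], xout = s_new)$y
  out
}

default_bundles <- function(shape) {
  frac <- function(f) f * shape
  r <- max(1.5, 0.09 * min(shape))
  list(
    list(name = "arcuate_like", r1_center = frac(c(0.70, 0.72, 0.55)),
         r2_center = frac(c(0.70, 0.30, 0.62)), radius = r),
    list(name = "corticospinal_like", r1_center = frac(c(0.62, 0.52, 0.82)),
         r2_center = frac(c(0.55, 0.48, 0.15)), radius = r),
    list(name = "transcallosal_like", r1_center = frac(c(0.26, 0.60, 0.66)),
         r2_center = frac(c(0.74, 0.60, 0.66)), radius = r)
  )
}

#' Generate a normative tractogram panel
#'
#' Builds smooth template bundles (polylines connecting designated region
#' pairs, resampled at a fixed step) and, for each control, a jittered copy
#' under a small random affine transform — a tractable stand-in for a panel
#' of healthy-control tractograms, whose inter-individual variability the
#' jitter and transforms emulate. Streamlines are stored in each control's
#' native space in continuous voxel coordinates; point jitter is tapered to
#' zero at the endpoints so every streamline keeps its endpoints inside its
#' bundle's seed regions after mapping back to template space.
#'
#' @param n_controls number of controls in the panel (>= 1).
#' @param n_streamlines streamlines per bundle.
#' @param grid a [volume_grid()].
#' @param jitter sd (voxels) of the smooth per-streamline displacement
#'   applied per control; 0 gives every control identical streamlines.
#' @param seed integer seed.
#' @param bundles list of bundle definitions `list(name, r1_center,
#'   r2_center, radius)` in voxel coordinates; default 3 bundles laid out as
#'   a fronto-temporal arch, a dorsal descending pathway and a transcallosal
#'   pathway.
#' @param step polyline resampling step in voxel edges.
#' @param max_rotation_deg,max_translation bounds of the per-control random
#'   affine (rotation in degrees, translation in voxels); 0 and 0 give
#'   identity transforms.
#' @return an object of class `tractogram_panel`.
#' @export
make_panel <- function(n_controls, n_streamlines = 25L, grid, jitter = 0.5,
                       seed = 1L, bundles = NULL, step = 1,
                       max_rotation_deg = 5, max_translation = 2) {
  stopifnot(inherits(grid, "volume_grid"))
  n_controls <- as.integer(n_controls)
  if (n_controls < 1L) stop("`n_controls` must be >= 1")
  if (n_streamlines < 1L) stop("`n_streamlines` must be >= 1")
  shape <- grid$shape
  if (is.null(bundles)) bundles <- default_bundles(shape)

  # template streamlines, shared by all controls
  set.seed(derive_seed(seed, 0L))
  templ <- list()
  bundle_of <- integer(0)
  for (b in seq_along(bundles)) {
    bd <- bundles[[b]]
    for (s in seq_len(n_streamlines)) {
      p0 <- runif_ball(bd$r1_center, bd$radius)
      p1 <- runif_ball(bd$r2_center, bd$radius)
      mid <- (p0 + p1) / 2
      perp <- rnorm(3)
      d <- p1 - p0
      perp <- perp - sum(perp * d) * d / sum(d^2)
      nperp <- sqrt(sum(perp^2))
      if (nperp > 0) perp <- perp / nperp
      bow <- runif(1, 0, 0.18 * sqrt(sum(d^2)))
      u <- seq(0, 1, length.out = 40L)
      bez <- outer((1 - u)^2, p0) + outer(2 * u * (1 - u), mid + bow * perp) +
        outer(u^2, p1)
      pts <- resample_polyline(bez, step)
      # keep template courses inside the grid
      for (c in 1:3) pts[, c] <- pmin(pmax(pts[, c], 0.01), shape[c] - 0.01)
      templ[[length(templ) + 1L]] <- pts
      bundle_of <- c(bundle_of, b)
    }
  }

  controls <- vector("list", n_controls)
  for (k in seq_len(n_controls)) {
    set.seed(derive_seed(seed, k, 1L))
    mat <- if (max_rotation_deg == 0 && max_translation == 0) diag(4) else
      random_small_affine(shape, max_rotation_deg, max_translation)
    sls <- vector("list", length(templ))
    for (s in seq_along(templ)) {
      pts <- templ[[s]]
      if (jitter > 0) {
        np <- nrow(pts)
        u <- seq(0, 1, length.out = np)
        a1 <- rnorm(3, 0, jitter)
        a2 <- rnorm(3, 0, jitter / 2)
        off <- outer(sin(pi * u), a1) + outer(sin(2 * pi * u), a2)
        pts <- pts + off
      }
      sls[[s]] <- apply_affine(mat, pts)
    }
    controls[[k]] <- list(control_id = sprintf("control_%03d", k),
                          transform = mat, streamlines = sls)
  }

  structure(
    list(grid = grid, bundles = bundles, bundle_of = bundle_of,
         template_streamlines = templ, controls = controls,
         jitter = jitter, seed = as.integer(seed)),
    class = "tractogram_panel"
  )
}

#' @export
print.tractogram_panel <- function(x, ...) {
  cat(sprintf(
    "<tractogram_panel> %d controls, %d streamlines each (%d bundles) on %s grid\n",
    length(x$controls), length(x$template_streamlines), length(x$bundles),
    paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

validate_control <- function(ctl) {
  if (abs(det(ctl$transform)) < 1e-12)
    stop("control ", ctl$control_id, " has a singular transform")
  if (any(vapply(ctl$streamlines, nrow, 0L) < 2L))
    stop("control ", ctl$control_id, " has a streamline with < 2 points")
  invisible(TRUE)
}
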