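# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (per-voxel loops, dense resampling, exhaustive
# enumeration) and never call the code paths they check.

random_mask <- function(shape, n_voxels, seed) {
  set.seed(seed)
  v <- array(FALSE, dim = shape)
  v[sample.int(prod(shape), n_voxels)] <- TRUE
  v
}

# Brute-force voxel count by explicit triple loop.
count_voxels_loop <- function(vox) {
  n <- 0L
  d <- dim(vox)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (vox[i, j, k]) n <- n + 1L
  n
}

# Brute-force block-counting downsampling oracle: explicit loop over target
# voxels, counting occupied source voxels in each block.
downsample_oracle <- function(vox, f, min_fraction = 0.5) {
  d <- dim(vox)
  od <- ceiling(d / f)
  out <- array(FALSE, od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (k in seq_len(od[3])) {
    xs <- ((i - 1) * f + 1):min(i * f, d[1])
    ys <- ((j - 1) * f + 1):min(j * f, d[2])
    zs <- ((k - 1) * f + 1):min(k * f, d[3])
    out[i, j, k] <- sum(vox[xs, ys, zs]) / f^3 >= min_fraction
  }
  out
}

# Brute-force segment-voxel intersection oracle: for every voxel cube in the
# segment's bounding box, clip the segment against the cube's three slabs
# (Liang-Barsky) and mark the voxel iff the chord inside it has positive
# length. Independent of the digital-line walk used by the implementation.
seg_visit_oracle <- function(a, b, vis) {
  shape <- dim(vis)
  lo <- pmax(floor(pmin(a, b)) - 1, 0)
  hi <- pmin(floor(pmax(a, b)) + 1, shape - 1)
  d <- b - a
  for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3]) {
    v <- c(x, y, z)
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (c in 1:3) {
      if (d[c] == 0) {
        if (a[c] < v[c] || a[c] > v[c] + 1) { ok <- FALSE; break }
      } else {
        tt <- sort(c((v[c] - a[c]) / d[c], (v[c] + 1 - a[c]) / d[c]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
        if (t0 >= t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 - t0 > 1e-12)
      vis[x + 1, y + 1, z + 1] <- TRUE
  }
  vis
}

dense_visit_oracle <- function(streamlines, shape, ...) {
  vis <- array(FALSE, dim = shape)
  for (pts in streamlines)
    for (i in seq_len(nrow(pts) - 1))
      vis <- seg_visit_oracle(pts[i, ], pts[i + 1, ], vis)
  vis
}

dense_select_oracle <- function(streamlines, mask, ...) {
  vapply(streamlines, function(pts) {
    any(dense_visit_oracle(list(pts), dim(mask)) & mask)
  }, logical(1))
}

# Brute-force TFCE oracle: enumerate connected components at every threshold
# step with igraph, accumulating in the same h order as the definition.
tfce_oracle <- function(stat, H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  d <- dim(stat)
  mx <- max(stat)
  out <- array(0, d)
  if (mx <= 0) return(out)
  if (is.null(dh)) dh <- mx / 100
  K <- floor(mx / dh + 1e-9)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  for (k in seq_len(K)) {
    h <- k * dh
    sel <- which(as.vector(stat) >= h)
    if (!length(sel)) next
    cc <- coords[sel, , drop = FALSE]
    # adjacency among supra-threshold voxels
    edges <- c()
    if (length(sel) > 1) {
      dx <- outer(cc[, 1], cc[, 1], `-`)
      dy <- outer(cc[, 2], cc[, 2], `-`)
      dz <- outer(cc[, 3], cc[, 3], `-`)
      ord <- abs(dx) + abs(dy) + abs(dz)
      adj <- abs(dx) <= 1 & abs(dy) <= 1 & abs(dz) <= 1 & ord > 0
      if (connectivity == 6) adj <- adj & ord == 1
      if (connectivity == 18) adj <- adj & ord <= 2
      ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
      edges <- as.vector(t(ij))
    }
    g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[sel] <- out[sel] + sizes^E * h^H * dh
  }
  out
}

# Classical pooled-variance two-sample t (group 1 minus group 2).
pooled_t_oracle <- function(y, g) {
  y1 <- y[g == 1]; y2 <- y[g == 0]
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
  (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Tiny deterministic panel + cohort used by several disconnectome tests.
small_panel <- function(n_controls = 10, grid = volume_grid(c(16, 16, 16),
                                                            c(2, 2, 2)),
                        jitter = 0.4, seed = 42) {
  make_panel(n_controls, n_streamlines = 6L, grid, jitter = jitter,
             seed = seed)
}
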