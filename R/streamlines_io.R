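# Streamline file I/O.
#
# Two dialects are supported and are interconvertible:
#  * TRK (TrackVis): the interoperable binary format; points are stored in
#    "voxmm" coordinates (continuous voxel coordinate times voxel size, voxel
#    (i,j,k) spanning [i,i+1) x ... so the voxel center is at (i+0.5)).
#  * a JSON dialect: one object per control,
#    {control_id, transform: 12 reals (row-major first three rows of the 4x4
#    template->native affine, in voxel units), streamlines: [[[x,y,z],...]]}
#    with streamline points in *template* millimetre coordinates (native
#    points mapped through the inverse transform, scaled by the voxel size).
# A panel file additionally carries the grid.

#' Write / read streamlines in TrackVis TRK format
#'
#' @param streamlines list of n-by-3 matrices of continuous voxel
#'   coordinates.
#' @param grid a [volume_grid()] supplying dimensions and voxel size.
#' @param path `.trk` file path.
#' @return `read_trk`: list with `streamlines` (voxel coordinates), `grid`.
#' @export
write_trk <- function(streamlines, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wchar("TRACK", 6L)
  writeBin(as.integer(grid$shape), con, size = 2L)          # dim[3]
  writeBin(as.numeric(grid$voxel_size_mm), con, size = 4L)  # voxel_size[3]
  writeBin(numeric(3L), con, size = 4L)                     # origin[3]
  writeBin(0L, con, size = 2L)                              # n_scalars
  writeBin(raw(200L), con)                                  # scalar_name
  writeBin(0L, con, size = 2L)                              # n_properties
  writeBin(raw(200L), con)                                  # property_name
  vox2ras <- diag(c(grid$voxel_size_mm, 1))
  writeBin(as.numeric(t(vox2ras)), con, size = 4L)          # vox_to_ras[4][4]
  writeBin(raw(444L), con)                                  # reserved
  wchar("RAS", 4L)                                          # voxel_order
  writeBin(raw(4L), con)                                    # pad2
  writeBin(numeric(6L), con, size = 4L)         # image_orientation_patient
  writeBin(raw(2L), con)                                    # pad1
  writeBin(raw(6L), con)                        # invert/swap flags
  writeBin(length(streamlines), con, size = 4L)             # n_count
  writeBin(2L, con, size = 4L)                              # version
  writeBin(1000L, con, size = 4L)                           # hdr_size
  for (pts in streamlines) {
    stopifnot(ncol(pts) == 3L)
    writeBin(nrow(pts), con, size = 4L)
    voxmm <- sweep(pts, 2L, grid$voxel_size_mm, `*`)
    writeBin(as.numeric(t(voxmm)), con, size = 4L)
  }
  invisible(path)
}

#' @rdname write_trk
#' @param orientation grid orientation to attach on read.
#' @export
read_trk <- function(path, orientation = c("R", "A", "S")) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (magic != "TRACK") stop("not a TRK file: ", path)
  dm <- readBin(con, "integer", 3L, size = 2L)
  vs <- readBin(con, "numeric", 3L, size = 4L)
  readBin(con, "numeric", 3L, size = 4L)   # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  readBin(con, "numeric", 16L, size = 4L)  # vox_to_ras
  readBin(con, "raw", 444L)
  readBin(con, "raw", 4L)                  # voxel_order
  readBin(con, "raw", 4L)
  readBin(con, "numeric", 6L, size = 4L)
  readBin(con, "raw", 2L)
  readBin(con, "raw", 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L)
  version <- readBin(con, "integer", 1L, size = 4L)
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (hdr_size != 1000L) stop("unsupported TRK header size: ", hdr_size)
  grid <- volume_grid(dm, vs, orientation)
  sls <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L)
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + n_scalars), size = 4L)
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L)
    sls[[length(sls) + 1L]] <- sweep(pts, 2L, vs, `/`)
    if (n_count > 0L && length(sls) >= n_count) break
  }
  list(streamlines = sls, grid = grid)
}

#' Write / read a tractogram panel
#'
#' `write_panel_json` stores the whole panel in one JSON file (grid, bundles,
#' and one object per control with its affine and its streamlines in template
#' millimetre coordinates). `write_panel_trk` writes one TRK file per control
#' (native-space streamlines) plus a `panel_meta.json` with the transforms;
#' reading either representation reconstructs an equivalent panel, so the two
#' functions double as a TRK/JSON converter.
#'
#' @param panel a [make_panel()] result.
#' @param path JSON file (`_json` variants) or directory (`_trk` variants).
#' @return the path, invisibly; readers return a `tractogram_panel`.
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "tractogram_panel"))
  vs <- panel$grid$voxel_size_mm
  ctl <- lapply(panel$controls, function(ct) {
    inv <- solve(ct$transform)
    sls <- lapply(ct$streamlines, function(pts) {
      tpl <- apply_affine(inv, pts)
      unname(sweep(tpl, 2L, vs, `*`))
    })
    list(control_id = ct$control_id,
         transform = as.vector(t(ct$transform[1:3, ])),
         streamlines = sls)
  })
  obj <- list(
    grid = list(shape = panel$grid$shape, voxel_size_mm = vs,
                orientation = panel$grid$orientation),
    bundle_of = panel$bundle_of,
    bundles = lapply(panel$bundles, function(b)
      list(name = b$name, r1_center = b$r1_center, r2_center = b$r2_center,
           radius = b$radius)),
    template_streamlines = lapply(panel$template_streamlines, unname),
    controls = ctl)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- volume_grid(obj$grid$shape, obj$grid$voxel_size_mm,
                      obj$grid$orientation)
  vs <- grid$voxel_size_mm
  tolist <- function(x) {
    if (is.list(x)) lapply(x, function(m) as.matrix(m)) else list(as.matrix(x))
  }
  templ <- tolist(obj$template_streamlines)
  controls <- lapply(seq_len(nrow_or_len(obj$controls)), function(i) {
    ct <- control_entry(obj$controls, i)
    mat <- rbind(matrix(unlist(ct$transform), 3L, 4L, byrow = TRUE),
                 c(0, 0, 0, 1))
    sls <- lapply(tolist(ct$streamlines), function(mm) {
      tpl <- sweep(mm, 2L, vs, `/`)
      apply_affine(mat, tpl)
    })
    list(control_id = ct$control_id, transform = mat, streamlines = sls)
  })
  bundles <- parse_bundles(obj$bundles)
  p <- structure(
    list(grid = grid, bundles = bundles,
         bundle_of = as.integer(obj$bundle_of),
         template_streamlines = templ, controls = controls,
         jitter = NA_real_, seed = NA_integer_),
    class = "tractogram_panel")
  lapply(p$controls, validate_control)
  p
}

# jsonlite may simplify the controls array to a data.frame; handle both.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
parse_bundles <- function(x) {
  if (is.data.frame(x))
    lapply(seq_len(nrow(x)), function(i)
      list(name = x$name[i], r1_center = as.numeric(x$r1_center[[i]]),
           r2_center = as.numeric(x$r2_center[[i]]),
           radius = as.numeric(x$radius[i])))
  else
    lapply(x, function(b)
      list(name = b$name, r1_center = as.numeric(b$r1_center),
           r2_center = as.numeric(b$r2_center),
           radius = as.numeric(b$radius)))
}
control_entry <- function(x, i) {
  if (is.data.frame(x))
    list(control_id = x$control_id[i], transform = x$transform[[i]],
         streamlines = x$streamlines[[i]])
  else x[[i]]
}

#' @rdname write_panel_json
#' @export
write_panel_trk <- function(panel, path) {
  stopifnot(inherits(panel, "tractogram_panel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ct in panel$controls)
    write_trk(ct$streamlines, panel$grid,
              file.path(path, paste0(ct$control_id, ".trk")))
  meta <- list(
    grid = list(shape = panel$grid$shape,
                voxel_size_mm = panel$grid$voxel_size_mm,
                orientation = panel$grid$orientation),
    bundle_of = panel$bundle_of,
    bundles = lapply(panel$bundles, function(b)
      list(name = b$name, r1_center = b$r1_center, r2_center = b$r2_center,
           radius = b$radius)),
    template_streamlines = lapply(panel$template_streamlines, unname),
    controls = lapply(panel$controls, function(ct)
      list(control_id = ct$control_id,
           transform = as.vector(t(ct$transform[1:3, ])))))
  jsonlite::write_json(meta, file.path(path, "panel_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_trk <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "panel_meta.json"),
                              simplifyVector = TRUE)
  grid <- volume_grid(meta$grid$shape, meta$grid$voxel_size_mm,
                      meta$grid$orientation)
  templ <- if (is.list(meta$template_streamlines))
    lapply(meta$template_streamlines, as.matrix)
  else list(as.matrix(meta$template_streamlines))
  controls <- lapply(seq_len(nrow_or_len(meta$controls)), function(i) {
    ct <- control_entry(meta$controls, i)
    mat <- rbind(matrix(unlist(ct$transform), 3L, 4L, byrow = TRUE),
                 c(0, 0, 0, 1))
    trk <- read_trk(file.path(path, paste0(ct$control_id, ".trk")),
                    grid$orientation)
    list(control_id = ct$control_id, transform = mat,
         streamlines = trk$streamlines)
  })
  bundles <- parse_bundles(meta$bundles)
  p <- structure(
    list(grid = grid, bundles = bundles,
         bundle_of = as.integer(meta$bundle_of),
         template_streamlines = templ, controls = controls,
         jitter = NA_real_, seed = NA_integer_),
    class = "tractogram_panel")
  lapply(p$controls, validate_control)
  p
}
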