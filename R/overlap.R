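# Atlas-overlap quantification of a binary disconnection-based map (the
# FWE-significant group-difference map) against tract, subcortical and
# cortical-parcel atlases, using two complementary percentages:
#   %disconnected tract    = |map & region| / |region| * 100
#   %disco/parcel overlap  = |map & region| / |map|    * 100

#' Percentage of a region covered by the disconnection map
#'
#' `100 * |map intersect region| / N_t`, where `N_t` is the voxel count of
#' the region: how much of the tract (or structure) is disconnected.
#'
#' @param disc_map binary 3-D array (or [lesion_mask()]), the
#'   disconnection-based map.
#' @param region binary 3-D array of the region, non-empty.
#' @return percentage in \[0, 100\].
#' @export
pct_disconnected_tract <- function(disc_map, region) {
  m <- as_binary_array(disc_map, what = "disconnection map")
  r <- as_binary_array(region, what = "region")
  if (!identical(dim(m), dim(r))) stop("map and region grids differ")
  nt <- sum(r)
  if (nt == 0L) stop("region is empty (division by zero)")
  100 * sum(m & r) / nt
}

#' Percentage of the disconnection map falling in a region
#'
#' `100 * |map intersect region| / N_d`, where `N_d` is the voxel count of
#' the whole disconnection-based map: the region's contribution to the
#' disconnection. Over an exhaustive disjoint parcellation covering the map
#' these percentages sum to 100.
#'
#' @inheritParams pct_disconnected_tract
#' @return percentage in \[0, 100\].
#' @export
pct_disco_parcel <- function(disc_map, region) {
  m <- as_binary_array(disc_map, what = "disconnection map")
  r <- as_binary_array(region, what = "region")
  if (!identical(dim(m), dim(r))) stop("map and region grids differ")
  nd <- sum(m)
  if (nd == 0L) stop("disconnection map is empty (division by zero)")
  100 * sum(m & r) / nd
}

#' Atlas-overlap report for a disconnection-based map
#'
#' Tabulates, for every region of every supplied atlas, the voxel counts and
#' both overlap percentages, flags tracts whose `%disconnected tract` is
#' strictly above `tract_display_min` (the display threshold used for tract
#' bar plots), and aggregates cortical parcels by functional network (union
#' of member parcel masks), retaining networks whose contribution
#' (`%disco/parcel overlap`) is strictly above `network_min`.
#'
#' @param disc_map binary 3-D array, typically [significant_map()] output.
#' @param atlases a [labeled_atlas()] or list of them (tract, subcortical
#'   and/or parcel atlases, all on the map's grid).
#' @param tract_display_min display threshold (%) for tract rows.
#' @param network_min retention threshold (%) for network rows.
#' @return object of class `overlap_report`: a list with `regions` (one row
#'   per atlas region: name, category, network, N_t, N_d, intersection,
#'   pct_disconnected_tract, pct_disco_parcel, display) and `networks`
#'   (aggregated network rows with a `retained` flag).
#' @export
overlap_report <- function(disc_map, atlases, tract_display_min = 10,
                           network_min = 2) {
  if (inherits(atlases, "labeled_atlas")) atlases <- list(atlases)
  m <- as_binary_array(disc_map, what = "disconnection map")
  nd <- sum(m)
  if (nd == 0L) stop("disconnection map is empty")
  rows <- list()
  net_rows <- list()
  for (atl in atlases) {
    stopifnot(inherits(atl, "labeled_atlas"))
    if (!identical(dim(m), as.integer(atl$grid$shape)))
      stop("atlas ", atl$name, " is not on the map's grid")
    lt <- atl$label_table
    for (i in seq_len(nrow(lt))) {
      r <- atl$labels == lt$label[i]
      nt <- sum(r)
      inter <- sum(m & r)
      rows[[length(rows) + 1L]] <- data.frame(
        atlas = atl$name, name = lt$name[i], category = lt$category[i],
        network = lt$network[i], N_t = nt, N_d = nd, intersection = inter,
        pct_disconnected_tract = if (nt > 0) 100 * inter / nt else NA_real_,
        pct_disco_parcel = 100 * inter / nd,
        stringsAsFactors = FALSE)
    }
    if (lt$category[1] == "parcel" && any(!is.na(lt$network))) {
      for (nw in unique(lt$network[!is.na(lt$network)])) {
        labs <- lt$label[lt$network == nw & !is.na(lt$network)]
        r <- array(atl$labels %in% labs, dim = dim(atl$labels))
        inter <- sum(m & r)
        net_rows[[length(net_rows) + 1L]] <- data.frame(
          atlas = atl$name, network = nw, N_t = sum(r), N_d = nd,
          intersection = inter,
          pct_disconnected_tract = if (sum(r) > 0) 100 * inter / sum(r)
                                   else NA_real_,
          pct_disco_parcel = 100 * inter / nd,
          stringsAsFactors = FALSE)
      }
    }
  }
  regions <- do.call(rbind, rows)
  regions$display <- regions$category == "tract" &
    !is.na(regions$pct_disconnected_tract) &
    regions$pct_disconnected_tract > tract_display_min
  networks <- if (length(net_rows)) do.call(rbind, net_rows) else
    data.frame(atlas = character(), network = character(), N_t = integer(),
               N_d = integer(), intersection = integer(),
               pct_disconnected_tract = numeric(),
               pct_disco_parcel = numeric())
  if (nrow(networks)) networks$retained <- networks$pct_disco_parcel > network_min
  structure(list(regions = regions, networks = networks,
                 tract_display_min = tract_display_min,
                 network_min = network_min, n_map_voxels = nd),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> map of %d voxels, %d regions, %d networks (%d retained > %g%%)\n",
              x$n_map_voxels, nrow(x$regions), nrow(x$networks),
              sum(x$networks$retained %||% logical()), x$network_min))
  top <- x$regions[x$regions$category == "tract", ]
  if (nrow(top)) {
    top <- top[order(-top$pct_disconnected_tract), ]
    cat("  top tracts by % disconnected:\n")
    for (i in seq_len(min(5L, nrow(top))))
      cat(sprintf("    %-24s %6.1f%%%s\n", top$name[i],
                  top$pct_disconnected_tract[i],
                  if (top$display[i]) " *" else ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an overlap report to TSV (and optionally JSON)
#'
#' @param report an [overlap_report()].
#' @param path output TSV path for the region table; the network table goes
#'   to `<path>` with suffix `_networks.tsv`.
#' @param json optional JSON path holding both tables.
#' @export
write_overlap_report <- function(report, path, json = NULL) {
  stopifnot(inherits(report, "overlap_report"))
  write.table(report$regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$networks,
              sub("\\.tsv$", "_networks.tsv", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(regions = report$regions,
                              networks = report$networks),
                         json, digits = NA, dataframe = "rows")
  invisible(path)
}
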