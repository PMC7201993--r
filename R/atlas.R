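#' Create a labeled atlas
#'
#' An integer-labelled volume (0 = background) with a label table describing
#' each region: its name, its category (white-matter `tract`, `subcortical`
#' structure, or cortical `parcel`) and, for cortical parcels, the functional
#' network the parcel belongs to.
#'
#' @param labels integer 3-D array on `grid` (0 = background).
#' @param grid a [volume_grid()].
#' @param label_table data.frame with columns `label` (integer), `name`,
#'   `category` (one of `"tract"`, `"subcortical"`, `"parcel"`) and optionally
#'   `network`. Every nonzero label present in `labels` must appear.
#' @param name short name of the atlas.
#' @return an object of class `labeled_atlas`.
#' @export
labeled_atlas <- function(labels, grid, label_table, name = "atlas") {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(labels) || length(dim(labels)) != 3L ||
      !identical(dim(labels), as.integer(grid$shape)))
    stop("`labels` must be a 3-D integer array matching the grid")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  lt <- as.data.frame(label_table, stringsAsFactors = FALSE)
  req <- c("label", "name", "category")
  if (!all(req %in% names(lt)))
    stop("label table needs columns: ", paste(req, collapse = ", "))
  if (!"network" %in% names(lt)) lt$network <- NA_character_
  lt$label <- as.integer(lt$label)
  bad_cat <- setdiff(unique(lt$category), c("tract", "subcortical", "parcel"))
  if (length(bad_cat))
    stop("unknown categories: ", paste(bad_cat, collapse = ", "))
  if (length(unique(lt$category)) > 1L)
    stop("one atlas instance must hold a single category")
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, lt$label)
  if (length(missing))
    stop("labels present in the volume but absent from the table: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(lt$label)) stop("duplicate labels in table")
  structure(list(grid = grid, labels = labels, label_table = lt, name = name),
            class = "labeled_atlas")
}

#' @export
print.labeled_atlas <- function(x, ...) {
  cat(sprintf("<labeled_atlas> %s: %d regions (%s) on %s grid\n", x$name,
              nrow(x$label_table), x$label_table$category[1],
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Binary mask of one atlas region
#' @param atlas a [labeled_atlas()].
#' @param label integer label or region name.
#' @return logical 3-D array.
#' @export
region_mask <- function(atlas, label) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  if (is.character(label)) {
    i <- match(label, atlas$label_table$name)
    if (is.na(i)) stop("unknown region name: ", label)
    label <- atlas$label_table$label[i]
  }
  atlas$labels == as.integer(label)
}

#' Read / write an atlas label table as TSV
#'
#' The table has columns `label`, `name`, `category`, `network`.
#'
#' @param path TSV file path.
#' @return `read_label_table`: a data.frame.
#' @export
read_label_table <- function(path) {
  lt <- read.delim(path, stringsAsFactors = FALSE)
  lt$label <- as.integer(lt$label)
  if (!"network" %in% names(lt)) lt$network <- NA_character_
  lt
}

#' @rdname read_label_table
#' @param label_table data.frame as in [labeled_atlas()].
#' @export
write_label_table <- function(label_table, path) {
  write.table(label_table[, c("label", "name", "category", "network")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
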