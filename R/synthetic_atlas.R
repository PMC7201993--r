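# Synthetic labeled atlases: a tract atlas derived from the panel's bundle
# courses, a subcortical atlas of eight canonical deep structures, and a
# cortical parcellation whose parcels are grouped into functional networks.
# These are labelled synthetic stand-ins with the same structure as the real
# atlases a user could supply (NIfTI + label TSV).

dilate6 <- function(vol) {
  out <- vol
  d <- dim(vol)
  out[-1, , ] <- out[-1, , ] | vol[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | vol[-1, , ]
  out[, -1, ] <- out[, -1, ] | vol[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | vol[, -1, ]
  out[, , -1] <- out[, , -1] | vol[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | vol[, , -1]
  out
}

ball_mask <- function(shape, center, radius) {
  i <- slice.index(array(0L, shape), 1) - center[1]
  j <- slice.index(array(0L, shape), 2) - center[2]
  k <- slice.index(array(0L, shape), 3) - center[3]
  i * i + j * j + k * k <= radius^2
}

#' Generate a synthetic atlas set matched to a panel
#'
#' Builds the three atlas categories the overlap analysis uses:
#' * a **tract** atlas: each bundle's template-space course (dilated by one
#'   voxel) becomes one labelled tract;
#' * a **subcortical** atlas: eight deep structures (thalamus, caudate,
#'   putamen, pallidum, brainstem, hippocampus, amygdala, accumbens) placed
#'   as small balls at fixed anatomically-inspired positions;
#' * a cortical **parcel** atlas: the outer shell of a brain-shaped ellipsoid
#'   partitioned into `n_parcels` parcels (k-means on voxel coordinates),
#'   each assigned to a functional network (default, ventral attention,
#'   cingulo-opercular, auditory, somatomotor, fronto-parietal).
#'
#' @param panel a [make_panel()] result; its bundles define the tracts.
#' @param n_parcels number of cortical parcels.
#' @param seed integer seed (parcel clustering).
#' @return named list of three [labeled_atlas()] objects:
#'   `tracts`, `subcortical`, `parcels`.
#' @export
make_atlas_set <- function(panel, n_parcels = 18L, seed = 1L) {
  stopifnot(inherits(panel, "tractogram_panel"))
  grid <- panel$grid
  shape <- grid$shape

  # tracts from bundle courses
  lab_t <- array(0L, shape)
  for (b in rev(seq_along(panel$bundles))) {
    course <- dilate6(bundle_course(panel, b))
    lab_t[course] <- b
  }
  tab_t <- data.frame(
    label = seq_along(panel$bundles),
    name = vapply(panel$bundles, `[[`, "", "name"),
    category = "tract", network = NA_character_,
    stringsAsFactors = FALSE)
  tracts <- labeled_atlas(lab_t, grid, tab_t, name = "synthetic_tracts")

  # subcortical structures
  sub_names <- c("thalamus", "caudate", "putamen", "pallidum", "brainstem",
                 "hippocampus", "amygdala", "accumbens")
  sub_pos <- rbind(
    c(0.55, 0.48, 0.50), c(0.58, 0.58, 0.55), c(0.66, 0.55, 0.48),
    c(0.62, 0.52, 0.46), c(0.50, 0.45, 0.20), c(0.64, 0.42, 0.38),
    c(0.64, 0.52, 0.34), c(0.58, 0.64, 0.40))
  r_sub <- max(1.2, 0.055 * min(shape))
  lab_s <- array(0L, shape)
  for (i in rev(seq_along(sub_names))) {
    lab_s[ball_mask(shape, sub_pos[i, ] * shape, r_sub)] <- i
  }
  tab_s <- data.frame(label = seq_along(sub_names), name = sub_names,
                      category = "subcortical", network = NA_character_,
                      stringsAsFactors = FALSE)
  subcortical <- labeled_atlas(lab_s, grid, tab_s,
                               name = "synthetic_subcortical")

  # cortical shell parcels grouped into networks
  ctr <- shape / 2
  semi <- 0.48 * shape
  i <- (slice.index(array(0L, shape), 1) - ctr[1]) / semi[1]
  j <- (slice.index(array(0L, shape), 2) - ctr[2]) / semi[2]
  k <- (slice.index(array(0L, shape), 3) - ctr[3]) / semi[3]
  r2 <- i * i + j * j + k * k
  shell <- r2 <= 1 & r2 >= 0.55
  coords <- which(shell, arr.ind = TRUE)
  n_parcels <- min(as.integer(n_parcels), nrow(coords))
  set.seed(derive_seed(seed, 3L))
  km <- kmeans(coords, centers = n_parcels, nstart = 3L, iter.max = 50L)
  lab_p <- array(0L, shape)
  lab_p[coords] <- km$cluster
  networks <- c("default", "ventral_attention", "cingulo_opercular",
                "auditory", "somatomotor", "fronto_parietal")
  tab_p <- data.frame(
    label = seq_len(n_parcels),
    name = sprintf("parcel_%02d", seq_len(n_parcels)),
    category = "parcel",
    network = networks[((seq_len(n_parcels) - 1L) %% length(networks)) + 1L],
    stringsAsFactors = FALSE)
  parcels <- labeled_atlas(lab_p, grid, tab_p, name = "synthetic_parcels")

  list(tracts = tracts, subcortical = subcortical, parcels = parcels)
}
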