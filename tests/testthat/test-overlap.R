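shape8 <- c(8, 8, 8)
grid8 <- volume_grid(shape8, c(2, 2, 2))

test_that("overlap percentages follow the two formulas", {
  map <- array(FALSE, shape8); map[1:4, , ] <- TRUE

  region_in <- array(FALSE, shape8); region_in[2:3, 2:3, 2:3] <- TRUE
  expect_equal(pct_disconnected_tract(map, region_in), 100)

  region_out <- array(FALSE, shape8); region_out[6:7, , ] <- TRUE
  expect_equal(pct_disconnected_tract(map, region_out), 0)
  expect_equal(pct_disco_parcel(map, region_out), 0)

  # N_t = 200, intersection = 50 -> 25%
  region <- array(FALSE, shape8)
  region[which(map)[1:50]] <- TRUE          # 50 voxels inside the map
  region[which(!map)[1:150]] <- TRUE        # 150 outside
  expect_equal(sum(region), 200)
  expect_equal(pct_disconnected_tract(map, region), 25)

  # N_d = 400, intersection = 8 -> 2%
  map2 <- array(FALSE, shape8); map2[seq_len(400)] <- TRUE
  region2 <- array(FALSE, shape8)
  region2[which(map2)[1:8]] <- TRUE
  expect_equal(pct_disco_parcel(map2, region2), 2)

  expect_error(pct_disconnected_tract(map, array(FALSE, shape8)), "empty")
  expect_error(pct_disco_parcel(array(FALSE, shape8), region), "empty")
})

test_that("parcel contributions sum to 100% over an exhaustive disjoint parcellation", {
  labels <- array(rep(1:8, each = 64), dim = shape8)  # 8 disjoint boxes
  for (seed in 1:10) {
    map <- random_mask(shape8, 70, seed + 300)
    pct <- vapply(1:8, function(l) pct_disco_parcel(map, labels == l), 0)
    expect_equal(sum(pct), 100, tolerance = 1e-9)
  }
})

test_that("percentages ignore background padding and match brute-force tallies", {
  map <- random_mask(shape8, 60, 5)
  region <- random_mask(shape8, 80, 6)
  inter <- 0L
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if (map[i, j, k] && region[i, j, k]) inter <- inter + 1L
  expect_equal(pct_disconnected_tract(map, region), 100 * inter / sum(region))
  expect_equal(pct_disco_parcel(map, region), 100 * inter / sum(map))

  # pad the grid with background: region percentages unchanged
  pad <- function(a) {
    out <- array(FALSE, dim(a) + 4L)
    out[3:(2 + dim(a)[1]), 3:(2 + dim(a)[2]), 3:(2 + dim(a)[3])] <- a
    out
  }
  expect_equal(pct_disconnected_tract(pad(map), pad(region)),
               pct_disconnected_tract(map, region))
  expect_equal(pct_disco_parcel(pad(map), pad(region)),
               pct_disco_parcel(map, region))
})

test_that("report thresholds are strict and network aggregation uses parcel unions", {
  # tract atlas: one tract at exactly 10% disconnected, one above
  lab_t <- array(0L, shape8)
  lab_t[1:8, 1, 1] <- 1L; lab_t[1:2, 2, 1] <- 1L   # tract 1: 10 voxels
  lab_t[1:8, 3, 1] <- 2L; lab_t[1:2, 4, 1] <- 2L   # tract 2: 10 voxels
  tab_t <- data.frame(label = 1:2, name = c("t10", "t30"),
                      category = "tract")
  tracts <- labeled_atlas(lab_t, grid8, tab_t)

  map <- array(FALSE, shape8)
  map[1:1, 1, 1] <- TRUE   # 1/10 of tract 1 = exactly 10%
  map[1:3, 3, 1] <- TRUE   # 3/10 of tract 2 = 30%
  rep_ <- overlap_report(map, tracts, tract_display_min = 10)
  expect_identical(rep_$regions$display,
                   c(FALSE, TRUE))  # exactly 10% is NOT displayed

  # parcels with networks; network percentages via union = sum over disjoint
  lab_p <- array(0L, shape8)
  lab_p[1:2, 5, 5] <- 1L; lab_p[3:4, 5, 5] <- 2L; lab_p[5:6, 5, 5] <- 3L
  tab_p <- data.frame(label = 1:3, name = paste0("p", 1:3),
                      category = "parcel",
                      network = c("net1", "net1", "net2"))
  parcels <- labeled_atlas(lab_p, grid8, tab_p)
  map2 <- array(FALSE, shape8)
  map2[1:6, 5, 5] <- TRUE
  map2[1:8, 1:5, 2] <- TRUE  # 40 voxels away from the parcels
  map2[1:4, 6, 2] <- TRUE    # 50 map voxels total
  r2 <- overlap_report(map2, parcels, network_min = 2)
  nets <- r2$networks
  expect_equal(nets$pct_disco_parcel[nets$network == "net1"],
               sum(r2$regions$pct_disco_parcel[tab_p$network == "net1"]))
  # net1: 4/50 = 8% retained; net2: 2/50 = 4% retained
  expect_true(all(nets$retained))
  r3 <- overlap_report(map2, parcels, network_min = 4)
  expect_identical(r3$networks$retained[r3$networks$network == "net2"],
                   FALSE)  # exactly 4% is not "above 4%"

  # single region covering everything
  all_lab <- array(1L, shape8)
  atlas_all <- labeled_atlas(all_lab, grid8,
                             data.frame(label = 1, name = "all",
                                        category = "tract"))
  r4 <- overlap_report(array(TRUE, shape8), atlas_all)
  expect_equal(r4$regions$pct_disconnected_tract, 100)
  expect_equal(r4$regions$pct_disco_parcel, 100)
})

test_that("overlap report rejects an atlas on a different grid", {
  small <- labeled_atlas(array(1L, c(4, 4, 4)), volume_grid(c(4, 4, 4)),
                         data.frame(label = 1, name = "x",
                                    category = "tract"))
  expect_error(overlap_report(random_mask(shape8, 10, 1), small),
               "grid")
})
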