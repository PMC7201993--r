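test_that("lesion volume is voxel count times voxel volume", {
  g1 <- volume_grid(c(8, 8, 8), c(1, 1, 1))
  g2 <- volume_grid(c(8, 8, 8), c(2, 2, 2))

  expect_equal(lesion_volume(array(0, c(8, 8, 8)), g1), 0)

  ten <- array(0L, c(8, 8, 8)); ten[1:10] <- 1L
  expect_equal(lesion_volume(ten, g2), 80)

  vox <- random_mask(c(8, 8, 8), 137, seed = 11)
  expect_equal(lesion_volume(vox, g1), 137)
  expect_equal(lesion_volume(vox, g1), count_voxels_loop(vox) * 1)

  m <- lesion_mask(vox, g2, "s1")
  expect_equal(m$volume_mm3, 137 * 8)
})

test_that("non-binary input is rejected with a diagnostic", {
  g <- volume_grid(c(4, 4, 4))
  bad <- array(0, c(4, 4, 4)); bad[1] <- 0.5
  expect_error(lesion_mask(bad, g), "not binary")
  expect_error(lesion_volume(bad, g), "not binary")
})

test_that("downsampling follows the majority rule with ties lesioned", {
  g <- volume_grid(c(8, 8, 8), c(1, 1, 1))
  a <- array(FALSE, c(8, 8, 8))
  a[1:2, 1:2, 1:2] <- TRUE            # full block -> lesioned
  a[3:4, 1:2, 1:2][1:3] <- TRUE       # 3/8 of a block -> not lesioned
  a[5:6, 1:2, 1:2][1:4] <- TRUE       # 4/8, tie -> lesioned
  m <- downsample_mask(lesion_mask(a, g), 2)
  expect_identical(dim(m$voxels), c(4L, 4L, 4L))
  expect_true(m$voxels[1, 1, 1])
  expect_false(m$voxels[2, 1, 1])
  expect_true(m$voxels[3, 1, 1])
  expect_equal(m$grid$voxel_size_mm, c(2, 2, 2))
})

test_that("downsampling matches the block-counting oracle and roughly preserves volume", {
  g <- volume_grid(c(12, 12, 12), c(1, 1, 1))
  for (seed in 1:5) {
    set.seed(seed)
    blob <- grow_blob(c(12, 12, 12), c(6, 6, 6), 150 + seed * 20)
    m <- downsample_mask(lesion_mask(blob, g), 2)
    expect_identical(m$voxels, downsample_oracle(blob, 2))
    v_src <- lesion_volume(blob, g)
    expect_lt(abs(m$volume_mm3 - v_src) / v_src, 0.5)
  }
})

test_that("non-integer downsampling ratio is rejected", {
  g <- volume_grid(c(8, 8, 8), c(1, 1, 1))
  m <- lesion_mask(random_mask(c(8, 8, 8), 20, 1), g)
  expect_error(downsample_mask(m, 1.5), "integer ratio")
})

test_that("hemisphere flipping mirrors about the LR midline and is an involution", {
  g <- volume_grid(c(9, 8, 8), c(2, 2, 2))  # odd LR axis length

  right <- lesion_mask(random_mask(c(9, 8, 8), 30, 2), g, side = "right")
  expect_identical(flip_to_right(right), right)

  a <- array(FALSE, c(9, 8, 8)); a[3, 5, 6] <- TRUE
  left <- lesion_mask(a, g, side = "left")
  fl <- flip_to_right(left)
  expect_equal(fl$side, "right")
  expect_true(fl$voxels[9 - 3 + 1, 5, 6])   # index i -> L - 1 - i (0-based)
  expect_equal(sum(fl$voxels), 1)
  expect_equal(fl$volume_mm3, left$volume_mm3)

  # involution on voxel content
  set.seed(3)
  b <- random_mask(c(9, 8, 8), 40, 4)
  lb <- lesion_mask(b, g, side = "left")
  twice <- flip_to_right(lesion_mask(flip_to_right(lb)$voxels, g,
                                     side = "left"))
  expect_identical(twice$voxels, b)

  # central slice of an odd axis is fixed
  ctr <- array(FALSE, c(9, 8, 8)); ctr[5, 2, 2] <- TRUE
  expect_identical(flip_to_right(lesion_mask(ctr, g, side = "left"))$voxels,
                   ctr)
})

test_that("flipping requires an unambiguous hemisphere", {
  g <- volume_grid(c(8, 8, 8))
  m <- lesion_mask(random_mask(c(8, 8, 8), 10, 5), g, side = "bilateral")
  expect_error(flip_to_right(m), "ambiguous")
  expect_error(volume_grid(c(8, 8, 8), orientation = c("A", "P", "S")),
               "left-right")
})

test_that("masks round-trip bit-exactly through NIfTI", {
  g <- volume_grid(c(10, 9, 8), c(2, 2, 2))
  m <- lesion_mask(random_mask(c(10, 9, 8), 55, 6), g, subject_id = "rt",
                   group = "AHP", side = "right")
  path <- file.path(tempdir(), "rt_mask.nii")
  write_mask_nifti(m, path)
  back <- read_mask_nifti(path, subject_id = "rt", group = "AHP")
  expect_identical(back$voxels, m$voxels)
  expect_equal(back$grid$voxel_size_mm, g$voxel_size_mm)
  expect_equal(back$volume_mm3, m$volume_mm3)

  # float maps round-trip too
  p <- array(runif(10 * 9 * 8), c(10, 9, 8))
  path2 <- file.path(tempdir(), "rt_prob.nii")
  write_volume_nifti(p, g, path2)
  expect_equal(read_volume_nifti(path2)$vol, p, tolerance = 1e-6)
})

test_that("label tables round-trip through TSV", {
  lt <- data.frame(label = 1:3, name = c("a", "b", "c"),
                   category = "tract", network = NA_character_)
  path <- file.path(tempdir(), "labels.tsv")
  write_label_table(lt, path)
  back <- read_label_table(path)
  expect_equal(back$label, lt$label)
  expect_equal(back$name, lt$name)
  expect_equal(back$category, lt$category)
})

test_that("labeled_atlas validates its label table", {
  g <- volume_grid(c(6, 6, 6))
  lab <- array(0L, c(6, 6, 6)); lab[1:4] <- 1L; lab[10:12] <- 2L
  tab <- data.frame(label = 1:2, name = c("r1", "r2"), category = "tract")
  a <- labeled_atlas(lab, g, tab)
  expect_s3_class(a, "labeled_atlas")
  expect_error(labeled_atlas(lab, g, tab[1, ]), "absent from the table")
  tab_bad <- data.frame(label = 1:2, name = c("r1", "r2"),
                        category = c("tract", "parcel"))
  expect_error(labeled_atlas(lab, g, tab_bad), "single category")
})
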