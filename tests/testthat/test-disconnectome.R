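grid16 <- volume_grid(c(16, 16, 16), c(2, 2, 2))

test_that("an empty lesion selects no streamlines", {
  p <- small_panel(3, grid16, jitter = 0.3, seed = 4)
  empty <- lesion_mask(array(FALSE, c(16, 16, 16)), grid16)
  sel <- select_streamlines(empty, p$controls[[1]], grid16)
  expect_false(any(sel))
})

test_that("a streamline through a lesioned voxel center is selected under identity", {
  vox <- array(FALSE, c(16, 16, 16)); vox[8, 8, 8] <- TRUE
  lesion <- lesion_mask(vox, grid16)
  # voxel [8,8,8] (1-based) spans [7,8)^3 in continuous coordinates
  through <- matrix(c(2.0, 7.5, 7.5, 13.0, 7.5, 7.5), 2, 3, byrow = TRUE)
  misses <- matrix(c(2.0, 2.5, 2.5, 13.0, 2.5, 2.5), 2, 3, byrow = TRUE)
  ctl <- list(control_id = "c", transform = diag(4),
              streamlines = list(through, misses))
  sel <- select_streamlines(lesion, ctl, grid16)
  expect_identical(as.vector(sel), c(TRUE, FALSE))
})

test_that("selection and visitation agree with the dense-resampling oracle", {
  p <- small_panel(4, grid16, jitter = 0.5, seed = 31)
  set.seed(77)
  vox <- grow_blob(c(16, 16, 16), c(10, 9, 9), 60)
  lesion <- lesion_mask(vox, grid16)
  for (ct in p$controls) {
    native <- disconnectr:::resample_binary(vox, solve(ct$transform),
                                            grid16$shape)
    sel <- select_streamlines(lesion, ct, grid16)
    oracle <- dense_select_oracle(ct$streamlines, native, step = 0.05)
    expect_identical(as.vector(sel), unname(oracle))

    vm <- visitation_map(ct$streamlines[sel], ct$transform, grid16,
                         ct$control_id)
    native_visit <- dense_visit_oracle(ct$streamlines[sel], grid16$shape,
                                       step = 0.05)
    tmpl_oracle <- disconnectr:::resample_binary(native_visit, ct$transform,
                                                 grid16$shape)
    expect_identical(vm$visited, tmpl_oracle)
  }
})

test_that("visitation of an axis-aligned streamline marks exactly the spanned voxels", {
  expect_identical(
    visitation_map(list(), diag(4), grid16)$visited,
    array(FALSE, c(16, 16, 16)))

  # from x=2.5 to x=8.5 at y=z=4.5: crosses voxels floor(2.5)..floor(8.5)
  sl <- matrix(c(2.5, 4.5, 4.5, 8.5, 4.5, 4.5), 2, 3, byrow = TRUE)
  vm <- visitation_map(list(sl), diag(4), grid16)
  expect_equal(sum(vm$visited), 7)
  expect_true(all(vm$visited[3:9, 5, 5]))
})

test_that("disconnectome probabilities are fractions of controls", {
  set.seed(5)
  vox <- grow_blob(c(16, 16, 16), c(11, 11, 10), 40)
  lesion <- lesion_mask(vox, grid16, subject_id = "s")

  # single control: binary map
  p1 <- small_panel(1, grid16, jitter = 0.3, seed = 9)
  d1 <- disconnectome_map(lesion, p1)
  expect_true(all(d1$probability %in% c(0, 1)))

  # four identical controls: equals the single-control map
  p4 <- p1
  p4$controls <- rep(p1$controls, 4)
  d4 <- disconnectome_map(lesion, p4)
  expect_equal(d4$probability, d1$probability)

  # 10-control jittered panel vs per-control loop oracle
  p10 <- small_panel(10, grid16, jitter = 0.5, seed = 10)
  d10 <- disconnectome_map(lesion, p10)
  acc <- array(0, c(16, 16, 16))
  for (ct in p10$controls) {
    sel <- select_streamlines(lesion, ct, grid16)
    acc <- acc + visitation_map(ct$streamlines[sel], ct$transform,
                                grid16)$visited
  }
  expect_equal(d10$probability, acc / 10)
  expect_true(all(d10$probability >= 0 & d10$probability <= 1))
  expect_true(all(abs(d10$probability * 10 - round(d10$probability * 10)) <
                    1e-9))
})

test_that("adding a control that misses the lesion rescales probabilities by n/(n+1)", {
  set.seed(6)
  vox <- grow_blob(c(16, 16, 16), c(11, 11, 10), 30)
  lesion <- lesion_mask(vox, grid16)
  p <- small_panel(5, grid16, jitter = 0.4, seed = 14)
  d5 <- disconnectome_map(lesion, p)
  # a control whose streamlines live far from any lesion: single tiny segment
  far <- matrix(c(0.2, 0.2, 0.2, 0.4, 0.4, 0.4), 2, 3, byrow = TRUE)
  p$controls <- c(p$controls, list(list(control_id = "miss",
                                        transform = diag(4),
                                        streamlines = list(far))))
  d6 <- disconnectome_map(lesion, p)
  expect_equal(d6$probability, d5$probability * 5 / 6)
})

test_that("enlarging the lesion never decreases any probability", {
  p <- small_panel(6, grid16, jitter = 0.4, seed = 15)
  set.seed(8)
  small <- grow_blob(c(16, 16, 16), c(10, 10, 10), 25)
  big <- small | grow_blob(c(16, 16, 16), c(9, 11, 9), 40)
  ds <- disconnectome_map(lesion_mask(small, grid16), p)
  db <- disconnectome_map(lesion_mask(big, grid16), p)
  expect_true(all(db$probability >= ds$probability))
})

test_that("thresholding is strict at the cutoff", {
  d <- structure(list(grid = grid16,
                      probability = array(0, c(16, 16, 16)),
                      subject_id = "s", n_controls = 10L),
                 class = "disconnectome_map")
  expect_false(any(threshold_disconnectome(d)))

  d$probability[1, 1, 1] <- 0.5
  d$probability[2, 1, 1] <- 0.6
  thr <- threshold_disconnectome(d, 0.5)
  expect_false(thr[1, 1, 1])   # exactly 0.5 excluded ("above 50%")
  expect_true(thr[2, 1, 1])
  expect_true(threshold_disconnectome(d, 0.5, strict = FALSE)[1, 1, 1])

  # random map: retained set equals a brute-force scan
  set.seed(9)
  d$probability <- array(sample(0:10, 16^3, replace = TRUE) / 10,
                         c(16, 16, 16))
  thr <- threshold_disconnectome(d, 0.5)
  oracle <- array(FALSE, c(16, 16, 16))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    oracle[i, j, k] <- d$probability[i, j, k] > 0.5
  expect_identical(thr, oracle)

  expect_error(threshold_disconnectome(d, 1), "cutoff")
  expect_error(threshold_disconnectome(d, -0.1), "cutoff")
})

test_that("a singular transform is rejected", {
  m <- diag(4); m[1, 1] <- 0
  expect_error(visitation_map(list(matrix(0, 2, 3)), m, grid16), "singular")
})
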