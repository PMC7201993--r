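test_that("zero-variance size specification yields exact lesion sizes", {
  g <- volume_grid(c(12, 12, 12), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(2, 2), grid = g,
                      size_mean = c(20, 20), size_sd = c(0, 0),
                      prop_left = c(0, 0), seed = 7)
  co <- make_cohort(spec)
  expect_length(co, 4)
  expect_true(all(vapply(co, function(m) sum(m$voxels), 0L) == 20L))
})

test_that("cohort generation is deterministic under a fixed seed", {
  g <- volume_grid(c(14, 14, 14), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(3, 3), grid = g,
                      size_mean = c(40, 80), size_sd = c(10, 20), seed = 99)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  for (i in seq_along(a)) expect_identical(a[[i]]$voxels, b[[i]]$voxels)
})

test_that("generated masks are binary, connected and follow the size distribution", {
  g <- volume_grid(c(20, 20, 20), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(30, 30), grid = g,
                      size_mean = c(100, 300), size_sd = c(10, 10),
                      prop_left = c(0, 0), seed = 5)
  co <- make_cohort(spec)
  sizes <- vapply(co, function(m) sum(m$voxels), 0L)
  grp <- vapply(co, `[[`, "", "group")
  for (m in co) {
    lab <- label_components(m$voxels, 6)
    expect_equal(max(lab), 1)  # connected
  }
  # empirical group means within 3 sd-of-the-mean of targets
  for (gi in 1:2) {
    mn <- mean(sizes[grp == spec$groups[gi]])
    expect_lt(abs(mn - spec$size_mean[gi]), 3 * 10 / sqrt(30))
  }
})

test_that("a lesion larger than the grid is rejected", {
  g <- volume_grid(c(6, 6, 6), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(2, 2), grid = g,
                      size_mean = c(500, 500), size_sd = c(0, 0), seed = 1)
  expect_error(make_cohort(spec), "exceeds the grid")
})

test_that("a degenerate panel carries identical streamlines for all controls", {
  g <- volume_grid(c(16, 16, 16), c(2, 2, 2))
  p <- make_panel(3, 5, g, jitter = 0, seed = 2, max_rotation_deg = 0,
                  max_translation = 0)
  for (k in 2:3)
    for (s in seq_along(p$controls[[1]]$streamlines))
      expect_identical(p$controls[[k]]$streamlines[[s]],
                       p$controls[[1]]$streamlines[[s]])
  expect_identical(p$controls[[1]]$transform, diag(4))
})

test_that("a 164-control panel can be generated on a small grid", {
  g <- volume_grid(c(20, 20, 20), c(2, 2, 2))
  p <- make_panel(164, 3, g, jitter = 0.3, seed = 6)
  expect_length(p$controls, 164)
})

test_that("streamline endpoints stay inside their bundle's regions in template space", {
  g <- volume_grid(c(20, 20, 20), c(2, 2, 2))
  p <- make_panel(5, 8, g, jitter = 0.6, seed = 12)
  for (ct in p$controls) {
    inv <- solve(ct$transform)
    for (s in seq_along(ct$streamlines)) {
      b <- p$bundles[[p$bundle_of[s]]]
      pts <- apply_affine(inv, ct$streamlines[[s]])
      p0 <- pts[1, ]; p1 <- pts[nrow(pts), ]
      expect_lte(sqrt(sum((p0 - b$r1_center)^2)), b$radius + 1e-6)
      expect_lte(sqrt(sum((p1 - b$r2_center)^2)), b$radius + 1e-6)
    }
  }
})

test_that("plant_effect with strength 0 returns the cohort unchanged", {
  g <- volume_grid(c(16, 16, 16), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(3, 3), grid = g,
                      size_mean = c(30, 30), size_sd = c(5, 5),
                      prop_left = c(0, 0), seed = 8)
  co <- make_cohort(spec)
  p <- small_panel(grid = g)
  expect_identical(plant_effect(co, p, 1, 0, seed = 3), co)
})

test_that("plant_effect with strength 1 forces intersection with the target bundle", {
  g <- volume_grid(c(16, 16, 16), c(2, 2, 2))
  spec <- cohort_spec(n_per_group = c(4, 3), grid = g,
                      size_mean = c(25, 25), size_sd = c(5, 5),
                      prop_left = c(0, 0), seed = 21)
  co <- make_cohort(spec)

  # jitter 0, identity transforms: every group-1 lesion must intersect a
  # target-bundle streamline of every control
  p0 <- make_panel(4, 6, g, jitter = 0, seed = 3, max_rotation_deg = 0,
                   max_translation = 0)
  co0 <- plant_effect(co, p0, 2, 1, seed = 5)
  for (m in co0) {
    if (m$group != "AHP") next
    for (ct in p0$controls) {
      sel <- select_streamlines(m, ct, g)
      expect_true(any(sel[p0$bundle_of == 2]))
    }
  }
  # group 2 untouched
  for (i in which(vapply(co, `[[`, "", "group") == "HP"))
    expect_identical(co0[[i]]$voxels, co[[i]]$voxels)

  # jittered panel: >= 80% of (lesion, control) pairs intersect, measured by
  # a brute-force dense-resampling intersection oracle
  pj <- make_panel(6, 6, g, jitter = 0.5, seed = 13)
  coj <- plant_effect(co, pj, 2, 1, seed = 5)
  hits <- 0; tot <- 0
  for (m in coj) {
    if (m$group != "AHP") next
    for (ct in pj$controls) {
      native <- disconnectr:::resample_binary(m$voxels, solve(ct$transform),
                                              g$shape)
      sel <- dense_select_oracle(ct$streamlines[pj$bundle_of == 2], native,
                                 step = 0.1)
      tot <- tot + 1
      if (any(sel)) hits <- hits + 1
    }
  }
  expect_gte(hits / tot, 0.8)
})
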