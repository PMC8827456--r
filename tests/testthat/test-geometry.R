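test_that("channel build reproduces the stated microfluidic dimensions", {
  dom <- build_channel(500, 250, 60, 125, 250, h = 2.5, tf_on = TRUE)
  expect_equal(dom$shape, c(200L, 100L, 24L))
  expect_true(all(dom$fluid_mask))
  # reactive floor faces span x in [125, 375) um, full width
  xs <- (seq_len(200) - 0.5) * 2.5
  on_floor <- apply(dom$reactive_mask, 1, any)
  expect_equal(which(on_floor), which(xs >= 125 & xs < 375))
  expect_true(all(dom$reactive_mask[, , 2:24] == FALSE))
  # film present and confined to 6 voxel layers above the patch (15 um / 2.5)
  expect_true(any(dom$film_mask))
  expect_true(all(which(apply(dom$film_mask, 3, any)) <= 6))
  expect_true(any(dom$film_mask[, , 1] & dom$reactive_mask[, , 1]))
})

test_that("empty patch and TF flag semantics", {
  dom <- build_channel(100, 50, 40, 0, 0, h = 5)
  expect_equal(sum(dom$reactive_mask), 0)
  dom2 <- build_channel(100, 50, 40, 25, 50, h = 5, tf_on = FALSE)
  expect_gt(sum(dom2$reactive_mask), 0)
  expect_equal(sum(dom2$film_mask), 0)
})

test_that("channel rejects invalid patches and spacings", {
  expect_error(build_channel(100, 50, 40, 80, 50, h = 5), "outside")
  expect_error(build_channel(100, 50, 40, -10, 20, h = 5), "outside")
  expect_error(build_channel(100, 50, 40, 0, 20, h = 60), "larger")
})

test_that("tube voxelization approximates the circular lumen", {
  dom <- build_tube(100, 60, 0.5, 50, h = 60 / 24)
  h <- dom$h_lkmc
  area <- sum(dom$fluid_mask[1, , ]) * h^2
  expect_lt(abs(area - pi * 30^2) / (pi * 30^2), 0.05)
  # full-arc patch is annular: every wall-adjacent voxel at patch stations
  domf <- build_tube(100, 60, 1.0, 50, h = 2.5)
  mid <- round(dom$shape[1] / 2)
  wall_adj <- thrombosim:::.wall_adjacent(domf$fluid_mask)
  expect_equal(domf$reactive_mask[mid, , ], wall_adj[mid, , ])
  expect_error(build_tube(100, 12, 0.5, 50, h = 5), "coarse")
})

test_that("tube lumen volume error decreases under refinement", {
  errs <- vapply(c(10, 5, 2.5, 1.25), function(h) {
    dom <- build_tube(60, 60, 0.5, 20, h = h)
    vol <- sum(dom$fluid_mask) * h^3
    abs(vol - pi * 30^2 * 60)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[length(errs)], errs[1])
})

test_that("stenosis throat narrows as sqrt(1 - area reduction)", {
  for (ar in c(0.5, 0.75)) {
    dom <- build_stenosis(500, 60, 250, ar, 0.5, h = 2.5)
    rx <- dom$meta$radius_profile
    # the throat voxel center sits within half a voxel of the midpoint
    expect_equal(min(rx), 30 * sqrt(1 - ar), tolerance = 1e-3)
    expect_equal(max(rx), 30, tolerance = 1e-10)
    # cosine bump: symmetric about the midpoint
    n <- length(rx)
    expect_equal(rx, rev(rx), tolerance = 1e-10)
  }
  expect_error(build_stenosis(500, 60, 250, 0.995, 0.5, h = 2.5), "throat")
  expect_error(build_stenosis(500, 60, 600, 0.5, 0.5, h = 2.5), "smaller")
})

test_that("stenosis collagen sits on the stenotic segment wall", {
  dom <- build_stenosis(400, 60, 200, 0.75, 0.5, h = 5)
  xs <- (seq_len(dom$shape[1]) - 0.5) * 5
  has_coll <- apply(dom$reactive_mask, 1, any)
  expect_true(all(xs[has_coll] >= 100 & xs[has_coll] <= 300))
  expect_gt(sum(has_coll), 0)
})

test_that("reactive faces are wall-fluid interfaces everywhere", {
  for (dom in list(build_tube(100, 60, 0.5, 50, h = 5),
                   build_stenosis(200, 60, 100, 0.5, 0.5, h = 5))) {
    wall_adj <- thrombosim:::.wall_adjacent(dom$fluid_mask)
    expect_true(all(dom$reactive_mask[dom$reactive_mask] ==
                      (dom$fluid_mask & wall_adj)[dom$reactive_mask]))
    expect_false(any(dom$reactive_mask & !dom$fluid_mask))
  }
})

test_that("film mask distance semantics", {
  dom <- build_channel(100, 50, 40, 25, 50, h = 2.5, tf_on = TRUE)
  # zero thickness -> empty; monotone nondecreasing in thickness
  expect_equal(sum(compute_film_mask(dom, 0)), 0)
  counts <- vapply(c(5, 10, 15, 20), function(th)
    sum(compute_film_mask(dom, th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # flat patch: 15 um at h = 2.5 reaches exactly 6 voxel layers
  fm <- compute_film_mask(dom, 15)
  layers <- which(apply(fm, 3, any))
  expect_equal(max(layers), 6)
})
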