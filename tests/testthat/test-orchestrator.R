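tiny_config <- function(t_end = 5, seed = 1, ...) {
  simulation_config(
    geometry = list(kind = "channel", length = 100, width = 50, height = 40,
                    patch_start = 25, patch_length = 50, h = 5, tf_on = TRUE),
    flow = flow_params(bc_kind = "constant_shear_inlet",
                       inlet_wall_shear = 200),
    lkmc = list(mean_concentration = 3e4),
    schedule = list(t_end = t_end),
    seed = seed, ...)
}

test_that("zero-duration runs produce empty series", {
  res <- run_simulation(tiny_config(t_end = 0))
  expect_equal(nrow(res$metrics), 0)
  expect_equal(nrow(res$snapshot_final), 0)
  expect_null(occlusion_time(res))
})

test_that("identical config and seed replay bit-identically", {
  r1 <- run_simulation(tiny_config(t_end = 5, seed = 42))
  r2 <- run_simulation(tiny_config(t_end = 5, seed = 42))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$snapshot_final$id, r2$snapshot_final$id)
  expect_identical(r1$snapshot_final$xi, r2$snapshot_final$xi)
})

test_that("platelet bookkeeping balances every macro step", {
  res <- run_simulation(tiny_config(t_end = 10, seed = 2))
  m <- res$metrics
  expect_true(all(m$injected == m$bound + m$mobile + m$exited))
  expect_true(all(m$bound >= 0))
})

test_that("clot height profiles recover constructed deposits", {
  dom <- build_channel(100, 50, 40, 25, 50, h = 5, tf_on = FALSE)
  snap1 <- data.frame(id = 1L, x = 37.5, y = 22.5, z = 2.5,
                      i = 8L, j = 5L, k = 1L, mobile = FALSE, xi = 0, t = 0)
  pr <- clot_height_profile(snap1, dom)
  expect_equal(pr$height[8], 5)
  expect_true(all(pr$height[-8] == 0))
  # full monolayer over the patch: flat profile of one voxel height
  ij <- expand.grid(i = 6:15, j = 1:10)
  snapm <- data.frame(id = seq_len(nrow(ij)), x = (ij$i - 0.5) * 5,
                      y = (ij$j - 0.5) * 5, z = 2.5, i = ij$i, j = ij$j,
                      k = 1L, mobile = FALSE, xi = 0, t = 0)
  prm <- clot_height_profile(snapm, dom)
  expect_true(all(prm$height[6:15] == 5))
  # synthetic ridge with known height function is recovered exactly
  hk <- c(2, 4, 6, 4, 2)   # voxels tall at stations 8..12
  rows <- do.call(rbind, lapply(seq_along(hk), function(s) {
    expand.grid(i = 7 + s, j = 1:10, k = seq_len(hk[s]))
  }))
  snapr <- data.frame(id = seq_len(nrow(rows)), x = (rows$i - 0.5) * 5,
                      y = (rows$j - 0.5) * 5, z = (rows$k - 0.5) * 5,
                      i = rows$i, j = rows$j, k = rows$k, mobile = FALSE,
                      xi = 0, t = 0)
  prr <- clot_height_profile(snapr, dom)
  expect_equal(prr$height[8:12], hk * 5)
  # empty snapshot: zero profile
  pre <- clot_height_profile(snap1[0, ], dom)
  expect_true(all(pre$height == 0))
})

test_that("occlusion time interpolates the first strict crossing", {
  mk <- function(t, Q, Q0) {
    structure(list(metrics = data.frame(t = t, Q = Q), Q0 = Q0),
              class = "thrombosim_result")
  }
  expect_null(occlusion_time(mk(c(0, 10), c(1, 1), 1)))
  # crossing of 0.05 Q0 between the samples {0: Q0, 10: 0.04 Q0}
  ot <- occlusion_time(mk(c(0, 10), c(1, 0.04), 1))
  expect_equal(ot, 10 * (1 - 0.05) / (1 - 0.04))
  # dips below then recovers: first crossing is reported
  ot2 <- occlusion_time(mk(c(0, 10, 20, 30), c(1, 0.03, 0.8, 0.02), 1))
  expect_lt(ot2, 10)
})

test_that("scenario presets cover the study geometries and reject unknowns", {
  ps <- scenario_presets()
  expect_setequal(names(ps), c("channel_200", "tube_100", "stenosis_37",
                               "stenosis_50", "stenosis_63", "stenosis_75"))
  s75 <- scenario_presets("stenosis_75")
  expect_equal(s75$geometry$area_reduction, 0.75)
  expect_equal(s75$flow$initial_inlet_wall_shear, 1000)
  expect_equal(s75$flow$bc_kind, "constant_pressure_drop")
  t100 <- scenario_presets("tube_100")
  expect_equal(t100$geometry$diameter, 60)
  expect_equal(t100$geometry$patch_arc_fraction, 0.5)
  expect_equal(t100$flow$inlet_wall_shear, 100)
  expect_error(scenario_presets("nope"), "valid presets")
  # treatment arm wiring
  cfg <- scenario_presets("channel_200", treatment = "no_ADP")
  expect_equal(cfg$treatment, "no_ADP")
})

test_that("a constant-basal calcium model limits deposition to primary adhesion", {
  cfg <- tiny_config(t_end = 30, seed = 3,
                     signaling = list(model = constant_calcium_model(),
                                      activation = activation_params(),
                                      dt = 0.5))
  res <- run_simulation(cfg)
  b <- res$snapshot_final[!res$snapshot_final$mobile, ]
  # all deposition stays in the first layer on the collagen patch
  expect_true(all(b$k == 1))
  expect_true(all(b$x >= 25 & b$x <= 75))
})

test_that("field and snapshot exports produce readable files", {
  res <- run_simulation(tiny_config(t_end = 5, seed = 4))
  vtk <- tempfile(fileext = ".vtk")
  write_vtk_fields(vtk, res$domain,
                   list(fluid = res$domain$fluid_mask + 0,
                        film = res$domain$film_mask + 0))
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_equal(sum(lines == "LOOKUP_TABLE default"), 2)
  csv <- tempfile(fileext = ".csv")
  write_metrics_csv(res, csv)
  m <- read.csv(csv)
  expect_equal(nrow(m), nrow(res$metrics))
  csv2 <- tempfile(fileext = ".csv")
  write_platelets_csv(res, csv2)
  expect_true(file.exists(csv2))
})
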