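test_that("motion rates split convection upwind and diffusion isotropically", {
  dom <- build_channel(100, 50, 50, 0, 0, h = 2.5)
  fl <- uniform_flow(dom, c(100, 0, 0))
  r <- motion_rates(c(10, 10, 10), fl, D_platelet = 0, h = 2.5)
  expect_equal(unname(r), c(40, 0, 0, 0, 0, 0))
  fl0 <- uniform_flow(dom, c(0, 0, 0))
  r2 <- motion_rates(c(10, 10, 10), fl0, D_platelet = 10, h = 2.5)
  expect_equal(unname(r2), rep(1.6, 6))
  r3 <- motion_rates(c(10, 10, 10), fl, D_platelet = 10, h = 2.5)
  expect_equal(unname(r3[c("+x", "-x")]), c(41.6, 1.6))
  # blocking: wall below, occupied neighbour, inlet face
  occ <- array(FALSE, dom$shape); occ[11, 10, 10] <- TRUE
  r4 <- motion_rates(c(10, 10, 10), fl, 10, 2.5, domain = dom,
                     occupancy = occ)
  expect_equal(unname(r4[["+x"]]), 0)
  r5 <- motion_rates(c(10, 10, 1), fl, 10, 2.5, domain = dom)
  expect_equal(unname(r5[["-z"]]), 0)
  r6 <- motion_rates(c(1, 10, 10), fl, 10, 2.5, domain = dom)
  expect_equal(unname(r6[["-x"]]), 0)
})

test_that("direct KMC selection matches categorical probabilities and waiting times", {
  set.seed(11)
  rates <- c(3, 1)
  n <- 1e5
  picks <- integer(n); dts <- numeric(n)
  for (i in seq_len(n)) {
    s <- select_event(rates)
    picks[i] <- s$index; dts[i] <- s$dt
  }
  expect_equal(mean(picks == 1), 0.75, tolerance = 0.012)
  expect_equal(mean(dts), 1 / sum(rates), tolerance = 0.02)
  # single event: exponential waiting time with mean 1/r
  r <- 5
  dts1 <- vapply(seq_len(1e5), function(i) select_event(r)$dt, numeric(1))
  expect_equal(mean(dts1), 1 / r, tolerance = 0.02)
  expect_true(select_event(numeric(0))$quiescent)
  expect_true(select_event(c(0, 0))$quiescent)
})

test_that("free diffusion reproduces MSD = 6 D t", {
  set.seed(5)
  dom <- build_channel(600, 600, 600, 0, 0, h = 5)
  grid <- as.matrix(expand.grid(seq(5, 115, by = 5), seq(5, 115, by = 5),
                                seq(5, 115, by = 5)))
  grid <- grid[seq_len(10000), ]
  pop <- population_at(dom, grid)
  fl <- uniform_flow(dom)
  gam <- array(0, dom$shape)
  n <- nrow(grid)
  res <- kmc_advance(pop, dom, fl, gam, rep(0.01, n), rep(0.01, n),
                     adhesion_params(), D_platelet = 10, dt = 1)
  expect_equal(length(res$population$id), n)   # nobody exits or binds
  tr <- pos_to_trip(res$population$pos0, dom$shape)
  msd <- mean(rowSums((tr - grid)^2) * 25)
  expect_equal(msd, 60, tolerance = 0.03)
})

test_that("uniform flow reproduces the drift v t", {
  set.seed(6)
  dom <- build_channel(600, 1000, 1000, 0, 0, h = 5)
  # sparse distinct (y, z) rows: negligible mutual exclusion, no censoring
  yz <- as.matrix(expand.grid(seq(2, 199), seq(2, 199)))
  yz <- yz[sample(nrow(yz), 5000), ]
  grid <- cbind(20L, yz)
  pop <- population_at(dom, grid)
  fl <- uniform_flow(dom, c(150, 0, 0))
  gam <- array(0, dom$shape)
  res <- kmc_advance(pop, dom, fl, gam, rep(0.01, 5000), rep(0.01, 5000),
                     adhesion_params(), D_platelet = 10, dt = 1)
  tr <- pos_to_trip(res$population$pos0, dom$shape)
  drift <- mean((tr[, 1] - 20) * 5)
  expect_equal(drift, 150, tolerance = 0.02)
})

test_that("hard exclusion holds and the event table audit is exact", {
  set.seed(9)
  dom <- build_channel(150, 50, 40, 25, 100, h = 5, tf_on = FALSE)
  fl <- uniform_flow(dom, c(300, 0, -20))
  gam <- array(100, dom$shape)
  grid <- as.matrix(expand.grid(1:15, seq(1, 9, by = 2), seq(1, 7, by = 2)))
  n <- nrow(grid)
  pop <- population_at(dom, grid)
  # strong activation so attach and detach events both fire
  res <- kmc_advance(pop, dom, fl, gam, rep(0.6, n), rep(0.6, n),
                     adhesion_params(), D_platelet = 10, dt = 2,
                     audit = TRUE)
  expect_gt(res$n_attach, 0)
  expect_equal(res$audit_diff, 0, tolerance = 1e-7)
  expect_false(any(duplicated(res$population$pos0)))
})

test_that("inlet injection matches the flux-concentration product", {
  set.seed(3)
  dom <- build_channel(150, 100, 60, 0, 0, h = 5)
  fp <- flow_params(bc_kind = "constant_shear_inlet", inlet_wall_shear = 200)
  fl <- solve_flow(dom, NULL, fp)
  conc <- 2e4
  # uniform profile: expected arrivals per second = Q * C (counting the
  # arrivals discarded by voxel exclusion restores the raw Poisson total)
  n_tot <- 0; nsteps <- 300
  for (i in seq_len(nsteps)) {
    pop <- inject_inlet(new_population(), dom, fl, conc,
                        wall_excess = list(factor = 1, delta = 5), dt = 0.5)
    n_tot <- n_tot + length(pop$id) + attr(pop, "n_discarded")
  }
  expected <- fl$Q / 60 * 1e9 * conc * 1e-9 * 0.5 * nsteps
  expect_equal(n_tot, expected, tolerance = 4 / sqrt(expected))
  # zero flow: no convective arrivals
  pop <- inject_inlet(new_population(), dom, uniform_flow(dom), conc,
                      list(factor = 1, delta = 5), dt = 0.5)
  expect_equal(length(pop$id), 0)
})

test_that("marginated profile enriches near-wall arrivals about threefold", {
  set.seed(4)
  dom <- build_channel(150, 100, 60, 0, 0, h = 5)
  fp <- flow_params(bc_kind = "constant_shear_inlet", inlet_wall_shear = 200)
  fl <- solve_flow(dom, NULL, fp)
  counts <- matrix(0, dom$shape[2], dom$shape[3])
  for (i in 1:600) {
    pop <- inject_inlet(new_population(), dom, fl, 3e3,
                        wall_excess = list(factor = 3, delta = 5.1), dt = 0.5)
    if (length(pop$id)) {
      tr <- pos_to_trip(pop$pos0, dom$shape)
      for (r in seq_len(nrow(tr)))
        counts[tr[r, 2], tr[r, 3]] <- counts[tr[r, 2], tr[r, 3]] + 1
    }
  }
  # compare arrival density per unit flux near wall vs core
  ux <- fl$ux[1, , ]
  wallband <- outer(pmin((1:dom$shape[2]) - 0.5, dom$shape[2] - (1:dom$shape[2]) + 0.5) * 5,
                    pmin((1:dom$shape[3]) - 0.5, dom$shape[3] - (1:dom$shape[3]) + 0.5) * 5,
                    pmin) <= 5.1
  dens_wall <- sum(counts[wallband]) / sum(ux[wallband])
  dens_core <- sum(counts[!wallband]) / sum(ux[!wallband])
  # core factor is depleted so the flux-weighted mean stays at C_mean
  Sw <- sum(ux[wallband]); Sc <- sum(ux[!wallband])
  f_core <- (Sw + Sc - 3 * Sw) / Sc
  expect_equal(dens_wall / dens_core, 3 / f_core, tolerance = 0.2)
  expect_gt(dens_wall / dens_core, 2.5)
})
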