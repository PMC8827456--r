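tp <- transport_params()

test_that("release rate follows the exponential granule-release law", {
  pl <- list(release_triggered = TRUE, t_release = 10)
  expect_equal(release_rate(pl, "ADP", 10, tp), tp$M[["ADP"]] / tp$tau[["ADP"]])
  expect_equal(release_rate(pl, "TXA2", 10 + tp$tau[["TXA2"]], tp),
               tp$M[["TXA2"]] / tp$tau[["TXA2"]] * exp(-1))
  expect_equal(release_rate(pl, "ADP", 5, tp), 0)      # before trigger time
  expect_equal(release_rate(list(release_triggered = FALSE,
                                 t_release = NA), "ADP", 100, tp), 0)
  # total released over 10 tau recovers M to within 0.1%
  total <- stats::integrate(function(t)
    vapply(t, function(ti) release_rate(pl, "ADP", ti, tp), numeric(1)),
    lower = 10, upper = 10 + 10 * tp$tau[["ADP"]])$value
  expect_lt(abs(total - tp$M[["ADP"]]) / tp$M[["ADP"]], 1e-3)
})

test_that("uniform field in a closed quiescent box is an equilibrium", {
  dom <- build_channel(50, 50, 50, 0, 0, h = 5)
  fl <- uniform_flow(dom)
  f <- concentration_fields(dom)
  f$C$ADP[] <- 7.5; f$C$TXA2[] <- 3.25
  f2 <- advance_transport(f, fl, list(), 0.5, tp, dom)
  expect_equal(f2$C$ADP, f$C$ADP, tolerance = 1e-12)
  expect_equal(f2$C$TXA2, f$C$TXA2, tolerance = 1e-12)
})

test_that("point source in quiescent fluid matches the diffusion Green's function", {
  dom <- build_channel(150, 150, 150, 0, 0, h = 2.5)
  fl <- uniform_flow(dom)
  f <- concentration_fields(dom)
  src <- list(ADP = array(0, dom$shape))
  ctr <- dom$shape %/% 2
  src$ADP[ctr[1], ctr[2], ctr[3]] <- 1e5       # nM/s in one voxel
  t_tot <- 5
  for (s in seq_len(t_tot / 0.5))
    f <- advance_transport(f, fl, src, 0.5, tp, dom, method = "explicit")
  D <- tp$D[["ADP"]]; h <- 2.5
  S_tot <- 1e5 * h^3                            # nM um^3 / s
  r <- (4:10) * h                               # r > 3h
  num <- f$C$ADP[ctr[1] + 4:10, ctr[2], ctr[3]]
  erfc <- function(x) 2 * stats::pnorm(sqrt(2) * x, lower.tail = FALSE)
  ana <- S_tot / (4 * pi * D * r) * erfc(r / sqrt(4 * D * t_tot))
  expect_lt(max(abs(num / ana - 1)), 0.05)
})

test_that("global mass balance holds per macro step under flow", {
  dom <- build_channel(150, 50, 50, 25, 50, h = 5)
  fp <- flow_params(bc_kind = "constant_shear_inlet", inlet_wall_shear = 200)
  fl <- solve_flow(dom, NULL, fp)
  h <- 5
  src <- list(ADP = array(0, dom$shape))
  src$ADP[10, 5, 2] <- 5e4; src$ADP[15, 6, 1] <- 2e4
  added_per_s <- sum(src$ADP) * h^3
  for (method in c("explicit", "implicit")) {
    f <- concentration_fields(dom)
    for (s in 1:20) {
      tot0 <- sum(f$C$ADP) * h^3
      f <- advance_transport(f, fl, src, 0.5, tp, dom, method = method)
      tot1 <- sum(f$C$ADP) * h^3
      out <- attr(f, "mass_out")[["ADP"]]
      balance <- (tot1 - tot0) - (added_per_s * 0.5 - out)
      denom <- max(added_per_s * 0.5, tot1)
      expect_lt(abs(balance) / denom, 0.005)
    }
    expect_true(all(f$C$ADP >= 0))
  }
})

test_that("released agonist forms a near-wall boundary layer under shear", {
  dom <- build_channel(200, 50, 60, 50, 100, h = 5)
  fp <- flow_params(bc_kind = "constant_shear_inlet", inlet_wall_shear = 200)
  fl <- solve_flow(dom, NULL, fp)
  f <- concentration_fields(dom)
  src <- list(ADP = array(0, dom$shape))
  src$ADP[20:28, 5, 1] <- 3e4   # steady release along the floor
  for (s in 1:120) f <- advance_transport(f, fl, src, 0.5, tp, dom,
                                          method = "explicit")
  prof <- f$C$ADP[30, 5, ]       # vertical profile just downstream
  zc <- (seq_along(prof) - 0.5) * 5
  # concentration confined near the wall: drops below 10% of its floor value
  # within ~10-15 um
  expect_lt(prof[4] / prof[1], 0.1)   # z = 17.5 um
  expect_gt(prof[1], 0)
})

test_that("agonist sampling reports EC50-normalized concentrations", {
  dom <- build_tube(50, 30, 0.5, 20, h = 5)
  f <- concentration_fields(dom)
  ctr <- c(5L, 3L, 3L)
  f$C$ADP[ctr[1], ctr[2], ctr[3]] <- tp$EC50[["ADP"]]
  f$C$TXA2[ctr[1], ctr[2], ctr[3]] <- 5 * tp$EC50[["TXA2"]]
  s <- sample_agonists(f, ctr, dom, tp)
  expect_equal(unname(s$ec50[["ADP"]]), 1)
  expect_equal(unname(s$ec50[["TXA2"]]), 5)
  expect_equal(unname(sample_agonists(f, c(6L, 3L, 3L), dom, tp)$nM[["ADP"]]), 0)
  wall <- which(dom$wall_mask, arr.ind = TRUE)[1, ]
  expect_error(sample_agonists(f, wall, dom, tp), "wall")
})
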