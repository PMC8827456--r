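adh <- adhesion_params()

test_that("shear enhancement E reproduces every printed branch", {
  expect_equal(shear_enhancement_E(0, adh), 1)
  expect_equal(shear_enhancement_E(1000, adh), 1)
  expect_equal(shear_enhancement_E(3000, adh), 1)
  expect_equal(shear_enhancement_E(5500, adh), 1 + 19 * 2500 / 5000) # 10.5
  expect_equal(shear_enhancement_E(8000, adh), 20)
  expect_equal(shear_enhancement_E(10000, adh), 20)
  expect_error(shear_enhancement_E(-1, adh), "nonnegative")
  # ablation flag: identity everywhere
  off <- adhesion_params(vwf_enhancement_on = FALSE)
  g <- seq(0, 20000, by = 500)
  expect_equal(shear_enhancement_E(g, off), rep(1, length(g)))
})

test_that("breakage G reproduces the printed piecewise form", {
  p <- adhesion_params(gamma_c = 1000, gamma_c_prime = 4000)
  expect_equal(breakage_G(0, p), 1)
  expect_equal(breakage_G(500, p), exp(0.5))
  expect_equal(breakage_G(1000, p), exp(1))
  # printed high-shear branch (with its jump at the breakpoint)
  expect_equal(breakage_G(2000, p), exp(1) * exp(2000 / 4000))
  expect_gt(breakage_G(1000 + 1e-9, p) / breakage_G(1000, p), exp(0.2))
  # continuity-corrected variant is continuous and monotone
  pc <- adhesion_params(gamma_c = 1000, gamma_c_prime = 4000,
                        G_continuous_variant = TRUE)
  expect_equal(breakage_G(1000 + 1e-9, pc), breakage_G(1000, pc),
               tolerance = 1e-6)
  g <- seq(0, 20000, by = 100)
  expect_true(all(diff(breakage_G(g, pc)) >= 0))
  expect_error(breakage_G(-5, p), "nonnegative")
})

test_that("attachment rate laws combine activation and enhancement", {
  expect_equal(attach_rate_collagen(1, 1, 100, adh), adh$k_att_collagen)
  expect_equal(attach_rate_collagen(0.01, 0.01, 100, adh),
               1e-4 * adh$k_att_collagen)
  # the 20-fold VWF factor passes straight through
  expect_equal(attach_rate_collagen(0.3, 0.2, 10000, adh) /
                 attach_rate_collagen(0.3, 0.2, 100, adh), 20)
  # platelet-platelet: geometric mean, symmetric under i <-> j
  expect_equal(attach_rate_platelet(c(1, 1), c(1, 1), 100, 100, adh),
               adh$k_att_platelet)
  expect_equal(attach_rate_platelet(c(0.01, 0.01), c(1, 1), 100, 100, adh),
               0.01 * adh$k_att_platelet)
  expect_equal(attach_rate_platelet(c(0.3, 0.7), c(0.9, 0.2), 4000, 6000, adh),
               attach_rate_platelet(c(0.9, 0.2), c(0.3, 0.7), 6000, 4000, adh))
})

test_that("detachment rate laws invert activation and accelerate with G", {
  p <- adhesion_params(gamma_c = 1000, gamma_c_prime = 4000)
  expect_equal(detach_rate_collagen(1, 1, 0, p), p$k_det_collagen)
  expect_equal(detach_rate_collagen(1, 1, 500, p),
               p$k_det_collagen * exp(0.5))
  # monotone: more activated platelets detach more slowly
  Fs <- seq(0.05, 1, by = 0.05)
  rates <- detach_rate_collagen(Fs, 0.5, 2000, p)
  expect_true(all(diff(rates) < 0))
  expect_error(detach_rate_collagen(0, 1, 100, p), "positive")
  expect_equal(detach_rate_platelet(c(1, 1), c(1, 1), 0, 0, p),
               p$k_det_platelet)
  expect_equal(detach_rate_platelet(c(0.3, 0.7), c(0.9, 0.2), 500, 800, p),
               detach_rate_platelet(c(0.9, 0.2), c(0.3, 0.7), 800, 500, p))
  # doubling both G factors doubles the rate: G(gamma) with gamma_c halved
  r1 <- detach_rate_platelet(c(1, 1), c(1, 1), 693.147, 693.147, p)
  expect_equal(r1, p$k_det_platelet * 2, tolerance = 1e-4)
})

test_that("VWF enhancement raises net deposition flux at pathological shear", {
  on <- adhesion_params(vwf_enhancement_on = TRUE)
  off <- adhesion_params(vwf_enhancement_on = FALSE)
  F_xi <- 0.5; F_dt <- 0.5; g <- 8000
  net_on <- attach_rate_collagen(F_xi, F_dt, g, on) -
    detach_rate_collagen(F_xi, F_dt, g, on)
  net_off <- attach_rate_collagen(F_xi, F_dt, g, off) -
    detach_rate_collagen(F_xi, F_dt, g, off)
  expect_gt(net_on, net_off)
})
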