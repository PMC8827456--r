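ap <- activation_params()

test_that("Hill activation passes the zero, midpoint and saturation identities", {
  expect_equal(hill_F(0, ap), ap$alpha_min)
  expect_equal(hill_F(ap$theta_50, ap), (ap$alpha_min + ap$alpha_max) / 2)
  expect_lt(abs(hill_F(1e6 * ap$theta_50, ap) - ap$alpha_max), 1e-9)
  # monotone nondecreasing, bounded
  th <- seq(0, 10 * ap$theta_50, length.out = 200)
  Fv <- hill_F(th, ap)
  expect_true(all(diff(Fv) >= 0))
  expect_true(all(Fv >= ap$alpha_min & Fv <= ap$alpha_max))
})

test_that("activation integrals accumulate supra-basal calcium", {
  st <- new_signal_state()
  for (i in 1:20) st <- update_activation(st, 100, 0.5, ap)
  expect_equal(st$xi, 0)
  expect_false(st$release_triggered)

  st <- new_signal_state()
  for (i in 1:20) st <- update_activation(st, 200, 0.5, ap)
  expect_equal(st$xi, 1000)   # (200 - 100) * 10 s
  # recent-history window: constant trace gives xi_dt / xi = window / t
  st <- new_signal_state()
  for (i in 1:200) st <- update_activation(st, 200, 0.5, ap)
  expect_equal(st$xi_dt / st$xi, ap$dt_window / 100, tolerance = 0.02)
  expect_error(update_activation(st, -5, 0.5, ap), "nonnegative")
})

test_that("release trigger latches at xi_crit and records the crossing time", {
  ap2 <- activation_params(xi_crit = 500)
  st <- new_signal_state()
  for (i in 1:20) st <- update_activation(st, 200, 0.5, ap2)
  expect_true(st$release_triggered)
  # 100 nM excess at 50 nM s per half-second step: xi first exceeds 500
  # at the 11th sample, t = 5.5 s
  expect_equal(st$t_release, 5.5)
})

test_that("default calcium model is basal-stable and inhibitable", {
  mod <- default_calcium_model()
  n <- 3
  state <- mod$init(n)
  zero <- list(collagen = numeric(n), adp = numeric(n), txa2 = numeric(n),
               thrombin = numeric(n), gsno = numeric(n), iloprost = numeric(n))
  for (i in 1:200) {
    out <- mod$step(state, zero, 0.5)
    state <- out$state
  }
  expect_equal(unname(out$ca), rep(100, n), tolerance = 1e-10)

  # saturating iloprost suppresses calcium under strong stimulation: xi
  # never approaches the release threshold
  state <- mod$init(1)
  expo <- list(collagen = 1, adp = 5000, txa2 = 500, thrombin = 100,
               gsno = 0, iloprost = 1)
  st <- new_signal_state()
  for (i in 1:800) {   # 400 s
    out <- mod$step(state, expo, 0.5); state <- out$state
    st <- update_activation(st, out$ca, 0.5, ap)
  }
  expect_lt(st$xi, ap$xi_crit / 10)
  expect_false(st$release_triggered)
})

test_that("thrombin response is fast-on slow-off relative to ADP", {
  mod <- default_calcium_model()
  decay_tau <- function(expo_on) {
    state <- mod$init(1)
    zero <- list(collagen = 0, adp = 0, txa2 = 0, thrombin = 0, gsno = 0,
                 iloprost = 0)
    for (i in 1:20) { out <- mod$step(state, expo_on, 0.5); state <- out$state }
    peak <- out$ca - 100
    tt <- 0
    repeat {
      out <- mod$step(state, zero, 0.5); state <- out$state; tt <- tt + 0.5
      if (out$ca - 100 < peak * exp(-1) || tt > 600) break
    }
    tt
  }
  tau_thr <- decay_tau(list(collagen = 0, adp = 0, txa2 = 0, thrombin = 100,
                            gsno = 0, iloprost = 0))
  tau_adp <- decay_tau(list(collagen = 0, adp = 5000, txa2 = 0, thrombin = 0,
                            gsno = 0, iloprost = 0))
  expect_gte(tau_thr / tau_adp, 5)
})

test_that("collagen + thrombin exposure outactivates soluble agonists alone", {
  mod <- default_calcium_model()
  run_xi <- function(expo) {
    state <- mod$init(1); st <- new_signal_state()
    for (i in 1:400) {   # 200 s
      out <- mod$step(state, expo, 0.5); state <- out$state
      st <- update_activation(st, out$ca, 0.5, ap)
    }
    st$xi
  }
  xi_core <- run_xi(list(collagen = 1, adp = 0, txa2 = 0, thrombin = 50,
                         gsno = 0, iloprost = 0))
  xi_shell <- run_xi(list(collagen = 0, adp = 1000, txa2 = 100, thrombin = 0,
                          gsno = 0, iloprost = 0))
  expect_gt(xi_core, xi_shell)
})
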