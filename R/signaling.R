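# Per-platelet signaling: a pluggable calcium model maps agonist exposure to
# an intracellular calcium trace; the trace is integrated into the cumulative
# activation state xi and the recent-history state xi_dt, which the Hill
# function maps onto integrin activation F.

CA_BASAL <- 100  # basal intracellular calcium (nM)

#' Activation-integral parameters
#'
#' @param alpha_min,alpha_max basal and maximal integrin activation levels
#' @param n Hill exponent
#' @param theta_50 half-activation calcium integral (nM s)
#' @param xi_crit cumulative activation threshold for dense-granule release
#'   (nM s)
#' @param dt_window recent-history window (s)
#' @return an `activation_params` list
#' @export
activation_params <- function(alpha_min = 0.01, alpha_max = 1, n = 2,
                              theta_50 = 15000, xi_crit = 15000,
                              dt_window = 30) {
  stopifnot(alpha_min > 0, alpha_min < alpha_max, n > 0, theta_50 > 0,
            xi_crit > 0, dt_window > 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, n = n,
                 theta_50 = theta_50, xi_crit = xi_crit,
                 dt_window = dt_window),
            class = "activation_params")
}

#' Hill-normalized integrin activation
#'
#' `F(theta) = alpha_min + (alpha_max - alpha_min) * theta^n /
#' (theta^n + theta_50^n)`, applied identically to the cumulative integral xi
#' and the recent-history integral xi_dt.
#'
#' @param theta calcium integral (nM s), vectorized, nonnegative
#' @param params an [activation_params()] object
#' @return dimensionless activation in `[alpha_min, alpha_max]`
#' @export
hill_F <- function(theta, params = activation_params()) {
  stopifnot(all(theta >= 0))
  tn <- theta^params$n
  params$alpha_min + (params$alpha_max - params$alpha_min) *
    tn / (tn + params$theta_50^params$n)
}

#' Initialize a platelet signaling state
#'
#' @param t0 creation time (s)
#' @return a `platelet_signal_state` list
#' @export
new_signal_state <- function(t0 = 0) {
  structure(list(ca_prev = NA_real_, xi = 0,
                 hist_t = numeric(0), hist_incr = numeric(0),
                 xi_dt = 0, release_triggered = FALSE, t_release = NA_real_,
                 t = t0),
            class = "platelet_signal_state")
}

#' Advance a platelet's activation integrals by one calcium sample
#'
#' Accumulates `max([Ca] - basal, 0)` into the cumulative integral xi by the
#' trapezoidal rule (the first sample is treated as a rectangle), recomputes
#' the recent-history integral xi_dt over the trailing `dt_window`, and
#' latches the release trigger when xi exceeds `xi_crit` (the crossing time
#' is recorded as `t_release`).
#'
#' @param state a `platelet_signal_state` (see [new_signal_state()])
#' @param new_ca calcium concentration at the new sample (nM)
#' @param dt time since the previous sample (s)
#' @param params an [activation_params()] object
#' @return the updated state
#' @export
update_activation <- function(state, new_ca, dt, params = activation_params()) {
  stopifnot(dt > 0)
  if (new_ca < 0) stop("calcium concentration must be nonnegative")
  above_new <- max(new_ca - CA_BASAL, 0)
  incr <- if (is.na(state$ca_prev)) above_new * dt
          else 0.5 * (max(state$ca_prev - CA_BASAL, 0) + above_new) * dt
  state$t <- state$t + dt
  state$xi <- state$xi + incr
  state$hist_t <- c(state$hist_t, state$t)
  state$hist_incr <- c(state$hist_incr, incr)
  keep <- state$hist_t > state$t - params$dt_window
  state$hist_t <- state$hist_t[keep]; state$hist_incr <- state$hist_incr[keep]
  state$xi_dt <- sum(state$hist_incr)
  if (!state$release_triggered && state$xi > params$xi_crit) {
    state$release_triggered <- TRUE
    state$t_release <- state$t
  }
  state$ca_prev <- new_ca
  state
}

#' Default phenomenological calcium model
#'
#' A stand-in for a trained patient-specific calcium-response model, built
#' from per-receptor occupancy kinetics: each agonist j drives a first-order
#' receptor state `a_j` (`da_j/dt = k_on_j s_j (1 - a_j) - k_off_j a_j`, with
#' `s_j` the saturating stimulus), ADP and TXA2 additionally desensitize
#' (`ds/dt = -s_j a-drive / tau_des`), and calcium relaxes toward
#' `basal + amp * drive / (drive + K_half)` scaled by `1 - I_inh`, where the
#' inhibition factor `I_inh` saturates to 1 under iloprost (IP receptor) or
#' GSNO stimulation. Collagen and thrombin dissociate slowly (sustained
#' calcium; thrombin is fast-on, slow-off), ADP and TXA2 faster.
#'
#' The model is deterministic, holds exactly at basal (100 nM) with zero
#' agonists, and is vectorized over platelets.
#'
#' @param params optional list overriding individual rate constants (see
#'   source for names)
#' @return a `calcium_model`: list with `init(n)` returning a state matrix
#'   for n platelets and `step(state, exposure, dt)` returning
#'   `list(ca, state)`. `exposure` is a list of equal-length vectors:
#'   `collagen` (0/1), `adp`, `txa2`, `thrombin` (nM), `gsno`, `iloprost`
#'   (saturation units: 1 = fully saturating).
#' @export
default_calcium_model <- function(params = list()) {
  p <- list(
    k_on_col = 0.05, k_off_col = 0.005,
    k_on_adp = 0.5,  k_off_adp = 0.1,
    k_on_txa = 0.5,  k_off_txa = 0.1,
    k_on_thr = 1.0,  k_off_thr = 0.01,
    tau_des = 150,
    w_col = 1.2, w_adp = 0.8, w_txa = 0.3, w_thr = 1.5,
    K_half = 0.5, ca_amp = 600, tau_ca = 5,
    ec50_adp = 500, ec50_txa2 = 50, ec50_thr = 5
  )
  p[names(params)] <- params
  state_cols <- c("a_col", "a_adp", "a_txa", "a_thr", "s_adp", "s_txa", "ca")
  init <- function(n) {
    m <- matrix(0, nrow = n, ncol = length(state_cols),
                dimnames = list(NULL, state_cols))
    if (n > 0) { m[, "s_adp"] <- 1; m[, "s_txa"] <- 1; m[, "ca"] <- CA_BASAL }
    m
  }
  step <- function(state, exposure, dt) {
    n <- nrow(state)
    stim_col <- as.numeric(exposure$collagen > 0)
    stim_adp <- exposure$adp / (exposure$adp + p$ec50_adp)
    stim_txa <- exposure$txa2 / (exposure$txa2 + p$ec50_txa2)
    stim_thr <- exposure$thrombin / (exposure$thrombin + p$ec50_thr)
    # sub-step the receptor ODEs for stability at the signaling step
    nsub <- max(1L, ceiling(dt / 0.5))
    ds <- dt / nsub
    a_col <- state[, "a_col"]; a_adp <- state[, "a_adp"]
    a_txa <- state[, "a_txa"]; a_thr <- state[, "a_thr"]
    s_adp <- state[, "s_adp"]; s_txa <- state[, "s_txa"]
    ca <- state[, "ca"]
    # inhibition saturates exactly at 1 (full shutdown) for iloprost or GSNO
    # at or above one saturation unit
    raw_inh <- 1 - 1 / ((1 + 20 * pmin(exposure$iloprost, 1e6)) *
                        (1 + 20 * pmin(exposure$gsno, 1e6)))
    inh <- pmin(1, raw_inh / (1 - 1 / 21))
    for (s in seq_len(nsub)) {
      a_col <- a_col + ds * (p$k_on_col * stim_col * (1 - a_col) -
                             p$k_off_col * a_col)
      a_adp <- a_adp + ds * (p$k_on_adp * stim_adp * s_adp * (1 - a_adp) -
                             p$k_off_adp * a_adp)
      a_txa <- a_txa + ds * (p$k_on_txa * stim_txa * s_txa * (1 - a_txa) -
                             p$k_off_txa * a_txa)
      a_thr <- a_thr + ds * (p$k_on_thr * stim_thr * (1 - a_thr) -
                             p$k_off_thr * a_thr)
      s_adp <- s_adp - ds * s_adp * stim_adp / p$tau_des
      s_txa <- s_txa - ds * s_txa * stim_txa / p$tau_des
      drive <- p$w_col * a_col + p$w_adp * a_adp + p$w_txa * a_txa +
        p$w_thr * a_thr
      ca_target <- CA_BASAL + p$ca_amp * drive / (drive + p$K_half) * (1 - inh)
      ca <- ca + ds * (ca_target - ca) / p$tau_ca
    }
    state[, "a_col"] <- a_col; state[, "a_adp"] <- a_adp
    state[, "a_txa"] <- a_txa; state[, "a_thr"] <- a_thr
    state[, "s_adp"] <- s_adp; state[, "s_txa"] <- s_txa
    state[, "ca"] <- pmax(ca, 0)
    list(ca = state[, "ca"], state = state)
  }
  structure(list(init = init, step = step, params = p),
            class = "calcium_model")
}

#' Constant-basal calcium model
#'
#' Returns basal calcium regardless of exposure; plugging it into a
#' simulation suppresses all activation-dependent deposition beyond primary
#' collagen adhesion.
#'
#' @return a `calcium_model`
#' @export
constant_calcium_model <- function() {
  init <- function(n) matrix(CA_BASAL, nrow = n, ncol = 1,
                             dimnames = list(NULL, "ca"))
  step <- function(state, exposure, dt) list(ca = state[, "ca"], state = state)
  structure(list(init = init, step = step, params = list()),
            class = "calcium_model")
}
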