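# Thin-film reduced coagulation cascade: an 8-state ODE system over the
# well-mixed ~15 um fibrin-rich zone above the tissue-factor-bearing patch.
# Network (Michaelis-Menten kinetics, one lumped activity per reaction, each
# scaled by an effectiveness factor for transport limitation):
#   r1 extrinsic tenase / FIXase: wall TF:VIIa activates FX and FIX, and FXIa
#      activates FIX (the lumped FIXase arm)
#   r2 intrinsic tenase: FIXa (with cofactor VIIIa, lumped) activates FX
#   r3 prothrombinase: FXa (with Va, lumped) converts prothrombin to thrombin
#   r4 thrombin feedback activation of FXI
#   r5 fibrin generation: thrombin cleaves fibrinogen
#   r6 thrombin-fibrin binding (sequestration, first order on/off)
# Soluble enzymes (FIXa, FXa, FXIa, free thrombin) elute from the film with
# first-order rate ln(2)/elution_half_life; fibrin and fibrin-bound thrombin
# do not. Zymogen pools FIX, FX, FXI are held at plasma levels; prothrombin
# and fibrinogen are tracked, depletable, and replenished toward plasma
# levels at the elution rate (the same exchange with flowing plasma that
# elutes the enzymes). Rate constants are literature-guided defaults and
# config-owned.

#' Coagulation parameters
#'
#' All kinetic constants of the thin-film reduced cascade. `tf_surface_density`
#' scales extrinsic initiation (1 = reference TF coating; 0 switches the
#' cascade off). Effectiveness factors (actual/transport-unlimited rate) scale
#' each reaction.
#'
#' @param kcat list-like overrides of catalytic constants (1/s), names
#'   `tf_ix`, `tf_x`, `xia_ix`, `ixa_x`, `xa_ii`, `iia_xi`, `iia_fg`
#' @param KM Michaelis constants (nM), names `ix`, `x`, `xi`, `ii`, `fg`
#' @param eff effectiveness factors in (0, 1], names `r1`..`r6`
#' @param elution_half_life s, half-life of soluble species elution (default 2)
#' @param plasma initial zymogen levels (nM), names `IX`, `X`, `XI`, `II`, `Fg`
#' @param tf_surface_density dimensionless TF coating scale
#' @param tf_conc effective TF:VIIa concentration at reference density (nM)
#' @param kon_fn,koff_fn thrombin-fibrin binding/unbinding rates (1/(nM s), 1/s)
#' @return a `coag_params` list
#' @export
coag_params <- function(kcat = list(), KM = list(), eff = list(),
                        elution_half_life = 2,
                        plasma = list(), tf_surface_density = 1,
                        tf_conc = 0.5, kon_fn = 2e-6, koff_fn = 0.01) {
  kc <- list(tf_ix = 5, tf_x = 11, xia_ix = 5.1, ixa_x = 6.7,
             xa_ii = 20, iia_xi = 0.0185, iia_fg = 15)
  kc[names(kcat)] <- kcat
  km <- list(ix = 240, x = 160, xi = 50, ii = 1060, fg = 7200)
  km[names(KM)] <- KM
  ef <- list(r1 = 0.01, r2 = 0.5, r3 = 0.3, r4 = 1, r5 = 0.05, r6 = 1)
  ef[names(eff)] <- eff
  pl <- list(IX = 90, X = 170, XI = 30, II = 1400, Fg = 9000)
  pl[names(plasma)] <- plasma
  stopifnot(elution_half_life > 0, tf_surface_density >= 0)
  if (any(unlist(ef) <= 0) || any(unlist(ef) > 1))
    stop("effectiveness factors must lie in (0, 1]")
  structure(list(kcat = kc, KM = km, eff = ef,
                 elution_half_life = elution_half_life,
                 plasma = pl, tf_surface_density = tf_surface_density,
                 tf_conc = tf_conc, kon_fn = kon_fn, koff_fn = koff_fn),
            class = "coag_params")
}

#' Initial coagulation state
#'
#' Plasma zymogen levels, no active enzymes, no fibrin.
#'
#' @param params a [coag_params()] object
#' @return a `coag_state` named numeric vector with time attribute
#' @export
coag_init <- function(params = coag_params()) {
  y <- c(FIXa = 0, FXa = 0, FXIa = 0, IIa = 0,
         II = params$plasma$II, Fg = params$plasma$Fg, Fn = 0, IIa_fn = 0)
  structure(list(y = y, t = 0), class = "coag_state")
}

.coag_rhs <- function(t, y, p) {
  kc <- p$kcat; km <- p$KM; ef <- p$eff; pl <- p$plasma
  kelu <- log(2) / p$elution_half_life
  tf <- p$tf_surface_density * p$tf_conc
  y <- pmax(y, 0)
  sat_ix <- pl$IX / (km$ix + pl$IX)
  sat_x <- pl$X / (km$x + pl$X)
  sat_xi <- pl$XI / (km$xi + pl$XI)
  sat_ii <- y[["II"]] / (km$ii + y[["II"]])
  sat_fg <- y[["Fg"]] / (km$fg + y[["Fg"]])
  v_ix <- (ef$r1 * kc$tf_ix * tf + ef$r2 * kc$xia_ix * y[["FXIa"]]) * sat_ix
  v_x_ext <- ef$r1 * kc$tf_x * tf * sat_x
  v_x_int <- ef$r2 * kc$ixa_x * y[["FIXa"]] * sat_x
  v_ii <- ef$r3 * kc$xa_ii * y[["FXa"]] * sat_ii
  v_xi <- ef$r4 * kc$iia_xi * y[["IIa"]] * sat_xi
  v_fg <- ef$r5 * kc$iia_fg * y[["IIa"]] * sat_fg
  bind <- ef$r6 * (p$kon_fn * y[["IIa"]] * y[["Fn"]] - p$koff_fn * y[["IIa_fn"]])
  list(c(
    FIXa = v_ix - kelu * y[["FIXa"]],
    FXa = v_x_ext + v_x_int - kelu * y[["FXa"]],
    FXIa = v_xi - kelu * y[["FXIa"]],
    IIa = v_ii - bind - kelu * y[["IIa"]],
    # elution exchanges film plasma with flowing plasma: tracked zymogens
    # are replenished toward their plasma levels at the same rate
    II = -v_ii + kelu * (pl$II - y[["II"]]),
    Fg = -v_fg + kelu * (pl$Fg - y[["Fg"]]),
    Fn = v_fg,
    IIa_fn = bind
  ))
}

#' Advance the thin-film coagulation state
#'
#' Stiff-safe integration (lsoda) of the reduced cascade over `dt`.
#' Nonnegativity is preserved (rates vanish at zero substrate; a final clip
#' removes integrator round-off).
#'
#' @param state a `coag_state`
#' @param params a [coag_params()] object
#' @param dt time step (s)
#' @return the advanced `coag_state`
#' @export
advance_coag <- function(state, params = coag_params(), dt) {
  stopifnot(inherits(state, "coag_state"), dt > 0)
  out <- deSolve::lsoda(y = state$y, times = c(0, dt), func = .coag_rhs,
                        parms = params, rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0)
    stop("coagulation ODE integration failed; state: ",
         paste(sprintf("%s=%.3g", names(state$y), state$y), collapse = ", "))
  y <- pmax(out[nrow(out), -1], 0)
  structure(list(y = setNames(as.numeric(y), names(state$y)),
                 t = state$t + dt), class = "coag_state")
}

#' Film thrombin concentration seen by a platelet
#'
#' Free thrombin of the thin-film model for voxels inside the film mask;
#' zero elsewhere and zero when the patch carries no TF (thrombin is not
#' monitored outside the film).
#'
#' @param state a `coag_state`
#' @param domain a `lattice_domain`
#' @param voxel 1-based voxel index triple
#' @return thrombin concentration (nM)
#' @export
film_thrombin <- function(state, domain, voxel) {
  if (!domain$tf_on) return(0)
  if (domain$film_mask[voxel[1], voxel[2], voxel[3]]) state$y[["IIa"]] else 0
}
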