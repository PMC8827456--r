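# Closed-form platelet adhesion kinetics: shear-dependent capture enhancement
# E (VWF unfolding), Bell-type bond breakage G, and the four attachment /
# detachment rate laws combining integrin activation F with E and G.

#' Adhesion kinetic parameters
#'
#' Rate constants for platelet-collagen and platelet-platelet bond formation
#' and rupture. `gamma_c` and `gamma_c_prime` are the characteristic shear
#' rates of the breakage function; `vwf_enhancement_on = FALSE` disables the
#' high-shear capture enhancement (E = 1 everywhere) for ablation studies.
#' `G_continuous_variant = TRUE` replaces the high-shear branch of G with a
#' form continuous at 1000 1/s (see [breakage_G()]).
#'
#' Defaults are calibrated so that a resting platelet touching collagen is
#' captured within its near-wall residence time while resting platelet pairs
#' do not aggregate in the bulk; activated platelets bind two orders of
#' magnitude faster and detach slowly.
#'
#' @param k_att_collagen fully activated platelet-collagen attachment rate (1/s)
#' @param k_att_platelet fully activated platelet-platelet attachment rate (1/s)
#' @param k_det_collagen baseline platelet-collagen detachment rate (1/s)
#' @param k_det_platelet baseline platelet-platelet detachment rate (1/s)
#' @param gamma_c,gamma_c_prime characteristic breakage shear rates (1/s)
#' @param vwf_enhancement_on flag, shear enhancement active
#' @param G_continuous_variant flag, continuity-corrected breakage function
#' @return an `adhesion_params` list
#' @export
adhesion_params <- function(k_att_collagen = 2e5, k_att_platelet = 1e4,
                            k_det_collagen = 2e-7, k_det_platelet = 2e-3,
                            gamma_c = 1000, gamma_c_prime = 1700,
                            vwf_enhancement_on = TRUE,
                            G_continuous_variant = FALSE) {
  stopifnot(k_att_collagen > 0, k_att_platelet > 0, k_det_collagen > 0,
            k_det_platelet > 0, gamma_c > 0, gamma_c_prime > 0)
  structure(list(k_att_collagen = k_att_collagen,
                 k_att_platelet = k_att_platelet,
                 k_det_collagen = k_det_collagen,
                 k_det_platelet = k_det_platelet,
                 gamma_c = gamma_c, gamma_c_prime = gamma_c_prime,
                 vwf_enhancement_on = isTRUE(vwf_enhancement_on),
                 G_continuous_variant = isTRUE(G_continuous_variant)),
            class = "adhesion_params")
}

#' Shear-dependent adhesion enhancement E
#'
#' Piecewise-linear capture enhancement representing the recruitment of
#' VWF-mediated bonds as shear rises: 1 up to 3000 1/s, rising linearly to
#' 20 at 8000 1/s, and 20 beyond (VWF fully unfolded). With
#' `vwf_enhancement_on = FALSE` returns 1 everywhere.
#'
#' @param gamma local shear rate (1/s), vectorized
#' @param params an [adhesion_params()] object
#' @return dimensionless enhancement factor(s)
#' @export
shear_enhancement_E <- function(gamma, params = adhesion_params()) {
  if (any(gamma < 0)) stop("shear rate must be nonnegative")
  if (!params$vwf_enhancement_on) return(rep(1, length(gamma)))
  ifelse(gamma <= 3000, 1,
         ifelse(gamma <= 8000, 1 + 19 * (gamma - 3000) / 5000, 20))
}

#' Shear-dependent bond breakage G
#'
#' Bell-type exponential acceleration of bond rupture:
#' `exp(gamma/gamma_c)` up to 1000 1/s and
#' `exp(1000/gamma_c) * exp(gamma/gamma_c')` beyond. The printed high-shear
#' branch jumps by a factor `exp(1000/gamma_c')` at the breakpoint; with
#' `G_continuous_variant = TRUE` the second branch uses
#' `exp((gamma - 1000)/gamma_c')`, which is continuous at 1000 1/s.
#'
#' @inheritParams shear_enhancement_E
#' @return dimensionless breakage factor(s)
#' @export
breakage_G <- function(gamma, params = adhesion_params()) {
  if (any(gamma < 0)) stop("shear rate must be nonnegative")
  lo <- exp(gamma / params$gamma_c)
  hi <- if (params$G_continuous_variant)
    exp(1000 / params$gamma_c) * exp((gamma - 1000) / params$gamma_c_prime)
  else
    exp(1000 / params$gamma_c) * exp(gamma / params$gamma_c_prime)
  ifelse(gamma <= 1000, lo, hi)
}

#' Platelet-collagen attachment rate
#'
#' `k_att_collagen * F(xi) * F(xi_dt) * E(gamma)`.
#'
#' @param F_xi,F_xidt integrin activation factors of the platelet (from
#'   [hill_F()])
#' @param gamma local shear rate (1/s)
#' @param params an [adhesion_params()] object
#' @return attachment rate (1/s)
#' @export
attach_rate_collagen <- function(F_xi, F_xidt, gamma,
                                 params = adhesion_params()) {
  params$k_att_collagen * F_xi * F_xidt * shear_enhancement_E(gamma, params)
}

#' Platelet-platelet attachment rate
#'
#' Geometric mean of the two platelets' activation and enhancement factors:
#' `k_att_platelet * (F_xi_i F_xi_j F_xidt_i F_xidt_j E(g_i) E(g_j))^(1/2)`.
#'
#' @param F_i,F_j length-2 vectors `c(F_xi, F_xidt)` for the two platelets
#' @param gamma_i,gamma_j local shear rates around the two platelets (1/s)
#' @param params an [adhesion_params()] object
#' @return attachment rate (1/s)
#' @export
attach_rate_platelet <- function(F_i, F_j, gamma_i, gamma_j,
                                 params = adhesion_params()) {
  params$k_att_platelet *
    sqrt(F_i[1] * F_j[1] * F_i[2] * F_j[2] *
         shear_enhancement_E(gamma_i, params) *
         shear_enhancement_E(gamma_j, params))
}

#' Platelet-collagen detachment rate
#'
#' `k_det_collagen * F(xi)^-1 * F(xi_dt)^-1 * E(gamma)^-1 * G(gamma)`: the
#' inverse activation/enhancement factors count the bonds to be broken, G
#' accelerates rupture with shear.
#'
#' @inheritParams attach_rate_collagen
#' @return detachment rate (1/s)
#' @export
detach_rate_collagen <- function(F_xi, F_xidt, gamma,
                                 params = adhesion_params()) {
  if (any(F_xi <= 0) || any(F_xidt <= 0))
    stop("activation factors must be positive")
  params$k_det_collagen * breakage_G(gamma, params) /
    (F_xi * F_xidt * shear_enhancement_E(gamma, params))
}

#' Platelet-platelet detachment rate
#'
#' `k_det_platelet * (F_xi_i F_xi_j F_xidt_i F_xidt_j E_i E_j)^(-1/2) *
#' (G_i G_j)^(1/2)`.
#'
#' @inheritParams attach_rate_platelet
#' @return detachment rate (1/s)
#' @export
detach_rate_platelet <- function(F_i, F_j, gamma_i, gamma_j,
                                 params = adhesion_params()) {
  if (any(c(F_i, F_j) <= 0)) stop("activation factors must be positive")
  params$k_det_platelet *
    sqrt(breakage_G(gamma_i, params) * breakage_G(gamma_j, params)) /
    sqrt(F_i[1] * F_j[1] * F_i[2] * F_j[2] *
         shear_enhancement_E(gamma_i, params) *
         shear_enhancement_E(gamma_j, params))
}
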