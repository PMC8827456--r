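# Convection-diffusion-reaction transport of the soluble agonists ADP and
# TXA2 on the flow lattice: first-order upwind convection, central diffusion,
# per-platelet exponential release sources. Platelet-occupied voxels exchange
# species by diffusion only (clot interior is diffusion-dominated); walls are
# zero-flux; the inlet admits agonist-free blood and the outlet is
# zero-gradient outflow.
#
# Time integration is explicit (sub-stepped to the stability bound). When the
# stability bound would require more sub-steps than `max_explicit_substeps`
# (high-shear stenotic flows), the same upwind flux discretization is
# advanced by a dimensionally split backward-Euler step (tridiagonal solves
# per lattice line): unconditionally stable, conservative, and
# nonnegativity-preserving, at the cost of first-order temporal smearing.

#' Transport parameters
#'
#' @param D_ADP,D_TXA2 diffusivities (um^2/s)
#' @param M_ADP,M_TXA2 releasable amount per platelet (mol)
#' @param tau_ADP,tau_TXA2 release time constants (s)
#' @param EC50_ADP,EC50_TXA2 half-maximal concentrations (nM), used for
#'   EC50-normalized reporting to the signaling module
#' @param dt_fvm transport macro step (s)
#' @param max_explicit_substeps explicit sub-step budget per macro step before
#'   switching to the implicit update
#' @return a `transport_params` list
#' @export
transport_params <- function(D_ADP = 240, D_TXA2 = 210,
                             M_ADP = 2.4e-17, M_TXA2 = 6e-18,
                             tau_ADP = 5, tau_TXA2 = 10,
                             EC50_ADP = 500, EC50_TXA2 = 50,
                             dt_fvm = 0.5, max_explicit_substeps = 120) {
  stopifnot(D_ADP > 0, D_TXA2 > 0, tau_ADP > 0, tau_TXA2 > 0, dt_fvm > 0,
            M_ADP >= 0, M_TXA2 >= 0)
  structure(list(
    species = c("ADP", "TXA2"),
    D = c(ADP = D_ADP, TXA2 = D_TXA2),
    M = c(ADP = M_ADP, TXA2 = M_TXA2),
    tau = c(ADP = tau_ADP, TXA2 = tau_TXA2),
    EC50 = c(ADP = EC50_ADP, TXA2 = EC50_TXA2),
    dt_fvm = dt_fvm, max_explicit_substeps = max_explicit_substeps),
    class = "transport_params")
}

#' Initialize empty concentration fields
#'
#' @param domain a `lattice_domain`
#' @return `concentration_fields`: per-species 3D arrays (nM) and time
#' @export
concentration_fields <- function(domain) {
  z <- array(0, domain$shape)
  structure(list(C = list(ADP = z, TXA2 = z), t = 0),
            class = "concentration_fields")
}

#' Per-platelet agonist release rate
#'
#' Zero before the platelet's release trigger; afterwards the stored amount
#' M_j elutes exponentially: `R_j(t) = M_j / tau_j * exp((t_release - t) /
#' tau_j)` (mol/s into the host voxel). Released platelets keep releasing
#' while mobile (moving sources).
#'
#' @param platelet list with fields `release_triggered` and `t_release`
#'   (e.g. a `platelet_signal_state`)
#' @param species "ADP" or "TXA2"
#' @param t current time (s)
#' @param params a [transport_params()] object
#' @return release rate (mol/s)
#' @export
release_rate <- function(platelet, species, t, params = transport_params()) {
  species <- match.arg(species, params$species)
  if (!isTRUE(platelet$release_triggered) || is.na(platelet$t_release) ||
      t < platelet$t_release)
    return(0)
  M <- params$M[[species]]; tau <- params$tau[[species]]
  M / tau * exp((platelet$t_release - t) / tau)
}

# cell-kind codes for the solver: 0 fluid, 1 wall, 2 platelet-occupied
.cellkind <- function(domain, occupancy = NULL) {
  k <- array(0L, domain$shape)
  k[domain$wall_mask] <- 1L
  if (!is.null(occupancy)) k[occupancy & !domain$wall_mask] <- 2L
  k
}

#' Advance the agonist fields by one transport step
#'
#' @param fields a `concentration_fields` object
#' @param flow a `flow_field`
#' @param sources list of per-voxel volumetric source arrays (nM/s), one per
#'   species (missing species default to zero)
#' @param dt time step (s)
#' @param params a [transport_params()] object
#' @param domain the `lattice_domain`
#' @param occupancy logical array of platelet-occupied voxels or NULL
#' @param method "explicit" (sub-stepped upwind), "implicit" (split
#'   backward Euler), or "auto": explicit unless the stability bound would
#'   require more than `max_explicit_substeps` sub-steps
#' @return updated `concentration_fields`; attribute `mass_out` holds the
#'   per-species outlet efflux (nM um^3) of the step
#' @export
advance_transport <- function(fields, flow, sources = list(), dt,
                              params = transport_params(), domain,
                              occupancy = NULL,
                              method = c("auto", "explicit", "implicit")) {
  stopifnot(inherits(fields, "concentration_fields"))
  method <- match.arg(method)
  kind <- .cellkind(domain, occupancy)
  h <- domain$h_lkmc
  d <- domain$shape
  if (method == "auto") {
    nsub <- .explicit_substeps(flow, params, h, dt)
    method <- if (nsub > params$max_explicit_substeps) "implicit"
              else "explicit"
  }
  mass_out <- c(ADP = 0, TXA2 = 0)
  for (sp in params$species) {
    src <- sources[[sp]]
    if (is.null(src)) src <- array(0, d)
    out <- if (method == "implicit")
      adi_advance_cpp(as.vector(fields$C[[sp]]), as.vector(kind),
                      as.vector(flow$ux), as.vector(flow$uy),
                      as.vector(flow$uz), as.vector(src),
                      d[1], d[2], d[3], params$D[[sp]], h, dt)
    else
      fvm_advance_cpp(as.vector(fields$C[[sp]]), as.vector(kind),
                      as.vector(flow$ux), as.vector(flow$uy),
                      as.vector(flow$uz), as.vector(src),
                      d[1], d[2], d[3], params$D[[sp]], h, dt,
                      0.85, 2000000L)
    fields$C[[sp]] <- array(out$C, d)
    mass_out[[sp]] <- out$mass_out
  }
  fields$t <- fields$t + dt
  attr(fields, "mass_out") <- mass_out
  attr(fields, "method") <- method
  fields
}

#' Number of explicit sub-steps dt would require
#' @noRd
.explicit_substeps <- function(flow, params, h, dt) {
  umax <- max(abs(flow$ux) + abs(flow$uy) + abs(flow$uz))
  dt_sub <- 0.85 * min(h^2 / (6 * max(params$D)),
                       if (umax > 0) h / umax else Inf)
  ceiling(dt / dt_sub)
}

#' Sample agonist concentrations at a voxel
#'
#' @param fields a `concentration_fields` object
#' @param voxel 1-based voxel index triple `c(i, j, k)`
#' @param domain the `lattice_domain`
#' @param params a [transport_params()] object (for EC50 normalization)
#' @return list with `nM` and `ec50` (EC50-normalized) per-species vectors
#' @export
sample_agonists <- function(fields, voxel, domain,
                            params = transport_params()) {
  stopifnot(length(voxel) == 3)
  if (domain$wall_mask[voxel[1], voxel[2], voxel[3]])
    stop("cannot sample agonists at a wall voxel")
  conc <- vapply(params$species, function(sp)
    fields$C[[sp]][voxel[1], voxel[2], voxel[3]], numeric(1))
  list(nM = conc, ec50 = conc / params$EC50[params$species])
}
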