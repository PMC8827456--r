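# Lattice kinetic Monte Carlo over the platelet population. Single-voxel
# platelets with hard exclusion; motion rates combine the upwind projection
# of the local fluid velocity with lattice diffusion; attachment/detachment
# rates come from the adhesion module. The event loop itself runs in
# compiled code (kmc_advance_cpp); the R-level functions here expose the
# rate laws and the direct-KMC selection rule for testing and light use,
# plus inlet injection with a marginated (near-wall-enriched) concentration
# profile.

DIR_NAMES <- c("+x", "-x", "+y", "-y", "+z", "-z")
DIR_OFFSETS <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                        0, 0, 1, 0, 0, -1), nrow = 6, byrow = TRUE)

#' Directional motion rates of a mobile platelet
#'
#' Per lattice direction: `max(v . e, 0)/h + D/h^2` — the convective part
#' only along directions with a positive velocity projection, the diffusive
#' part isotropic. Moves into walls or occupied voxels get rate zero (when
#' `domain`/`occupancy` are supplied); the -x move across the inlet face is
#' blocked, the +x move across the outlet face represents washout.
#'
#' @param voxel 1-based voxel index triple of the platelet
#' @param flow a `flow_field` (local velocity lookup)
#' @param D_platelet platelet diffusivity (um^2/s)
#' @param h lattice spacing (um)
#' @param domain optional `lattice_domain` for wall blocking
#' @param occupancy optional logical array of occupied voxels
#' @return named vector of 6 rates (1/s)
#' @export
motion_rates <- function(voxel, flow, D_platelet, h, domain = NULL,
                         occupancy = NULL) {
  v <- c(flow$ux[voxel[1], voxel[2], voxel[3]],
         flow$uy[voxel[1], voxel[2], voxel[3]],
         flow$uz[voxel[1], voxel[2], voxel[3]])
  rates <- numeric(6)
  for (d in 1:6) {
    proj <- sum(v * DIR_OFFSETS[d, ])
    r <- max(proj, 0) / h + D_platelet / h^2
    tgt <- voxel + DIR_OFFSETS[d, ]
    if (!is.null(domain)) {
      dshape <- domain$shape
      if (tgt[1] < 1) r <- 0                       # inlet face blocked
      else if (tgt[1] > dshape[1]) r <- r          # outlet: washout allowed
      else if (any(tgt[2:3] < 1) || any(tgt[2:3] > dshape[2:3])) r <- 0
      else if (domain$wall_mask[tgt[1], tgt[2], tgt[3]]) r <- 0
      else if (!is.null(occupancy) && occupancy[tgt[1], tgt[2], tgt[3]]) r <- 0
    }
    rates[d] <- r
  }
  names(rates) <- DIR_NAMES
  rates
}

#' Direct (rejection-free) KMC event selection
#'
#' Selects event k with probability `rate_k / sum(rates)` and draws the
#' exponential waiting time `dt = -log(u)/sum(rates)`.
#'
#' @param rates nonnegative event rates (1/s)
#' @return list with `index` (or NA for a quiescent system), `dt` (s, Inf
#'   when quiescent) and `quiescent`
#' @export
select_event <- function(rates) {
  stopifnot(all(rates >= 0))
  lambda <- sum(rates)
  if (lambda <= 0)
    return(list(index = NA_integer_, dt = Inf, quiescent = TRUE))
  dt <- -log(runif(1)) / lambda
  idx <- findInterval(runif(1) * lambda, cumsum(rates),
                      left.open = TRUE) + 1L
  list(index = min(idx, length(rates)), dt = dt, quiescent = FALSE)
}

#' Create an empty platelet population
#' @return a `platelet_population`
#' @export
new_population <- function() {
  structure(list(id = integer(0), pos0 = integer(0), mobile = logical(0),
                 created_t = numeric(0), next_id = 1L),
            class = "platelet_population")
}

# linear 0-based voxel index from 1-based triples (matrix n x 3)
.lin0 <- function(trip, shape) {
  (trip[, 1] - 1L) + shape[1] * ((trip[, 2] - 1L) + shape[2] * (trip[, 3] - 1L))
}
.trip1 <- function(lin0, shape) {
  cbind(lin0 %% shape[1] + 1L,
        (lin0 %/% shape[1]) %% shape[2] + 1L,
        lin0 %/% (shape[1] * shape[2]) + 1L)
}

# occupancy code vector: -1 empty fluid, -2 solid, else 0-based platelet row
.occ_codes <- function(population, domain) {
  occ <- rep(-1L, prod(domain$shape))
  occ[as.vector(domain$wall_mask)] <- -2L
  if (length(population$id))
    occ[population$pos0 + 1L] <- seq_along(population$id) - 1L
  occ
}

#' Inject platelets at the inlet with a marginated concentration profile
#'
#' Poisson arrivals per inlet voxel with intensity `u_x * h^2 * c_local * dt`.
#' The local concentration is `mean_concentration` times an excess factor `w`
#' within `delta_m` of the wall, with the core factor renormalized so the
#' flux-weighted mean equals `mean_concentration`. Arrivals into occupied
#' voxels are discarded.
#'
#' @param population a `platelet_population`
#' @param domain a `lattice_domain`
#' @param flow a `flow_field`
#' @param mean_concentration platelet concentration (platelets/uL)
#' @param wall_excess list `(factor, delta)`: excess factor within `delta`
#'   (um) of the wall
#' @param dt injection interval (s)
#' @param t current time (s), recorded on new platelets
#' @return updated population; attribute `n_discarded` counts arrivals into
#'   occupied voxels
#' @export
inject_inlet <- function(population, domain, flow, mean_concentration,
                         wall_excess = list(factor = 3, delta = 5),
                         dt, t = 0) {
  stopifnot(dt > 0)
  shape <- domain$shape; h <- domain$h_lkmc
  fl <- domain$fluid_mask[1, , ]
  ux_in <- pmax(flow$ux[1, , ], 0)
  # wall distance in the inlet cross-section
  yc <- (seq_len(shape[2]) - 0.5) * h; zc <- (seq_len(shape[3]) - 0.5) * h
  if (domain$geometry_kind == "channel") {
    W <- shape[2] * h; H <- shape[3] * h
    dw <- outer(pmin(yc, W - yc), pmin(zc, H - zc), pmin)
  } else {
    R <- (domain$meta$inlet_diameter %||% domain$meta$diameter) / 2
    rr <- sqrt(outer((yc - R)^2, (zc - R)^2, `+`))
    dw <- pmax(R - rr, 0)
  }
  f <- matrix(1, shape[2], shape[3])
  wallband <- dw <= wall_excess$delta
  f[wallband] <- wall_excess$factor
  flux_wall <- sum(ux_in[fl & wallband])
  flux_core <- sum(ux_in[fl & !wallband])
  if (flux_core > 0) {
    f_core <- (flux_wall + flux_core - wall_excess$factor * flux_wall) /
      flux_core
    f[!wallband] <- max(f_core, 0)
  }
  conc_vox <- mean_concentration * 1e-9          # platelets per um^3
  lambda <- ux_in * h^2 * conc_vox * f * dt
  lambda[!fl] <- 0
  arrivals <- array(rpois(length(lambda), lambda), dim(lambda))
  n_disc <- 0L
  occ <- .occ_codes(population, domain)
  new_trip <- NULL
  idx <- which(arrivals > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    trip <- c(1L, idx[r, 1], idx[r, 2])
    lin <- .lin0(matrix(trip, 1), shape)
    # voxel holds at most one platelet: extra arrivals discarded
    n_here <- arrivals[idx[r, 1], idx[r, 2]]
    if (occ[lin + 1] == -1L) {
      new_trip <- rbind(new_trip, trip)
      occ[lin + 1] <- 0L  # occupied now
      n_disc <- n_disc + n_here - 1L
    } else n_disc <- n_disc + n_here
  }
  if (!is.null(new_trip)) {
    k <- nrow(new_trip)
    ids <- population$next_id + seq_len(k) - 1L
    population$id <- c(population$id, ids)
    population$pos0 <- c(population$pos0, .lin0(new_trip, shape))
    population$mobile <- c(population$mobile, rep(TRUE, k))
    population$created_t <- c(population$created_t, rep(t, k))
    population$next_id <- population$next_id + k
  }
  attr(population, "n_discarded") <- n_disc
  population
}

#' Advance the platelet population by rejection-free KMC
#'
#' Runs the compiled direct-KMC event loop (motion, attachment, detachment,
#' outlet washout) for `dt` seconds of simulated time at frozen flow, shear
#' and activation factors.
#'
#' @param population a `platelet_population`
#' @param domain a `lattice_domain`
#' @param flow a `flow_field`
#' @param gamma_around per-voxel effective shear array from [shear_around()]
#' @param F_xi,F_xidt per-platelet activation factors (aligned with the
#'   population rows)
#' @param adhesion an [adhesion_params()] object
#' @param D_platelet platelet diffusivity (um^2/s)
#' @param dt simulated duration (s)
#' @param max_events event budget (safety valve)
#' @param audit audit the incremental event table against a full rebuild
#' @return list: updated `population`, per-row `removed` flags already
#'   dropped, event counters, `audit_diff`, and per-platelet total rates
#' @export
kmc_advance <- function(population, domain, flow, gamma_around,
                        F_xi, F_xidt, adhesion = adhesion_params(),
                        D_platelet = 10, dt, max_events = 5e7,
                        audit = FALSE) {
  n <- length(population$id)
  shape <- domain$shape
  if (n == 0) {
    return(list(population = population, n_events = 0, n_removed = 0,
                n_attach = 0, n_detach = 0, n_moves = 0, n_cascade = 0,
                audit_diff = 0, rates = numeric(0), exited_ids = integer(0)))
  }
  stopifnot(length(F_xi) == n, length(F_xidt) == n)
  occ <- .occ_codes(population, domain)
  res <- kmc_advance_cpp(population$pos0, as.integer(population$mobile),
                         F_xi, F_xidt, occ,
                         as.integer(collagen_adjacent(domain)),
                         as.vector(flow$ux), as.vector(flow$uy),
                         as.vector(flow$uz), as.vector(gamma_around),
                         shape[1], shape[2], shape[3], domain$h_lkmc,
                         D_platelet, unclass(adhesion), dt, max_events,
                         audit)
  removed <- res$removed == 1L
  exited <- population$id[removed]
  keep <- !removed
  population$pos0 <- res$pos[keep]
  population$mobile <- res$mobile[keep] == 1L
  population$id <- population$id[keep]
  population$created_t <- population$created_t[keep]
  list(population = population, kept = keep,
       n_events = res$n_events, n_moves = res$n_moves,
       n_attach = res$n_attach, n_detach = res$n_detach,
       n_removed = res$n_removed, n_cascade = res$n_cascade,
       audit_diff = res$audit_diff, rates = res$rates[keep],
       exited_ids = exited)
}
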