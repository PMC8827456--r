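# Steady incompressible flow over the instantaneous platelet occupancy,
# solved with a D3Q19 BGK lattice Boltzmann scheme (half-way bounce-back on
# walls and bound platelets). Because the microfluidic regime is viscous
# (Re << 10), the solver runs at a small fixed lattice forcing amplitude and
# the resulting Stokes-linear field is rescaled to the requested boundary
# condition; compressibility error stays negligible at any physical driving.

#' Flow solver parameters
#'
#' @param rho blood density (kg/m^3)
#' @param mu blood dynamic viscosity (Pa s)
#' @param bc_kind "constant_shear_inlet" (prescribed inlet wall shear rate) or
#'   "constant_pressure_drop" (fixed total pressure drop inlet to outlet)
#' @param inlet_wall_shear inlet wall shear rate (1/s), for
#'   "constant_shear_inlet"
#' @param pressure_drop total pressure drop (Pa), for "constant_pressure_drop"
#' @param convergence_tol relative L-infinity velocity change per convergence
#'   check below which the solve is declared steady
#' @param max_iter maximum lattice sweeps
#' @return a `flow_params` list
#' @export
flow_params <- function(rho = 1060, mu = 3.5e-3,
                        bc_kind = c("constant_shear_inlet",
                                    "constant_pressure_drop"),
                        inlet_wall_shear = NULL, pressure_drop = NULL,
                        convergence_tol = 1e-6, max_iter = 40000) {
  bc_kind <- match.arg(bc_kind)
  stopifnot(rho > 0, mu > 0, convergence_tol > 0)
  if (bc_kind == "constant_shear_inlet" && is.null(inlet_wall_shear))
    stop("constant_shear_inlet requires inlet_wall_shear")
  if (bc_kind == "constant_pressure_drop" && is.null(pressure_drop))
    stop("constant_pressure_drop requires pressure_drop")
  structure(list(rho = rho, mu = mu, bc_kind = bc_kind,
                 inlet_wall_shear = inlet_wall_shear,
                 pressure_drop = pressure_drop,
                 convergence_tol = convergence_tol, max_iter = max_iter),
            class = "flow_params")
}

# inlet axial-velocity profile (um/s) over the x = 0 cross-section, from the
# analytic fully developed profile of the *unoccluded* inlet geometry
.inlet_profile <- function(domain, wall_shear) {
  d <- domain$shape; h <- domain$h_lkmc
  yc <- (seq_len(d[2]) - 0.5) * h
  zc <- (seq_len(d[3]) - 0.5) * h
  if (domain$geometry_kind == "channel") {
    W <- d[2] * h; H <- d[3] * h
    outer(yc, zc, function(y, z) duct_velocity(y, z, W, H, wall_shear))
  } else {
    R <- domain$meta$inlet_diameter %||% domain$meta$diameter
    R <- R / 2
    cc <- R
    rr <- sqrt(outer((yc - cc)^2, (zc - cc)^2, `+`))
    poiseuille_velocity(rr, R, wall_shear) * (rr <= R)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve steady flow over the current platelet occupancy
#'
#' @param domain a `lattice_domain`
#' @param occupancy logical 3D array of bound-platelet voxels (no-slip), or
#'   NULL for a platelet-free solve
#' @param params a [flow_params()] object
#' @param warm_start a previous `flow_field` on the same lattice to initialize
#'   from (speeds up quasi-steady re-solves)
#' @return a `flow_field`: velocity components `ux, uy, uz` (um/s, 3D arrays),
#'   `pressure` (Pa), `Q` (uL/min at the inlet), `converged`, `iterations`
#' @export
solve_flow <- function(domain, occupancy = NULL, params, warm_start = NULL) {
  stopifnot(inherits(domain, "lattice_domain"), inherits(params, "flow_params"))
  d <- domain$shape; h <- domain$h_lkmc; n <- prod(d)
  solid <- domain$wall_mask
  if (!is.null(occupancy)) solid <- solid | occupancy
  mask <- as.integer(solid)

  nu_phys <- params$mu / params$rho * 1e12   # um^2/s
  nu_lb <- 1 / 6; tau <- 3 * nu_lb + 0.5     # tau = 1: accurate wall placement
  # velocity conversion chosen so the lattice Mach number stays tiny
  # independent of the physical driving (Stokes-linear rescaling below);
  # compressibility error in Q scales with this amplitude
  u_scale_target <- 0.002                     # lattice velocity amplitude

  zeros <- numeric(n)
  init <- list(ux = zeros, uy = zeros, uz = zeros, rho = rep(1, n))

  if (params$bc_kind == "constant_shear_inlet") {
    prof <- .inlet_profile(domain, params$inlet_wall_shear)   # um/s, (ny,nz)
    umax_phys <- max(prof)
    if (umax_phys <= 0) stop("inlet profile is identically zero")
    C_u <- umax_phys / u_scale_target          # um/s per lattice unit
    inlet_ux <- as.vector(prof) / C_u
    # block inlet faces that are occluded by platelets at x = 1
    occ_in <- as.vector(solid[1, , ])
    inlet_ux[occ_in] <- 0
    # refuse to pump into a fully blocked domain: if no fluid path exists
    # from inlet to outlet, return a zero field
    if (!.has_fluid_path(solid)) {
      return(.zero_flow_field(domain, note = "occluded"))
    }
    if (!is.null(warm_start)) {
      init$ux <- as.vector(warm_start$ux) / C_u
      init$uy <- as.vector(warm_start$uy) / C_u
      init$uz <- as.vector(warm_start$uz) / C_u
    } else {
      # fully developed initial guess: replicate inlet profile downstream
      gx <- array(rep(as.vector(prof) / C_u, each = d[1]), d)
      gx[solid] <- 0
      init$ux <- as.vector(gx)
    }
    sol <- lb_solve_cpp(mask, d[1], d[2], d[3], tau, 1L, inlet_ux,
                        1, 1, params$max_iter, params$convergence_tol, 50L,
                        init$ux, init$uy, init$uz, init$rho)
    scale <- C_u
    p_unit <- params$rho * (C_u * 1e-6)^2      # Pa per lattice pressure unit
  } else {
    # pressure-drop BC: solve at a small trial density difference and rescale
    # the Stokes-linear solution to the requested physical drop
    drho_trial <- 1e-3
    dp_trial <- drho_trial / 3                  # lattice pressure units
    if (!is.null(warm_start) && !is.null(warm_start$lb_scale)) {
      s0 <- warm_start$lb_scale
      init$ux <- as.vector(warm_start$ux) / s0
      init$uy <- as.vector(warm_start$uy) / s0
      init$uz <- as.vector(warm_start$uz) / s0
    }
    sol <- lb_solve_cpp(mask, d[1], d[2], d[3], tau, 2L, numeric(d[2] * d[3]),
                        1 + drho_trial / 2, 1 - drho_trial / 2,
                        params$max_iter, params$convergence_tol, 50L,
                        init$ux, init$uy, init$uz, init$rho)
    # physical velocity scale: dt from viscosity matching, then linear
    # rescale so the applied lattice drop maps to the requested Pa drop
    dt_visc <- nu_lb * h^2 / nu_phys
    C_u0 <- h / dt_visc
    p_unit0 <- params$rho * (C_u0 * 1e-6)^2
    dp_trial_pa <- dp_trial * p_unit0
    scale <- C_u0 * (params$pressure_drop / dp_trial_pa)
    p_unit <- p_unit0 * (params$pressure_drop / dp_trial_pa)
  }

  ux <- array(sol$ux * scale, d); uy <- array(sol$uy * scale, d)
  uz <- array(sol$uz * scale, d)
  rho_l <- array(sol$rho, d)
  pressure <- (rho_l - 1) / 3 * p_unit
  ff <- structure(list(ux = ux, uy = uy, uz = uz, pressure = pressure,
                       converged = isTRUE(sol$converged),
                       iterations = sol$iterations,
                       lb_scale = scale, domain_shape = d, h = h,
                       bc_kind = params$bc_kind),
                  class = "flow_field")
  ff$Q <- flow_rate(ff, domain, station = 1L)
  if (!ff$converged)
    warning("flow solve did not reach tolerance after ", sol$iterations,
            " sweeps (relative change still above ", params$convergence_tol,
            ")")
  ff
}

.zero_flow_field <- function(domain, note = NULL) {
  d <- domain$shape
  z <- array(0, d)
  structure(list(ux = z, uy = z, uz = z, pressure = array(0, d),
                 converged = TRUE, iterations = 0L, lb_scale = 1,
                 domain_shape = d, h = domain$h_lkmc, Q = 0, note = note,
                 bc_kind = "constant_shear_inlet"),
            class = "flow_field")
}

# breadth-first check for a connected fluid path from inlet to outlet
.has_fluid_path <- function(solid) {
  d <- dim(solid)
  lab <- array(FALSE, d)
  frontier <- which(!solid[1, , , drop = FALSE])
  if (length(frontier) == 0) return(FALSE)
  lab[1, , ][!solid[1, , ]] <- TRUE
  repeat {
    grown <- FALSE
    for (axis in 1:3) for (dir in c(1, -1)) {
      sh <- .shift3(lab, axis, dir)
      new <- sh & !solid & !lab
      if (any(new)) { lab <- lab | new; grown <- TRUE }
    }
    if (!grown) break
  }
  any(lab[d[1], , ])
}

# shift a 3D logical array by one voxel along axis (dir = +1 shifts content
# toward higher indices); vacated slots FALSE
.shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
  else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field>\n")
  cat(sprintf("  lattice   : %d x %d x %d\n", x$domain_shape[1],
              x$domain_shape[2], x$domain_shape[3]))
  cat(sprintf("  Q         : %.4g uL/min\n", x$Q))
  cat(sprintf("  max |u|   : %.4g um/s\n",
              max(abs(x$ux), abs(x$uy), abs(x$uz))))
  cat(sprintf("  converged : %s (%d sweeps)\n", x$converged, x$iterations))
  invisible(x)
}

#' Local shear-rate magnitude field
#'
#' `gamma = sqrt(2 D:D)` from the central-difference strain-rate tensor, with
#' one-sided differences at fluid-solid interfaces (solid and wall voxels
#' carry zero velocity).
#'
#' @param flow a `flow_field`
#' @param domain the `lattice_domain` it was solved on
#' @return a `shear_field` with 3D array `gamma` (1/s)
#' @export
shear_magnitude <- function(flow, domain) {
  h <- domain$h_lkmc
  fluid <- domain$fluid_mask
  fl_num <- array(as.numeric(fluid), dim(fluid))
  # central differences in the interior; next to a solid voxel the one-sided
  # stencil places the no-slip wall at h/2 (half-way bounce-back) and fits a
  # quadratic through (wall, this voxel, far neighbour), exact for locally
  # parabolic profiles
  gradw <- function(u, axis) {
    d <- dim(u)
    up <- .shiftval(u, axis, +1); dn <- .shiftval(u, axis, -1)
    fup <- .shiftval(fl_num, axis, +1) > 0
    fdn <- .shiftval(fl_num, axis, -1) > 0
    if (axis == 1) {
      # inlet/outlet planes are open, not walls: replicate (zero-gradient)
      up[d[1], , ] <- u[d[1], , ]; fup[d[1], , ] <- fluid[d[1], , ]
      dn[1, , ] <- u[1, , ]; fdn[1, , ] <- fluid[1, , ]
    }
    g <- array(0, d)
    both <- fup & fdn
    g[both] <- (up[both] - dn[both]) / (2 * h)
    wd <- fup & !fdn   # wall below (negative side)
    g[wd] <- (up[wd] + 3 * u[wd]) / (3 * h)
    wu <- !fup & fdn   # wall above (positive side)
    g[wu] <- -(dn[wu] + 3 * u[wu]) / (3 * h)
    g
  }
  gxx <- gradw(flow$ux, 1); gxy <- gradw(flow$ux, 2); gxz <- gradw(flow$ux, 3)
  gyx <- gradw(flow$uy, 1); gyy <- gradw(flow$uy, 2); gyz <- gradw(flow$uy, 3)
  gzx <- gradw(flow$uz, 1); gzy <- gradw(flow$uz, 2); gzz <- gradw(flow$uz, 3)
  Dxy <- 0.5 * (gxy + gyx); Dxz <- 0.5 * (gxz + gzx); Dyz <- 0.5 * (gyz + gzy)
  g2 <- 2 * (gxx^2 + gyy^2 + gzz^2 + 2 * (Dxy^2 + Dxz^2 + Dyz^2))
  gamma <- sqrt(pmax(g2, 0))
  gamma[!fluid] <- 0
  structure(list(gamma = array(gamma, dim(flow$ux))), class = "shear_field")
}

# shift with zero fill (values)
.shiftval <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
  else { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Wall shear rate at the channel floor midline
#'
#' Quadratic one-sided extrapolation of du/dz to the z = 0 wall from the two
#' fluid voxels above it, at the spanwise midline.
#'
#' @param flow a `flow_field`
#' @param domain the channel `lattice_domain`
#' @param station axial voxel index (1-based); defaults to mid-length
#' @return wall shear rate (1/s)
#' @export
wall_shear_floor <- function(flow, domain, station = NULL) {
  d <- domain$shape; h <- domain$h_lkmc
  if (is.null(station)) station <- max(1L, d[1] %/% 2)
  jmid <- max(1L, d[2] %/% 2)
  u1 <- flow$ux[station, jmid, 1]; u2 <- flow$ux[station, jmid, 2]
  (9 * u1 - u2) / (3 * h)
}

#' Volumetric flow rate through a cross-section
#'
#' Surface integral of the axial velocity over the fluid voxels of the
#' cross-section at the given axial station.
#'
#' @param flow a `flow_field`
#' @param domain the `lattice_domain`
#' @param station axial voxel index, 1-based
#' @return flow rate (uL/min)
#' @export
flow_rate <- function(flow, domain, station = 1L) {
  d <- domain$shape
  if (station < 1 || station > d[1]) stop("station outside the domain")
  h <- domain$h_lkmc
  sum(flow$ux[station, , ][domain$fluid_mask[station, , ]]) * h^2 * 60 / 1e9
}

#' Throat wall shear rate of a stenosed tube
#'
#' Wall shear at the narrowest cross-section, measured from the shear field:
#' the median of the shear magnitude over wall-adjacent fluid voxels of the
#' stations nearest the minimum-lumen station. At the throat the wall shear
#' is axisymmetric, so the ring median is its robust location estimate:
#' voxelizing the curved wall scatters individual voxel values both ways
#' (oblique stencils under-read, staircase corners over-read) and a mean or
#' maximum inherits those artifacts.
#'
#' @param flow a `flow_field`
#' @param domain a stenosis `lattice_domain`
#' @param shear optional precomputed [shear_magnitude()] result
#' @param n_stations number of axial stations around the throat to pool
#' @return list: `gamma_w` (1/s), `station`, `r_eff` (um)
#' @export
throat_wall_shear <- function(flow, domain, shear = NULL, n_stations = 5) {
  h <- domain$h_lkmc
  if (is.null(shear)) shear <- shear_magnitude(flow, domain)
  A <- apply(domain$fluid_mask, 1, sum) * h^2
  station <- which.min(A)
  half <- n_stations %/% 2
  stations <- max(1, station - half):min(domain$shape[1], station + half)
  wall_adj <- .wall_adjacent(domain$fluid_mask)
  g <- unlist(lapply(stations, function(i)
    shear$gamma[i, , ][wall_adj[i, , ]]))
  list(gamma_w = stats::median(g), station = station,
       r_eff = sqrt(A[station] / pi))
}

#' Occlusion criterion
#'
#' TRUE when the flow rate has dropped strictly below `threshold` times its
#' initial value.
#'
#' @param Q current flow rate (uL/min)
#' @param Q0 initial flow rate (uL/min), must be positive
#' @param threshold occlusion fraction (default 0.05)
#' @return logical
#' @export
is_occluded <- function(Q, Q0, threshold = 0.05) {
  if (Q0 <= 0) stop("Q0 must be positive")
  Q < threshold * Q0
}

#' Effective shear rate around each voxel
#'
#' For adhesion kinetics the shear rate "around" a platelet is taken as the
#' maximum shear magnitude over its face-adjacent fluid voxels (a deposited
#' platelet itself sits in a zero-velocity voxel).
#'
#' @param shear a `shear_field`
#' @param domain the `lattice_domain`
#' @return 3D array of effective shear rates (1/s)
#' @export
shear_around <- function(shear, domain) {
  g <- shear$gamma
  fluid <- domain$fluid_mask
  gf <- g; gf[!fluid] <- 0
  out <- gf
  for (axis in 1:3) for (dir in c(1, -1)) {
    out <- pmax(out, .shiftval(gf, axis, dir))
  }
  array(out, dim(g))
}
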