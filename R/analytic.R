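# Closed-form laminar profiles used both to impose inlet boundary conditions
# and as independent oracles for the lattice Boltzmann solver.

#' Fully developed rectangular-duct axial velocity (series solution)
#'
#' Axial velocity of steady pressure-driven flow in a rectangular duct of
#' width `W` (y in [0, W]) and height `H` (z in [0, H]), evaluated at the
#' given points and normalized so that the wall shear rate at the floor
#' midline (y = W/2, z = 0) equals `wall_shear`.
#'
#' @param y,z coordinates (um), recycled against each other
#' @param W,H duct width and height (um)
#' @param wall_shear target wall shear rate at the floor midline (1/s)
#' @param nterms number of odd series terms
#' @return axial velocity (um/s) at the points
#' @export
duct_velocity <- function(y, z, W, H, wall_shear = 1, nterms = 60) {
  a <- W / 2; b <- H / 2
  yy <- y - a; zz <- z - b     # centered coordinates
  shape <- function(yy, zz) {
    u <- 0
    for (k in seq_len(nterms)) {
      n <- 2 * k - 1
      bn <- n * pi / (2 * b)
      # overflow-safe cosh(bn*yy)/cosh(bn*a) for |yy| <= a
      ratio <- exp(bn * (abs(yy) - a)) *
        (1 + exp(-2 * bn * abs(yy))) / (1 + exp(-2 * bn * a))
      u <- u + (-1)^((n - 1) / 2) / n^3 * (1 - ratio) * cos(bn * zz)
    }
    u
  }
  eps <- 1e-4 * b
  g0 <- (shape(0, -b + eps) - shape(0, -b)) / eps   # du/dz at floor midline
  wall_shear / g0 * shape(yy, zz)
}

#' Rectangular-duct volumetric flow rate for a floor-midline wall shear
#'
#' Numerically integrates the duct series solution over the cross-section.
#'
#' @inheritParams duct_velocity
#' @param ngrid quadrature points per dimension
#' @return flow rate in uL/min
#' @export
duct_flow_rate <- function(W, H, wall_shear, ngrid = 200, nterms = 60) {
  ys <- (seq_len(ngrid) - 0.5) * (W / ngrid)
  zs <- (seq_len(ngrid) - 0.5) * (H / ngrid)
  u <- outer(ys, zs, function(y, z) duct_velocity(y, z, W, H, wall_shear, nterms))
  sum(u) * (W / ngrid) * (H / ngrid) * 60 / 1e9
}

#' Poiseuille tube profile for a given wall shear rate
#'
#' `u(r) = (wall_shear * R / 2) * (1 - (r/R)^2)`; the corresponding flow rate
#' is `Q = pi * wall_shear * R^3 / 4`.
#'
#' @param r radial coordinate (um), may be a vector
#' @param R tube radius (um)
#' @param wall_shear wall shear rate (1/s)
#' @return axial velocity (um/s)
#' @export
poiseuille_velocity <- function(r, R, wall_shear) {
  pmax(wall_shear * R / 2 * (1 - (r / R)^2), 0)
}

#' Poiseuille tube flow rate (uL/min)
#' @inheritParams poiseuille_velocity
#' @export
poiseuille_flow_rate <- function(R, wall_shear) {
  pi * wall_shear * R^3 / 4 * 60 / 1e9
}
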