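# Voxelized simulation domains: rectangular channel, cylindrical tube, and
# stenosed tube, each with a reactive (collagen +/- tissue factor) patch and
# the thin-film coagulation zone above TF-bearing surface.
#
# Conventions: 0-based voxel indices in the solver kernels, 1-based R arrays;
# voxel centers at (i - 1/2) * h in physical coordinates; x is the flow
# direction (inlet at x = 0 face, outlet at x = L face); z is channel height;
# the tube/stenosis axis runs along x with the cross-section in (y, z).
# Solid voxels are marked in wall_mask; voxels beyond the array boundary are
# implicitly solid (the channel builder relies on this, so its array covers
# exactly the fluid extent). reactive_mask marks *fluid* voxels owning a
# wall-adjacent reactive face.

#' Lattice domain constructor (internal)
#'
#' @param fluid logical 3D array, TRUE for fluid voxels
#' @param reactive logical 3D array, TRUE for fluid voxels owning a reactive
#'   wall face
#' @param h lattice spacing (um)
#' @param tf_on logical, tissue factor present on the reactive patch
#' @param geometry_kind one of "channel", "tube", "stenosis"
#' @param film_thickness thin-film thickness (um)
#' @param meta list of builder arguments kept for reporting
#' @noRd
new_lattice_domain <- function(fluid, reactive, h, tf_on, geometry_kind,
                               film_thickness = 15, meta = list()) {
  stopifnot(is.array(fluid), length(dim(fluid)) == 3L)
  dom <- structure(list(
    shape = dim(fluid),
    h_lkmc = h,
    fluid_mask = fluid,
    wall_mask = !fluid,
    reactive_mask = reactive,
    tf_on = isTRUE(tf_on),
    film_mask = array(FALSE, dim(fluid)),
    film_thickness = film_thickness,
    inlet = "x-min", outlet = "x-max",
    geometry_kind = geometry_kind,
    meta = meta
  ), class = "lattice_domain")
  if (dom$tf_on && any(reactive)) {
    dom$film_mask <- compute_film_mask(dom, film_thickness)
  }
  dom
}

#' @export
print.lattice_domain <- function(x, ...) {
  cat(sprintf("<lattice_domain: %s>\n", x$geometry_kind))
  cat(sprintf("  shape   : %d x %d x %d voxels (h = %g um)\n",
              x$shape[1], x$shape[2], x$shape[3], x$h_lkmc))
  cat(sprintf("  fluid   : %d voxels (%.1f%%)\n", sum(x$fluid_mask),
              100 * mean(x$fluid_mask)))
  cat(sprintf("  reactive: %d voxel faces; TF %s; film %d voxels\n",
              sum(x$reactive_mask), if (x$tf_on) "on" else "off",
              sum(x$film_mask)))
  invisible(x)
}

#' Build a rectangular channel domain
#'
#' The channel occupies `length x width x height` (um) with flow along x. A
#' reactive patch (collagen, optionally coated with tissue factor) spans the
#' full width of the floor from `patch_start` to `patch_start + patch_length`.
#' Channel walls are the array boundary itself, so the voxel array covers
#' exactly the fluid interior.
#'
#' @param length,width,height channel dimensions (um)
#' @param patch_start axial position where the reactive patch begins (um)
#' @param patch_length axial extent of the reactive patch (um); 0 gives an
#'   inert channel
#' @param h lattice spacing (um)
#' @param tf_on does the patch carry tissue factor (enables the thin-film
#'   coagulation zone)?
#' @param film_thickness thin-film thickness (um)
#' @return a `lattice_domain`
#' @examples
#' dom <- build_channel(500, 250, 60, 125, 250, h = 2.5, tf_on = TRUE)
#' dom$shape  # 200 100 24
#' @export
build_channel <- function(length, width, height, patch_start, patch_length,
                          h = 2.5, tf_on = TRUE, film_thickness = 15) {
  stopifnot(length > 0, width > 0, height > 0, h > 0, patch_length >= 0)
  if (h > min(length, width, height))
    stop("lattice spacing h is larger than a domain dimension")
  if (patch_length > 0 &&
      (patch_start < 0 || patch_start + patch_length > length))
    stop("reactive patch [", patch_start, ", ", patch_start + patch_length,
         "] falls outside the channel floor [0, ", length, "]")
  nx <- round(length / h); ny <- round(width / h); nz <- round(height / h)
  if (max(abs(c(nx, ny, nz) * h - c(length, width, height))) > h)
    stop("h does not divide the channel dimensions to within one voxel")
  fluid <- array(TRUE, c(nx, ny, nz))
  reactive <- array(FALSE, c(nx, ny, nz))
  if (patch_length > 0) {
    xc <- (seq_len(nx) - 0.5) * h
    in_patch <- xc >= patch_start & xc < patch_start + patch_length
    reactive[in_patch, , 1] <- TRUE  # floor faces (z = 0 wall)
  }
  new_lattice_domain(fluid, reactive, h, tf_on, "channel", film_thickness,
                     meta = list(length = length, width = width,
                                 height = height, patch_start = patch_start,
                                 patch_length = patch_length))
}

# angular membership of a wall-adjacent voxel on the tube circumference:
# patch covers `arc_fraction` of the circumference centered at the bottom
# (-z), axially centered on the domain
.arc_member <- function(yc, zc, cy, cz, arc_fraction) {
  ang <- atan2(zc - cz, yc - cy)            # -pi..pi, bottom = -pi/2
  half <- arc_fraction * pi                  # half-arc in radians
  d <- abs(ang - (-pi / 2))
  d <- pmin(d, 2 * pi - d)
  d <= half + 1e-12
}

#' Build a cylindrical tube domain
#'
#' Straight tube of the given diameter with flow along x. The reactive patch
#' covers `patch_arc_fraction` of the circumference (0.5 = semicylindrical,
#' centered at the bottom of the tube), centered axially.
#'
#' @param length tube length (um)
#' @param diameter lumen diameter (um)
#' @param patch_arc_fraction fraction of the circumference covered by the
#'   reactive patch, in (0, 1]
#' @param patch_length axial extent of the patch (um)
#' @param h lattice spacing (um)
#' @param tf_on does the patch carry tissue factor?
#' @param film_thickness thin-film thickness (um)
#' @return a `lattice_domain`
#' @examples
#' dom <- build_tube(500, 60, 0.5, 250, h = 2.5, tf_on = TRUE)
#' @export
build_tube <- function(length, diameter, patch_arc_fraction, patch_length,
                       h = 2.5, tf_on = TRUE, film_thickness = 15) {
  stopifnot(length > 0, diameter > 0, patch_length >= 0)
  if (patch_arc_fraction <= 0 || patch_arc_fraction > 1)
    stop("patch_arc_fraction must lie in (0, 1]")
  if (diameter / h < 4)
    stop("lattice too coarse: fewer than 4 voxels across the tube diameter")
  nx <- round(length / h); nyz <- round(diameter / h)
  r <- diameter / 2; c_yz <- diameter / 2
  fluid <- array(FALSE, c(nx, nyz, nyz))
  yc <- (seq_len(nyz) - 0.5) * h
  rad2 <- outer((yc - c_yz)^2, (yc - c_yz)^2, `+`)    # (y, z) center distances
  circ <- rad2 <= r^2
  for (i in seq_len(nx)) fluid[i, , ] <- circ
  reactive <- array(FALSE, c(nx, nyz, nyz))
  if (patch_length > 0) {
    xc <- (seq_len(nx) - 0.5) * h
    ax <- abs(xc - length / 2) <= patch_length / 2
    wall_adj <- .wall_adjacent(fluid)
    arc <- outer(yc, yc, function(y, z)
      .arc_member(y, z, c_yz, c_yz, patch_arc_fraction))
    sel <- circ & arc
    for (i in which(ax)) reactive[i, , ] <- sel & wall_adj[i, , ]
  }
  new_lattice_domain(fluid, reactive, h, tf_on, "tube", film_thickness,
                     meta = list(length = length, diameter = diameter,
                                 patch_arc_fraction = patch_arc_fraction,
                                 patch_length = patch_length))
}

#' Build a stenosed tube domain
#'
#' Axisymmetric smooth narrowing (cosine bump) of a straight tube: inside the
#' stenotic segment of length `stenosis_length` centered axially, the lumen
#' radius is
#' `r(x) = r0 - (r0 - rt) * (1 + cos(2*pi*(x - x_mid)/L_s)) / 2`
#' with throat radius `rt = r0 * sqrt(1 - area_reduction)`. Collagen covers
#' `collagen_arc_fraction` of the circumference over the stenotic segment.
#'
#' @param length domain length (um)
#' @param inlet_diameter unstenosed lumen diameter (um)
#' @param stenosis_length axial extent of the narrowing (um)
#' @param area_reduction fractional reduction of lumen cross-sectional area at
#'   the throat, in [0, 1)
#' @param collagen_arc_fraction circumferential fraction coated with collagen
#' @param h lattice spacing (um)
#' @param tf_on does the collagen surface also carry tissue factor? Default
#'   FALSE (collagen-only stenosis).
#' @param film_thickness thin-film thickness (um)
#' @return a `lattice_domain`
#' @examples
#' dom <- build_stenosis(500, 60, 250, 0.75, 0.5, h = 2.5)
#' @export
build_stenosis <- function(length, inlet_diameter, stenosis_length,
                           area_reduction, collagen_arc_fraction = 0.5,
                           h = 2.5, tf_on = FALSE, film_thickness = 15) {
  stopifnot(length > 0, inlet_diameter > 0)
  if (area_reduction < 0 || area_reduction >= 1)
    stop("area_reduction must lie in [0, 1)")
  if (stenosis_length >= length)
    stop("stenosis_length must be smaller than the domain length")
  r0 <- inlet_diameter / 2
  rt <- r0 * sqrt(1 - area_reduction)
  if (rt / h < 1.5)
    stop("throat too narrow: fewer than 3 voxels across at the given h")
  nx <- round(length / h); nyz <- round(inlet_diameter / h)
  c_yz <- inlet_diameter / 2
  xc <- (seq_len(nx) - 0.5) * h
  x_mid <- length / 2
  rx <- rep(r0, nx)
  inside <- abs(xc - x_mid) <= stenosis_length / 2
  rx[inside] <- r0 - (r0 - rt) *
    0.5 * (1 + cos(2 * pi * (xc[inside] - x_mid) / stenosis_length))
  fluid <- array(FALSE, c(nx, nyz, nyz))
  yc <- (seq_len(nyz) - 0.5) * h
  rad2 <- outer((yc - c_yz)^2, (yc - c_yz)^2, `+`)
  for (i in seq_len(nx)) fluid[i, , ] <- rad2 <= rx[i]^2
  reactive <- array(FALSE, c(nx, nyz, nyz))
  wall_adj <- .wall_adjacent(fluid)
  arc <- outer(yc, yc, function(y, z)
    .arc_member(y, z, c_yz, c_yz, collagen_arc_fraction))
  for (i in which(inside)) reactive[i, , ] <- fluid[i, , ] & arc & wall_adj[i, , ]
  new_lattice_domain(fluid, reactive, h, tf_on, "stenosis", film_thickness,
                     meta = list(length = length,
                                 inlet_diameter = inlet_diameter,
                                 stenosis_length = stenosis_length,
                                 area_reduction = area_reduction,
                                 collagen_arc_fraction = collagen_arc_fraction,
                                 radius_profile = rx))
}

# fluid voxels with at least one face-adjacent solid voxel or domain boundary
.wall_adjacent <- function(fluid) {
  d <- dim(fluid)
  solid <- !fluid
  adj <- array(FALSE, d)
  pad <- function(arr, axis, dir) {
    # shift solid mask by one voxel; outside counts as solid
    out <- array(TRUE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (dir > 0) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
    else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3) for (dir in c(1, -1)) {
    if (axis == 1) next  # x faces are inlet/outlet, not walls
    adj <- adj | pad(solid, axis, dir)
  }
  adj & fluid
}

#' Thin-film coagulation mask
#'
#' Fluid voxels whose minimal within-fluid distance to a TF-bearing reactive
#' face is at most `thickness`. Distances are measured from voxel center to
#' the wall face (the fluid voxel owning a reactive face sits h/2 from it) by
#' a 26-neighbour chamfer transform, which cannot leak through walls.
#'
#' @param domain a `lattice_domain` with a reactive patch
#' @param thickness film thickness (um); 0 gives an empty mask
#' @return logical 3D array over voxels
#' @export
compute_film_mask <- function(domain, thickness) {
  stopifnot(inherits(domain, "lattice_domain"), thickness >= 0)
  if (!any(domain$reactive_mask) || thickness <= 0)
    return(array(FALSE, domain$shape))
  d <- chamfer_dist_cpp(as.integer(domain$reactive_mask),
                        as.integer(domain$fluid_mask),
                        domain$shape[1], domain$shape[2], domain$shape[3],
                        domain$h_lkmc)
  array(is.finite(d) & d <= thickness, domain$shape) & domain$fluid_mask
}

# per-voxel flag: fluid voxel with a face-adjacent reactive face (collagen
# contactable). reactive_mask already marks such fluid voxels.
collagen_adjacent <- function(domain) domain$reactive_mask
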