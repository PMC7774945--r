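.geom_args <- function(dims, spacing, geometry, angles_deg = NULL) {
  list(dims = as.integer(dims), spacing = as.numeric(spacing),
       sid = geometry$sid, sdd = geometry$sdd,
       angles = (if (is.null(angles_deg)) geometry$angles_deg else
         angles_deg) * pi / 180,
       nu = geometry$detector_shape[1], nv = geometry$detector_shape[2],
       pitch = geometry$pitch)
}

#' Forward projection of a phantom at one energy
#'
#' Computes, for every view and detector pixel, the line integral of the
#' linear attenuation coefficient along the source-to-pixel ray
#' (exact Siddon voxel traversal), i.e. the noiseless log-attenuation
#' projection. Air-only rays give exactly 0.
#'
#' @param phantom a [voxel_phantom()].
#' @param geometry an [acquisition_geometry()].
#' @param energy_kev photon energy in keV (within the attenuation-table
#'   range).
#' @return a [projection_stack()] tagged with the energy.
#' @export
forward_project <- function(phantom, geometry, energy_kev) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(geometry, "acquisition_geometry"))
  mu <- phantom_mu(phantom, energy_kev)
  a <- .geom_args(dim(mu), phantom$spacing, geometry)
  p <- cpp_forward_project(as.numeric(mu), a$dims, a$spacing, a$sid, a$sdd,
                           a$angles, a$nu, a$nv, a$pitch)
  dim(p) <- c(a$nu, a$nv, length(a$angles))
  projection_stack(p, geometry, sprintf("mono(%g keV)", energy_kev),
                   energy_kev)
}

#' Matter path length projection
#'
#' Line integrals (cm) of the matter indicator (voxels whose fractions sum
#' to 1). This is the total path length through matter per ray — the exact
#' volume-conservation closure for three-material decomposition (see
#' [decompose()]).
#'
#' @inheritParams forward_project
#' @return a [projection_stack()] of path lengths in cm, tagged
#'   `"path-length"`.
#' @export
project_path_length <- function(phantom, geometry) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  ind <- phantom$frac$bone + phantom$frac$soft + phantom$frac$nodule
  a <- .geom_args(dim(ind), phantom$spacing, geometry)
  p <- cpp_forward_project(as.numeric(ind), a$dims, a$spacing, a$sid, a$sdd,
                           a$angles, a$nu, a$nv, a$pitch)
  dim(p) <- c(a$nu, a$nv, length(a$angles))
  projection_stack(p, geometry, "path-length", NA_real_)
}

#' Simulate a dual-energy acquisition
#'
#' Forward-projects the phantom at two effective monochromatic energies
#' (pulsed low/high-kVp acquisition idealised as two effective energies) and
#' optionally adds photon-counting noise: line integrals g are converted to
#' transmitted counts `N0 * exp(-g)`, Poisson-perturbed with the given seed,
#' and converted back (zero counts are floored at half a count).
#'
#' @param phantom a [voxel_phantom()].
#' @param geometry an [acquisition_geometry()].
#' @param low_kev,high_kev effective beam energies, keV (`low_kev < high_kev`;
#'   defaults 40 and 70 for the 60/120 kVp pair).
#' @param n0 incident photon count per detector pixel, or `NULL` for a
#'   noiseless simulation.
#' @param seed integer seed (identical seeds reproduce identical stacks).
#' @return list with elements `low` and `high`, both [projection_stack()]s.
#' @export
simulate_dual_energy <- function(phantom, geometry, low_kev = 40,
                                 high_kev = 70, n0 = NULL, seed = 1L) {
  if (!(low_kev < high_kev)) stop("low_kev must be less than high_kev")
  low <- forward_project(phantom, geometry, low_kev)
  high <- forward_project(phantom, geometry, high_kev)
  low$energy_tag <- "low-kV"; high$energy_tag <- "high-kV"
  if (!is.null(n0)) {
    if (n0 <= 0) stop("n0 must be positive")
    .with_seed(seed, {
      for (nm in c("low", "high")) {
        st <- get(nm)
        counts <- stats::rpois(length(st$frames), n0 * exp(-st$frames))
        counts[counts == 0] <- 0.5
        st$frames <- array(-log(counts / n0), dim = dim(st$frames))
        assign(nm, st)
      }
    })
  }
  list(low = low, high = high)
}

#' Length-weighted backprojection
#'
#' The exact adjoint of the forward projector: accumulates
#' `num[j] = sum_i a_ij * value_i` and `den[j] = sum_i a_ij` over the given
#' views, with `a_ij` the ray-voxel intersection lengths (cm).
#'
#' @param values array `c(nu, nv, n_views_sel)` of per-ray values.
#' @param grid a [recon_grid()] describing the output volume.
#' @param geometry an [acquisition_geometry()].
#' @param angles_deg view angles to backproject (default: all geometry
#'   angles; `values` must have matching view count).
#' @return list of two 3D arrays, `num` and `den`.
#' @export
backproject <- function(values, grid, geometry, angles_deg = NULL) {
  a <- .geom_args(grid$shape, grid$spacing, geometry, angles_deg)
  stopifnot(length(values) == a$nu * a$nv * length(a$angles))
  bp <- cpp_backproject(as.numeric(values), a$dims, a$spacing, a$sid, a$sdd,
                        a$angles, a$nu, a$nv, a$pitch)
  list(num = array(bp$num, grid$shape), den = array(bp$den, grid$shape))
}

# forward projection of a bare volume array on a recon grid (internal)
.project_volume <- function(vol, grid, geometry, angles_deg = NULL) {
  a <- .geom_args(grid$shape, grid$spacing, geometry, angles_deg)
  p <- cpp_forward_project(as.numeric(vol), a$dims, a$spacing, a$sid, a$sdd,
                           a$angles, a$nu, a$nv, a$pitch)
  dim(p) <- c(a$nu, a$nv, length(a$angles))
  p
}

# per-ray chord length through the grid box (cm) for given views (internal)
.chord_lengths <- function(grid, geometry, angles_deg = NULL) {
  a <- .geom_args(grid$shape, grid$spacing, geometry, angles_deg)
  ch <- cpp_chord_length(a$dims, a$spacing, a$sid, a$sdd, a$angles,
                         a$nu, a$nv, a$pitch)
  dim(ch) <- c(a$nu, a$nv, length(a$angles))
  ch
}
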