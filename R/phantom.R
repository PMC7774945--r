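#' Voxel phantom container
#'
#' A labelled 3D grid of material-fraction triples. `frac` is a named list of
#' three congruent 3D arrays (`bone`, `soft`, `nodule`); every voxel triple
#' lies in \[0,1\]^3 and sums to exactly 1 (tissue) or 0 (air). Axis
#' convention: dim 1 = x (tube sweep direction), dim 2 = y (in-plane,
#' orthogonal to the sweep), dim 3 = z (beam axis, source at +z); the volume
#' is centred on the isocenter.
#'
#' @param frac named list of three 3D fraction arrays (bone, soft, nodule).
#' @param spacing voxel edge lengths in mm, length 1 or 3.
#' @param materials three [material_spec()] records in the fixed order
#'   bone, soft, nodule (default [attenuation_basis()]).
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(frac, spacing, materials = attenuation_basis()) {
  stopifnot(is.list(frac), identical(names(frac), c("bone", "soft", "nodule")))
  d <- dim(frac$bone)
  stopifnot(length(d) == 3L, identical(d, dim(frac$soft)),
            identical(d, dim(frac$nodule)))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  stopifnot(all(spacing > 0))
  s <- frac$bone + frac$soft + frac$nodule
  bad <- abs(s) > 1e-12 & abs(s - 1) > 1e-12
  if (any(bad))
    stop("fraction closure violated: per-voxel sums must be exactly 0 or 1")
  structure(list(frac = frac, spacing = spacing, materials = materials),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$frac$bone)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  for (m in names(x$frac))
    cat(sprintf("  %-7s %8d voxels with fraction > 0\n", m,
                sum(x$frac[[m]] > 0)))
  invisible(x)
}

#' @export
dim.voxel_phantom <- function(x) dim(x$frac$bone)

# voxel-centre coordinate vectors (mm), isocenter at the volume centre
.axis_coords <- function(n, spacing) (seq_len(n) - 0.5 - n / 2) * spacing

# run expr with a temporarily-seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic chest phantom
#'
#' Builds a parametric three-material digital chest phantom: an elliptical
#' soft-tissue thorax (cylinder along the sweep axis x), two air-filled lung
#' cavities, circumferential rib-like bone arcs spaced along x (these provoke
#' the limited-angle ripple artifacts), branching soft-tissue vessel cylinders
#' inside the lungs, and spherical low-density nodules with nodule fraction 1.
#' Air voxels carry fraction (0,0,0); every tissue voxel sums to exactly 1.
#'
#' @param grid_shape voxel counts, length 3 (default `c(128, 128, 128)`).
#' @param spacing voxel size in mm (default 2).
#' @param nodules list of nodules, each `list(center = c(x,y,z) mm,
#'   diameter = mm)`; positions are relative to the isocenter. The default
#'   places one 5 mm nodule in the mid-right lung on the isocenter plane.
#' @param seed integer seed controlling the randomised vessel tree.
#' @param materials attenuation basis (see [attenuation_basis()]).
#' @return a [voxel_phantom()].
#' @export
make_chest_phantom <- function(grid_shape = c(128, 128, 128), spacing = 2,
                               nodules = list(list(center = c(18, 40, 0),
                                                   diameter = 5)),
                               seed = 1L,
                               materials = attenuation_basis()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  xs <- .axis_coords(nx, spacing[1])
  ys <- .axis_coords(ny, spacing[2])
  zs <- .axis_coords(nz, spacing[3])
  ext <- grid_shape * spacing

  # thorax: elliptical cylinder along x, cross-section in (y, z)
  ay <- 0.42 * ext[2]; az <- 0.33 * ext[3]
  Y <- array(rep(ys, each = nx), dim = grid_shape)
  Z <- array(rep(zs, each = nx * ny), dim = grid_shape)
  r2_thorax <- (Y / ay)^2 + (Z / az)^2
  body <- r2_thorax <= 1

  # two lung cavities: elliptical cylinders along x, trimmed at the apices
  X <- array(xs, dim = grid_shape)
  lung_ay <- 0.36 * ay; lung_az <- 0.62 * az
  lung_cy <- 0.47 * ay
  x_half <- 0.40 * ext[1]
  lungR <- (((Y - lung_cy) / lung_ay)^2 + (Z / lung_az)^2 <= 1) &
    (abs(X) <= x_half)
  lungL <- (((Y + lung_cy) / lung_ay)^2 + (Z / lung_az)^2 <= 1) &
    (abs(X) <= x_half)
  lung <- (lungR | lungL) & body

  # rib arcs: elliptical-annulus shell near the thorax boundary, in periodic
  # bands along x (the sweep axis) so their shadows ripple along the sweep
  shell <- r2_thorax >= 0.80^2 & r2_thorax <= 0.92^2 & body
  rib_period <- 24; rib_width <- 8  # mm
  bands <- (((X + ext[1] / 2) %% rib_period) < rib_width) & (abs(X) <= x_half)
  ribs <- shell & bands

  bone <- array(0, grid_shape); soft <- array(0, grid_shape)
  nod <- array(0, grid_shape)
  soft[body] <- 1
  soft[lung] <- 0                 # lung field is air
  bone[ribs] <- 1; soft[ribs] <- 0

  # branching vessels: straight soft-tissue cylinders radiating from each hilum
  vess <- .with_seed(seed, {
    v <- array(FALSE, grid_shape)
    for (side in c(1, -1)) {
      hil <- c(0, side * lung_cy * 0.55, 0)
      n_br <- 6L
      for (b in seq_len(n_br)) {
        dir <- c(stats::runif(1, -1, 1), side * stats::runif(1, 0.2, 1),
                 stats::runif(1, -0.6, 0.6))
        dir <- dir / sqrt(sum(dir^2))
        len <- stats::runif(1, 0.45, 0.95) * lung_ay * 2
        rad <- stats::runif(1, 2.2, 4.5)  # mm
        # distance from each voxel centre to the segment hil + t*dir, t in [0,len]
        PX <- X - hil[1]; PY <- Y - hil[2]; PZ <- Z - hil[3]
        t <- pmin(pmax(PX * dir[1] + PY * dir[2] + PZ * dir[3], 0), len)
        d2 <- (PX - t * dir[1])^2 + (PY - t * dir[2])^2 + (PZ - t * dir[3])^2
        v <- v | (d2 <= rad^2)
      }
    }
    v
  })
  soft[vess & lung & !ribs] <- 1

  # nodule spheres (fraction 1 inside); reject centres outside the grid
  half <- ext / 2
  for (i in seq_along(nodules)) {
    nd <- nodules[[i]]
    ctr <- as.numeric(nd$center); dia <- as.numeric(nd$diameter)
    if (any(abs(ctr) + dia / 2 > half))
      stop(sprintf("nodule %d (centre %g, %g, %g mm; diameter %g mm) lies outside the grid",
                   i, ctr[1], ctr[2], ctr[3], dia))
    inside <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= (dia / 2)^2
    nod[inside] <- 1
    soft[inside] <- 0; bone[inside] <- 0
  }

  voxel_phantom(list(bone = bone, soft = soft, nodule = nod),
                spacing, materials)
}

#' Uniform water phantom
#'
#' A rectangular uniform block of water-equivalent material (soft-tissue basis
#' at density 1.0 g/cm^3) with the requested physical extents, centred in and
#' clipped to the grid. The default extents are the full-scale uniform phantom
#' (x 300 mm, y 200 mm, z 450 mm); pass `extent_mm = NULL` to fill the whole
#' grid.
#'
#' @param grid_shape voxel counts, length 3.
#' @param spacing voxel size in mm (length 1 or 3).
#' @param extent_mm physical block extents in mm (length 3), or `NULL` for a
#'   grid-filling block.
#' @param materials attenuation basis; the soft-tissue record is re-used at
#'   density 1.0 for water.
#' @return a [voxel_phantom()] with all matter in the `soft` channel.
#' @export
make_water_phantom <- function(grid_shape, spacing,
                               extent_mm = c(300, 200, 450),
                               materials = attenuation_basis()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  ext <- grid_shape * spacing
  if (is.null(extent_mm)) extent_mm <- ext
  extent_mm <- pmin(rep(as.numeric(extent_mm), length.out = 3L), ext)
  soft <- array(0, grid_shape)
  inside <- rep(TRUE, prod(grid_shape))
  dim(inside) <- grid_shape
  for (ax in 1:3) {
    co <- .axis_coords(grid_shape[ax], spacing[ax])
    keep <- abs(co) <= extent_mm[ax] / 2
    perm <- array(rep(keep, each = prod(grid_shape[seq_len(ax - 1)])),
                  dim = grid_shape)
    inside <- inside & perm
  }
  soft[inside] <- 1
  mats <- materials
  mats$soft <- material_spec("water", 1.0, mats$soft$energies_kev,
                             mats$soft$mu_rho)
  voxel_phantom(list(bone = array(0, grid_shape), soft = soft,
                     nodule = array(0, grid_shape)),
                spacing, mats)
}

#' Linear-attenuation volume of a phantom at one energy
#'
#' @param phantom a [voxel_phantom()].
#' @param energy_kev photon energy in keV.
#' @return 3D array of linear attenuation coefficients (1/cm).
#' @export
phantom_mu <- function(phantom, energy_kev) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  m <- phantom$materials
  phantom$frac$bone * linear_attenuation(m$bone, energy_kev) +
    phantom$frac$soft * linear_attenuation(m$soft, energy_kev) +
    phantom$frac$nodule * linear_attenuation(m$nodule, energy_kev)
}
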