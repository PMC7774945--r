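#' Linear-sweep acquisition geometry
#'
#' Isocentric linear tomosynthesis: the source translates along a line at
#' height `sid` above the isocenter (positions `sid * tan(theta)` for view
#' angles `theta` spanning the swing angle symmetrically), the detector is
#' stationary below the isocenter. Two profiles are built in:
#' `"desk"` (21 views, 256^2 detector at 1.6 mm pitch — minutes-scale runs)
#' and `"full"` (37 views, 1024^2 detector — the full-scale system:
#' source-to-isocenter 924 mm, source-to-detector 1100 mm, 40 degree swing).
#'
#' @param profile `"desk"` or `"full"`; individual arguments override the
#'   profile values.
#' @param sid source-to-isocenter distance, mm.
#' @param sdd source-to-detector distance, mm (> sid).
#' @param swing_deg total swing angle, degrees, in (0, 180).
#' @param n_views number of views (>= 2).
#' @param detector_shape pixel counts `c(nu, nv)`.
#' @param pitch detector pixel pitch, mm.
#' @param sweep_axis in-plane axis of tube travel (only `"x"` is implemented).
#' @return an object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(profile = c("desk", "full"),
                                 sid = NULL, sdd = NULL, swing_deg = NULL,
                                 n_views = NULL, detector_shape = NULL,
                                 pitch = NULL, sweep_axis = "x") {
  profile <- match.arg(profile)
  def <- if (profile == "desk") {
    list(sid = 924, sdd = 1100, swing_deg = 40, n_views = 21L,
         detector_shape = c(256L, 256L), pitch = 1.6)
  } else {
    list(sid = 924, sdd = 1100, swing_deg = 40, n_views = 37L,
         detector_shape = c(1024L, 1024L), pitch = 0.28)
  }
  g <- list(
    sid = if (is.null(sid)) def$sid else sid,
    sdd = if (is.null(sdd)) def$sdd else sdd,
    swing_deg = if (is.null(swing_deg)) def$swing_deg else swing_deg,
    n_views = as.integer(if (is.null(n_views)) def$n_views else n_views),
    detector_shape = as.integer(if (is.null(detector_shape))
      def$detector_shape else rep(detector_shape, length.out = 2L)),
    pitch = if (is.null(pitch)) def$pitch else pitch,
    sweep_axis = sweep_axis)
  if (!(g$sdd > g$sid && g$sid > 0))
    stop("require sdd > sid > 0")
  if (g$n_views < 2L) stop("n_views must be >= 2")
  if (g$swing_deg <= 0 || g$swing_deg >= 180)
    stop("swing angle must lie in (0, 180) degrees")
  if (!identical(sweep_axis, "x"))
    stop("only sweep_axis = 'x' is implemented")
  g$angles_deg <- seq(-g$swing_deg / 2, g$swing_deg / 2,
                      length.out = g$n_views)
  class(g) <- "acquisition_geometry"
  g
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> sid %g mm, sdd %g mm, swing %g deg, %d views\n",
    x$sid, x$sdd, x$swing_deg, x$n_views))
  cat(sprintf("  detector %d x %d px @ %g mm pitch, sweep along %s\n",
              x$detector_shape[1], x$detector_shape[2], x$pitch,
              x$sweep_axis))
  invisible(x)
}

#' Projection stack container
#'
#' Ordered 2D detector frames of line-integral values (dimensionless
#' attenuation, i.e. -ln of relative transmitted intensity), with per-view
#' angles, an energy tag and the acquisition geometry. Frame array dims are
#' `c(nu, nv, n_views)` with dim 1 along the sweep axis.
#'
#' @param frames numeric array `c(nu, nv, n_views)`; all values finite.
#' @param geometry an [acquisition_geometry()].
#' @param energy_tag one of `"low-kV"`, `"high-kV"` or `"VM(<keV> keV)"`
#'   style tags; any single string is accepted.
#' @param energy_kev effective photon energy of the frames, keV (may be `NA`).
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(frames, geometry, energy_tag = "low-kV",
                             energy_kev = NA_real_) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  d <- dim(frames)
  if (length(d) != 3L)
    stop("frames must be a 3D array [nu, nv, n_views]")
  if (d[3] != geometry$n_views)
    stop("frame count must equal geometry$n_views")
  if (!all(is.finite(frames))) stop("frames must be finite")
  structure(list(frames = frames, geometry = geometry,
                 energy_tag = energy_tag, energy_kev = energy_kev),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<projection_stack> %s: %d frames of %d x %d px, range [%.4g, %.4g]\n",
              x$energy_tag, d[3], d[1], d[2], min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.projection_stack <- function(x) dim(x$frames)
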