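#' Reconstruction grid specification
#'
#' @param shape voxel counts `c(nx, ny, nz)` (dim 3 = slice/beam axis).
#' @param spacing voxel sizes mm: in-plane pixel size (dims 1-2) and slice
#'   increment (dim 3); length 1 or 3.
#' @return an object of class `recon_grid`.
#' @export
recon_grid <- function(shape, spacing) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  stopifnot(all(spacing > 0))
  structure(list(shape = shape, spacing = spacing), class = "recon_grid")
}

#' Reconstructed volume container
#'
#' @param values 3D array of attenuation values (finite).
#' @param grid the [recon_grid()] the volume lives on.
#' @param geometry the [acquisition_geometry()] it was reconstructed from
#'   (may be `NULL` for derived volumes).
#' @param log optional per-iteration data frame (iteration, rmse, tv,
#'   residual).
#' @return an object of class `recon_volume`.
#' @export
recon_volume <- function(values, grid, geometry = NULL, log = NULL) {
  stopifnot(inherits(grid, "recon_grid"),
            identical(dim(values), as.integer(grid$shape)))
  if (!all(is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, grid = grid, geometry = geometry,
                 log = log), class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- x$grid$shape
  cat(sprintf("<recon_volume> %d x %d x %d @ (%g, %g, %g) mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$grid$spacing[1], x$grid$spacing[2],
              x$grid$spacing[3], min(x$values), max(x$values)))
  if (!is.null(x$log))
    cat(sprintf("  %d logged iterations, final inter-iterate RMSE %.3g\n",
                nrow(x$log), x$log$rmse[nrow(x$log)]))
  invisible(x)
}

#' In-focus plane of a reconstructed volume
#'
#' The slice through the isocenter (centre of rotation), where features at
#' the isocenter plane are sharpest in linear tomosynthesis.
#'
#' @param volume a [recon_volume()].
#' @return 2D matrix (dim 1 along the sweep axis).
#' @export
in_focus_plane <- function(volume) {
  stopifnot(inherits(volume, "recon_volume"))
  k <- (volume$grid$shape[3] + 1L) %/% 2L
  volume$values[, , k]
}

# ---- FBP --------------------------------------------------------------------

#' Discrete Ram-Lak ramp-filter kernel
#'
#' Spatial-domain taps of the band-limited ramp filter for sample spacing
#' `pitch`: `h[0] = 1/(4 pitch^2)`, `h[n] = -1/(pi n pitch)^2` for odd n and
#' 0 for even nonzero n.
#'
#' @param n half-width: taps are returned for offsets `-n ... n`.
#' @param pitch detector sample spacing, mm.
#' @return numeric vector of length `2n + 1`.
#' @export
ramp_kernel <- function(n, pitch = 1) {
  off <- -n:n
  h <- numeric(2L * n + 1L)
  h[off == 0] <- 1 / (4 * pitch^2)
  odd <- off %% 2L != 0L
  h[odd] <- -1 / (pi * off[odd] * pitch)^2
  h
}

# convolve each column of m (detector rows along the sweep axis) with the
# ramp kernel, linear convolution via zero-padded FFT
.ramp_filter_rows <- function(m, pitch) {
  nu <- nrow(m)
  h <- ramp_kernel(nu - 1L, pitch)
  nfft <- 2^ceiling(log2(2 * nu))
  hp <- numeric(nfft)
  hp[1:(2 * nu - 1)] <- h
  H <- stats::fft(hp)
  mp <- matrix(0, nfft, ncol(m))
  mp[1:nu, ] <- m
  conv <- Re(stats::mvfft(stats::mvfft(mp) * H, inverse = TRUE)) / nfft
  conv[nu:(2 * nu - 1), , drop = FALSE] * pitch  # centre of linear convolution
}

#' Filtered backprojection
#'
#' Convolves each detector row along the sweep direction with the
#' Ramachandran-Lakshminarayanan (ramp) kernel in the frequency domain
#' (zero-padded to the next power of two) and backprojects along the
#' geometry's rays with intersection-length weighting, averaging over views.
#'
#' @param stack a [projection_stack()].
#' @param grid output [recon_grid()].
#' @param kernel filter identifier; only `"ram-lak"` is available.
#' @return a [recon_volume()].
#' @export
fbp <- function(stack, grid, kernel = "ram-lak") {
  stopifnot(inherits(stack, "projection_stack"), inherits(grid, "recon_grid"))
  if (!identical(kernel, "ram-lak"))
    stop(sprintf("unknown kernel '%s'", kernel))
  f <- stack$frames
  for (a in seq_len(dim(f)[3]))
    f[, , a] <- .ramp_filter_rows(f[, , a], stack$geometry$pitch)
  bp <- backproject(f, grid, stack$geometry)
  vals <- bp$num
  ok <- bp$den > 1e-9
  vals[ok] <- vals[ok] / bp$den[ok]
  vals[!ok] <- 0
  recon_volume(vals, grid, stack$geometry)
}

# ---- SART -------------------------------------------------------------------

#' SART configuration
#'
#' @param relaxation relaxation factor lambda in (0, 2] (default 1).
#' @param n_iterations outer iteration count (default 24, the optimised
#'   plain-SART setting at full scale).
#' @return an object of class `sart_config`.
#' @export
sart_config <- function(relaxation = 1, n_iterations = 24L) {
  if (!(relaxation > 0 && relaxation <= 2))
    stop("relaxation must lie in (0, 2]")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(relaxation = relaxation,
                 n_iterations = as.integer(n_iterations)),
            class = "sart_config")
}

#' One SART sweep over all views
#'
#' For each view in angle order, the volume receives the relaxed SART
#' correction: the projection residual is normalised by the per-ray weight
#' sum, backprojected with the ray-voxel intersection weights, normalised by
#' the per-voxel weight sum and scaled by the relaxation factor. Rays or
#' voxels with zero intersection weight contribute nothing.
#'
#' @param volume 3D array or [recon_volume()] (current estimate).
#' @param stack a [projection_stack()] of measured line integrals.
#' @param grid the [recon_grid()] (required if `volume` is a bare array).
#' @param config a [sart_config()] (only `relaxation` is used here).
#' @param chords optional precomputed per-ray chord lengths
#'   (`[nu, nv, n_views]`, from the internal chord projector) so repeated
#'   sweeps skip recomputing the ray normalisation.
#' @return updated volume of the same type as the input.
#' @export
sart_sweep <- function(volume, stack, grid = NULL,
                       config = sart_config(), chords = NULL) {
  is_rv <- inherits(volume, "recon_volume")
  if (is_rv) { grid <- volume$grid; vals <- volume$values } else vals <- volume
  stopifnot(inherits(grid, "recon_grid"), inherits(stack, "projection_stack"))
  geom <- stack$geometry
  lam <- config$relaxation
  for (a in seq_len(geom$n_views)) {
    ang <- geom$angles_deg[a]
    p <- .project_volume(vals, grid, geom, ang)
    r <- if (is.null(chords)) .chord_lengths(grid, geom, ang) else
      chords[, , a, drop = FALSE]
    corr <- array(0, dim(p))
    ok <- r > 1e-9
    corr[ok] <- (stack$frames[, , a][ok] - p[ok]) / r[ok]
    bp <- backproject(corr, grid, geom, ang)
    upd <- bp$num
    okv <- bp$den > 1e-9
    upd[okv] <- upd[okv] / bp$den[okv]
    upd[!okv] <- 0
    vals <- vals + lam * upd
  }
  if (is_rv) { volume$values <- vals; volume } else vals
}

# ---- TV ---------------------------------------------------------------------

#' Anisotropic-magnitude total variation of a volume
#'
#' Sum over voxels of the Euclidean magnitude of backward differences along
#' the three axes (differences at the first index of each axis are 0).
#'
#' @param volume 3D array or [recon_volume()].
#' @return scalar TV value.
#' @export
tv_norm <- function(volume) {
  v <- if (inherits(volume, "recon_volume")) volume$values else volume
  stopifnot(length(dim(v)) == 3L)
  cpp_tv_norm(as.numeric(v), dim(v))
}

# gradient of tv_norm with smoothed magnitude sqrt(. + eps)
.tv_gradient <- function(v, eps = 1e-8) {
  array(cpp_tv_gradient(as.numeric(v), dim(v), eps), dim(v))
}

#' TV descent configuration
#'
#' @param beta regularisation step control (default 1e-7, the setting that
#'   maximised nodule contrast at full scale).
#' @param n_inner steepest-descent steps per outer iteration (default 20).
#' @param tolerance optional data-inconsistency stopping bound for
#'   [reconstruct()] (`NULL` disables the stopping rule; the reference
#'   protocol runs a fixed iteration count).
#' @return an object of class `tv_config`.
#' @export
tv_config <- function(beta = 1e-7, n_inner = 20L, tolerance = NULL) {
  if (beta <= 0) stop("beta must be positive")
  if (n_inner < 1L) stop("n_inner must be >= 1")
  structure(list(beta = beta, n_inner = as.integer(n_inner),
                 tolerance = tolerance), class = "tv_config")
}

#' TV steepest-descent step block
#'
#' Computes the SART step size `d_p = ||volume - volume_pre_sart||_2` once,
#' then performs `n_inner` steepest-descent steps on the TV gradient. The
#' gradient is normalised voxelwise to unit magnitude (a descent field), so
#' each voxel moves by at most `beta * d_p` per inner step; the gradient
#' magnitude is smoothed with epsilon 1e-8 to avoid division by zero. If
#' `d_p` is 0 the input is returned unchanged. See the methods vignette for
#' why the voxelwise normalisation is the reading under which `beta`
#' actually controls regularisation strength.
#'
#' @param volume volume after the SART update (array or [recon_volume()]).
#' @param volume_pre_sart volume before the SART update (congruent).
#' @param config a [tv_config()].
#' @return updated volume of the same type as the input.
#' @export
tv_descent <- function(volume, volume_pre_sart, config = tv_config()) {
  is_rv <- inherits(volume, "recon_volume")
  v <- if (is_rv) volume$values else volume
  v0 <- if (inherits(volume_pre_sart, "recon_volume"))
    volume_pre_sart$values else volume_pre_sart
  stopifnot(identical(dim(v), dim(v0)))
  dp <- sqrt(sum((v - v0)^2))
  if (dp > 0)
    v <- array(cpp_tv_descent(as.numeric(v), dim(v), config$beta * dp,
                              config$n_inner, 1e-8), dim(v))
  if (is_rv) { volume$values <- v; volume } else v
}

# ---- FISTA ------------------------------------------------------------------

#' Initial FISTA state
#'
#' @param initial the initial volume (array or [recon_volume()] values).
#' @return an object of class `fista_state` with `t = 1`, `previous` equal
#'   to the initial volume and global index `m = 0`.
#' @export
fista_state <- function(initial) {
  v <- if (inherits(initial, "recon_volume")) initial$values else initial
  structure(list(t = 1, previous = v, m = 0L), class = "fista_state")
}

#' FISTA momentum step
#'
#' Advances the momentum scalar by `t_next = (1 + sqrt(1 + 4 t^2)) / 2` and
#' extrapolates `s + ((t - 1)/t_next) (s - s_prev)`. At the first step
#' (t = 1) the extrapolation is the identity.
#'
#' @param current current volume (array or [recon_volume()]).
#' @param state a [fista_state()].
#' @return list with `volume` (extrapolated, same type as `current`) and the
#'   advanced `state`.
#' @export
fista_step <- function(current, state) {
  stopifnot(inherits(state, "fista_state"))
  is_rv <- inherits(current, "recon_volume")
  v <- if (is_rv) current$values else current
  t_next <- (1 + sqrt(1 + 4 * state$t^2)) / 2
  coef <- (state$t - 1) / t_next
  out <- v + coef * (v - state$previous)
  new_state <- structure(list(t = t_next, previous = v, m = state$m + 1L),
                         class = "fista_state")
  if (is_rv) { current$values <- out
    list(volume = current, state = new_state)
  } else list(volume = out, state = new_state)
}

# ---- driver -----------------------------------------------------------------

#' Volume reconstruction
#'
#' Reconstructs a volume from a projection stack with one of three methods:
#' `"fbp"` (ramp-filtered backprojection), `"sart"` (relaxed SART sweeps) or
#' `"sart_tv_fista"` (per outer iteration: SART sweep, TV steepest-descent
#' block, FISTA momentum extrapolation). Iterative methods start from a zero
#' volume; the root-mean-square difference between successive iterates, the
#' TV value and the projection residual norm are logged per iteration.
#'
#' @param stack a [projection_stack()].
#' @param method `"fbp"`, `"sart"` or `"sart_tv_fista"`.
#' @param grid output [recon_grid()].
#' @param sart a [sart_config()]; `n_iterations` defaults to 24 for plain
#'   SART and 30 for SART-TV-FISTA unless given explicitly.
#' @param tv a [tv_config()] (used by `"sart_tv_fista"`); if its `tolerance`
#'   is non-`NULL`, iteration stops early once the projection residual norm
#'   falls below it.
#' @param verbose print per-iteration progress.
#' @param log_residual also log the projection residual norm per iteration
#'   (costs one extra forward projection per iteration; forced on when
#'   `tv$tolerance` is set).
#' @param restart adaptive momentum restart: reset the FISTA state
#'   (`t = 1`) when the successive-iterate RMSE rises by more than 10%
#'   (default `TRUE`). Plain momentum on the relaxed SART map can amplify
#'   iterate changes instead of damping them; the restart caps that
#'   runaway without reacting to noise-level wiggles and leaves the
#'   t-recurrence untouched between restarts.
#' @return a [recon_volume()] with an iteration `log` for iterative methods.
#' @export
reconstruct <- function(stack, method = c("sart_tv_fista", "sart", "fbp"),
                        grid, sart = NULL, tv = tv_config(),
                        verbose = FALSE, log_residual = FALSE,
                        restart = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "projection_stack"), inherits(grid, "recon_grid"))
  if (method == "fbp") return(fbp(stack, grid))
  if (is.null(sart))
    sart <- sart_config(n_iterations = if (method == "sart") 24L else 30L)
  vals <- array(0, grid$shape)
  chords <- .chord_lengths(grid, stack$geometry)
  st <- fista_state(vals)
  log <- data.frame(iteration = integer(), rmse = numeric(),
                    tv = numeric(), residual = numeric())
  prev_iterate <- vals
  for (it in seq_len(sart$n_iterations)) {
    v0 <- vals
    vals <- sart_sweep(vals, stack, grid, sart, chords = chords)
    if (method == "sart_tv_fista") {
      vals <- tv_descent(vals, v0, tv)
      iterate <- vals
      fs <- fista_step(vals, st)
      vals <- fs$volume; st <- fs$state
    } else iterate <- vals
    res <- if (log_residual || !is.null(tv$tolerance))
      sqrt(sum((.project_volume(iterate, grid, stack$geometry) -
                  stack$frames)^2)) else NA_real_
    log[it, ] <- list(it, sqrt(mean((iterate - prev_iterate)^2)),
                      tv_norm(iterate), res)
    if (method == "sart_tv_fista" && restart && it > 1L &&
        log$rmse[it] > 1.1 * log$rmse[it - 1L]) {
      # momentum runaway (not mere noise wiggle): reset the acceleration
      st <- fista_state(iterate)
      vals <- iterate
    }
    if (verbose)
      message(sprintf("iter %2d  rmse %.4g  tv %.4g  residual %.4g",
                      it, log$rmse[it], log$tv[it], log$residual[it]))
    prev_iterate <- iterate
    if (!is.null(tv$tolerance) && method == "sart_tv_fista" &&
        res < tv$tolerance) break
  }
  recon_volume(prev_iterate, grid, stack$geometry, log = log[seq_len(nrow(log)), ])
}
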