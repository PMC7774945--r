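# Shared fixtures, built in code. Heavyweight results are memoised per
# session so several tests can share one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small empty phantom scaffold
empty_frac <- function(shape) {
  list(bone = array(0, shape), soft = array(0, shape),
       nodule = array(0, shape))
}

# uniform slab phantom of one material filling a centred sub-box
slab_phantom <- function(shape, spacing, material = "soft",
                         fill = c(1, 1, 1)) {
  fr <- empty_frac(shape)
  idx <- lapply(seq_len(3), function(ax) {
    n <- shape[ax]
    w <- max(1L, round(fill[ax] * n))
    lo <- (n - w) %/% 2L + 1L
    lo:(lo + w - 1L)
  })
  fr[[material]][idx[[1]], idx[[2]], idx[[3]]] <- 1
  voxel_phantom(fr, spacing)
}

# small acquisition for solver tests
toy_geometry <- function(n_views = 3L, det = 16L, pitch = 8) {
  acquisition_geometry(n_views = n_views, detector_shape = c(det, det),
                       pitch = pitch)
}

# dense system matrix of one geometry/grid by projecting basis volumes;
# independent of the SART update logic it is used to check
dense_system_matrix <- function(grid, geometry) {
  nvox <- prod(grid$shape)
  nray <- prod(geometry$detector_shape) * geometry$n_views
  A <- matrix(0, nray, nvox)
  basis <- array(0, grid$shape)
  for (j in seq_len(nvox)) {
    basis[j] <- 1
    A[, j] <- as.numeric(detomo:::.project_volume(basis, grid, geometry))
    basis[j] <- 0
  }
  A
}

# direct implementation of the relaxed SART view update with dense algebra
dense_sart_sweep <- function(x, A, g, geometry, lambda = 1) {
  nray_view <- prod(geometry$detector_shape)
  for (a in seq_len(geometry$n_views)) {
    rows <- (a - 1L) * nray_view + seq_len(nray_view)
    Av <- A[rows, , drop = FALSE]
    r <- rowSums(Av)
    corr <- numeric(length(rows))
    ok <- r > 1e-9
    corr[ok] <- (g[rows][ok] - (Av %*% x)[ok]) / r[ok]
    colw <- colSums(Av)
    upd <- as.numeric(crossprod(Av, corr))
    okv <- colw > 1e-9
    upd[okv] <- upd[okv] / colw[okv]
    upd[!okv] <- 0
    x <- x + lambda * upd
  }
  x
}

# direct double-loop evaluation of the bilateral weighting (replicate
# padding, range kernel on the min/max-normalised image)
brute_bilateral <- function(img, sigma_d, sigma_r) {
  half <- as.integer(2 * sigma_d)
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img)
  s <- (img - lo) / (hi - lo)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    num <- 0; den <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), nrow(img))
      jj <- min(max(j + dj, 1), ncol(img))
      w <- exp(-(di^2 + dj^2) / (2 * sigma_d^2)) *
        exp(-(s[i, j] - s[ii, jj])^2 / (2 * sigma_r^2))
      num <- num + w * s[ii, jj]; den <- den + w
    }
    out[i, j] <- num / den
  }
  out * (hi - lo) + lo
}

# Gumbel(location, scale) draws
rgumbel <- function(n, location, scale)
  location - scale * log(-log(stats::runif(n)))

# a 24 x 24 window whose per-profile largest adjacent variation equals the
# given 23 values exactly (one step per column)
gumbel_window_from_maxima <- function(maxima, size = 24L) {
  w <- matrix(0, size, size)
  for (j in seq_along(maxima)) w[(size %/% 2):size, j] <- maxima[j]
  w
}

# tiny end-to-end pipeline configuration (seconds-scale)
tiny_pipeline_config <- function(seed = 5L, arms = NULL) {
  cfg <- pipeline_config(
    phantom = list(grid_shape = c(32L, 32L, 32L), spacing = 8,
                   nodules = list(list(center = c(16, 40, 0),
                                       diameter = 20))),
    geometry = acquisition_geometry(n_views = 5L,
                                    detector_shape = c(48L, 48L),
                                    pitch = 8),
    recon = list(grid_shape = c(32L, 32L, 16L), spacing = c(8, 8, 16),
                 sart_iterations = 4L, stf_iterations = 5L,
                 relaxation = 1, tv = tv_config()),
    sr = sr_net_config(depth = 3L, width = 8L, epochs = 2L, batch = 8L,
                       patch_size = 17L),
    sr_patches = 16L,
    rois = list(
      nodule = roi_spec(c(18.5, 21.5), 1.3, "nodule"),
      background = list(roi_spec(c(8, 22), 3), roi_spec(c(26, 22), 3)),
      gumbel_origin = c(3L, 9L), gumbel_size = 12L,
      mtf_radius = 4),
    water = NULL,
    seed = seed)
  if (!is.null(arms)) cfg$arms <- arms
  cfg
}

tiny_run <- function() memo("tiny_run", suppressMessages(
  run_comparison(tiny_pipeline_config())))
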