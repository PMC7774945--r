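#' Circular region-of-interest specification
#'
#' @param center pixel coordinates `c(x, y)` (1-based, dim 1 = sweep axis).
#' @param radius radius in pixels (> 0).
#' @param role one of `"nodule"`, `"background"`, `"artifact-window"`,
#'   `"mtf-region"`, `"nps-region"`.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius, role = "background") {
  stopifnot(length(center) == 2L, radius > 0)
  role <- match.arg(role, c("nodule", "background", "artifact-window",
                            "mtf-region", "nps-region"))
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 role = role), class = "roi_spec")
}

# logical mask of pixels whose centres lie within the ROI circle
.roi_mask <- function(roi, dims) {
  gx <- matrix(seq_len(dims[1]), dims[1], dims[2])
  gy <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (gx - roi$center[1])^2 + (gy - roi$center[2])^2 <= roi$radius^2
}

.check_roi_inside <- function(roi, dims) {
  if (roi$center[1] - roi$radius < 0.5 || roi$center[2] - roi$radius < 0.5 ||
      roi$center[1] + roi$radius > dims[1] + 0.5 ||
      roi$center[2] + roi$radius > dims[2] + 0.5)
    stop("ROI extends outside the image")
}

#' Root-mean-square error between two images
#'
#' @param image_a,image_b congruent numeric matrices.
#' @return scalar RMSE.
#' @export
rmse <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b))) stop("shape mismatch")
  sqrt(mean((image_a - image_b)^2))
}

#' Signal-difference-to-noise ratio
#'
#' `|mean(nodule) - mean(background)| / sd(background)` with the background
#' statistics pooled over all pixels of the background ROIs (radius 9 px in
#' the reference layout). ROI membership is by pixel centre.
#'
#' @param slice 2D image (in-focus plane).
#' @param nodule_roi a [roi_spec()] for the nodule.
#' @param background_rois list of at least two background [roi_spec()]s,
#'   non-overlapping with the nodule ROI.
#' @return scalar SDNR.
#' @export
sdnr <- function(slice, nodule_roi, background_rois) {
  stopifnot(inherits(nodule_roi, "roi_spec"), length(background_rois) >= 2L)
  d <- dim(slice)
  .check_roi_inside(nodule_roi, d)
  nmask <- .roi_mask(nodule_roi, d)
  bmask <- matrix(FALSE, d[1], d[2])
  for (r in background_rois) {
    .check_roi_inside(r, d)
    m <- .roi_mask(r, d)
    if (any(m & nmask)) stop("background ROI overlaps the nodule ROI")
    bmask <- bmask | m
  }
  bg <- slice[bmask]
  s <- stats::sd(bg)
  if (s == 0) stop("zero background standard deviation")
  abs(mean(slice[nmask]) - mean(bg)) / s
}

#' Gumbel largest-variation ripple statistic
#'
#' Quantifies high-frequency streak (ripple) artifacts: inside a square
#' window oriented with the sweep axis, parallel line profiles are taken
#' along the sweep direction at 1-pixel intervals; for each profile the
#' maximal absolute difference between adjacent pixels is recorded. The
#' sample of maxima is ranked, assigned cumulative probabilities by the
#' symmetry rank method `Q = (rank - 0.5) / l`, and regressed on the Gumbel
#' reduced variate `-ln(-ln Q)`: the fitted intercept/slope estimate the
#' extreme-value location/scale, and the Pearson correlation of the rank
#' plot measures how well the maxima follow the extreme-value law.
#'
#' @param slice 2D image (dim 1 = sweep axis).
#' @param origin window corner `c(x, y)` (1-based).
#' @param size window edge length in pixels (default 24, giving 23 profiles
#'   of 23 adjacent differences).
#' @return an object of class `gumbel_result`: `largest_variations` (the
#'   per-profile maxima), `mean`, `sd`, `pearson_r`, `location`, `scale`,
#'   `n_profiles` and `degenerate` (TRUE when all maxima are equal and the
#'   fit is undefined).
#' @export
gumbel_ripple <- function(slice, origin = c(1L, 1L), size = 24L) {
  d <- dim(slice)
  origin <- as.integer(origin); size <- as.integer(size)
  if (origin[1] < 1L || origin[2] < 1L || origin[1] + size - 1L > d[1] ||
      origin[2] + size - 1L > d[2])
    stop("analysis window out of bounds")
  win <- slice[origin[1]:(origin[1] + size - 1L),
               origin[2]:(origin[2] + size - 1L)]
  nprof <- size - 1L
  # profiles run along the sweep axis (rows of dim 1); one per column offset
  maxima <- vapply(seq_len(nprof), function(j)
    max(abs(diff(win[, j]))), numeric(1))
  l <- length(maxima)
  srt <- sort(maxima)
  q <- (seq_len(l) - 0.5) / l
  y <- -log(-log(q))
  degenerate <- stats::sd(srt) == 0
  if (degenerate) {
    loc <- srt[1]; scl <- 0; r <- NA_real_
  } else {
    fit <- stats::lm.fit(cbind(1, y), srt)
    loc <- fit$coefficients[1]; scl <- fit$coefficients[2]
    r <- stats::cor(y, srt)
  }
  structure(list(largest_variations = maxima, mean = mean(maxima),
                 sd = stats::sd(maxima), pearson_r = r,
                 location = unname(loc), scale = unname(scl),
                 n_profiles = l, degenerate = degenerate),
            class = "gumbel_result")
}

#' @export
print.gumbel_result <- function(x, ...) {
  cat(sprintf("<gumbel_result> %d maxima: %.4g +/- %.4g; location %.4g, scale %.4g, r %.3f%s\n",
              x$n_profiles, x$mean, x$sd, x$location, x$scale,
              ifelse(is.na(x$pearson_r), NaN, x$pearson_r),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Spectrum curve container
#'
#' @param frequencies non-negative, increasing, cycles/mm.
#' @param values MTF (dimensionless) or NPS values.
#' @param kind `"mtf"` or `"nps"`.
#' @param axis for NPS cuts: `"horizontal"` or `"vertical"` (NA for MTF).
#' @return an object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(frequencies, values, kind = "mtf",
                           axis = NA_character_) {
  stopifnot(length(frequencies) == length(values),
            all(frequencies >= 0), all(diff(frequencies) > 0))
  structure(list(frequencies = frequencies, values = values, kind = kind,
                 axis = axis), class = "spectrum_curve")
}

#' Radial modulation transfer function of a circular object
#'
#' Treats the edge of a disc as a superposition of radial edges: samples
#' radial profiles from the disc centre over 360 spokes (bilinear
#' interpolation, radial step 0.1 px), averages them into an edge-spread
#' function, differentiates to the line-spread function, and returns the
#' magnitude of its 1D Fourier transform normalised to 1 at zero frequency.
#'
#' @param slice 2D image containing the disc and surrounding background.
#' @param center disc centre `c(x, y)`, pixels.
#' @param radius_px evaluation-region radius in pixels (default 9, the
#'   reference region of ~254 px^2); must contain the full edge.
#' @param pixel_size pixel size in mm (sets the frequency axis).
#' @param n_spokes number of radial spokes (default 360).
#' @param radial_step radial sampling step, px (default 0.1).
#' @return a [spectrum_curve()] of kind `"mtf"`; attribute `degenerate` is
#'   TRUE when the region contains no edge (flat profile).
#' @export
radial_mtf <- function(slice, center, radius_px = 9, pixel_size = 1,
                       n_spokes = 360L, radial_step = 0.1) {
  d <- dim(slice)
  if (center[1] < 1 || center[2] < 1 || center[1] > d[1] || center[2] > d[2])
    stop("disc centre outside the image")
  rs <- seq(0, radius_px, by = radial_step)
  th <- seq(0, 2 * pi, length.out = n_spokes + 1L)[-(n_spokes + 1L)]
  xi <- outer(rs, th, function(r, t) center[1] + r * cos(t))
  yi <- outer(rs, th, function(r, t) center[2] + r * sin(t))
  prof <- matrix(.bilinear_sample(slice, as.numeric(xi), as.numeric(yi)),
                 length(rs), n_spokes)
  esf <- rowMeans(prof)
  lsf <- diff(esf) / radial_step
  degenerate <- max(abs(lsf)) < 1e-12 * max(1, max(abs(esf)))
  mag <- Mod(stats::fft(lsf))
  n <- length(lsf)
  nf <- floor(n / 2) + 1L
  mtf <- if (degenerate) rep(NA_real_, nf) else mag[seq_len(nf)] / mag[1]
  freq <- (seq_len(nf) - 1L) / (n * radial_step * pixel_size)
  out <- spectrum_curve(freq, mtf, kind = "mtf")
  attr(out, "degenerate") <- degenerate
  out
}

#' Noise power spectrum of a uniform slice
#'
#' Tiles overlapping square ROIs on a regular grid inside a central
#' analysis region, subtracts a least-squares 2D quadratic surface from
#' each ROI (trend correction), averages
#' `|2D DFT|^2 * (dx * dy) / (Nx * Ny)` over the ROIs, and extracts 1D
#' horizontal and vertical cuts through zero frequency (each averaged with
#' its +/- 1 neighbouring lines, DC bin excluded).
#'
#' @param slice 2D image.
#' @param roi_size ROI edge length in pixels (reference 64).
#' @param step ROI grid step in pixels (reference 8).
#' @param n_grid ROIs per axis (reference 8, i.e. 64 ROIs).
#' @param pixel_size pixel size in mm.
#' @param region optional `c(x0, y0, x1, y1)` analysis region (default: the
#'   largest centred region hosting the ROI grid, up to 256 x 256).
#' @return list with `horizontal` and `vertical` [spectrum_curve()]s, the
#'   averaged 2D spectrum `nps2d` (DC at element \[1,1\]), and `n_rois`.
#' @export
nps <- function(slice, roi_size = 64L, step = 8L, n_grid = 8L,
                pixel_size = 1, region = NULL) {
  d <- dim(slice)
  roi_size <- as.integer(roi_size); step <- as.integer(step)
  span <- roi_size + step * (n_grid - 1L)
  if (is.null(region)) {
    half <- pmin(c(256L, 256L), d) %/% 2L
    cx <- d %/% 2L
    region <- c(cx[1] - half[1] + 1L, cx[2] - half[2] + 1L,
                cx[1] - half[1] + pmin(c(256L, 256L), d)[1],
                cx[2] - half[2] + pmin(c(256L, 256L), d)[2])
  }
  rw <- c(region[3] - region[1] + 1L, region[4] - region[2] + 1L)
  if (any(span > rw))
    stop("ROI grid does not fit inside the analysis region")
  # centre the ROI lattice in the region
  off <- (rw - span) %/% 2L
  x0 <- region[1] + off[1]; y0 <- region[2] + off[2]
  # quadratic detrending design matrix (shared by all ROIs)
  gx <- matrix(seq_len(roi_size), roi_size, roi_size)
  gy <- t(gx)
  X <- cbind(1, as.numeric(gx), as.numeric(gy), as.numeric(gx)^2,
             as.numeric(gx) * as.numeric(gy), as.numeric(gy)^2)
  qrX <- qr(X)
  acc <- matrix(0, roi_size, roi_size)
  n_rois <- 0L
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      ox <- x0 + (i - 1L) * step; oy <- y0 + (j - 1L) * step
      roi <- slice[ox:(ox + roi_size - 1L), oy:(oy + roi_size - 1L)]
      res <- roi - matrix(X %*% qr.coef(qrX, as.numeric(roi)),
                          roi_size, roi_size)
      acc <- acc + Mod(stats::fft(res))^2
      n_rois <- n_rois + 1L
    }
  }
  nps2d <- acc / n_rois * pixel_size^2 / (roi_size * roi_size)
  nf <- floor(roi_size / 2)
  freq <- seq_len(nf) / (roi_size * pixel_size)
  wrap <- function(k) ((k) %% roi_size) + 1L  # 0-based index -> 1-based
  horiz <- vapply(seq_len(nf), function(k)
    mean(nps2d[wrap(k), wrap(c(-1L, 0L, 1L))]), numeric(1))
  vert <- vapply(seq_len(nf), function(k)
    mean(nps2d[wrap(c(-1L, 0L, 1L)), wrap(k)]), numeric(1))
  list(horizontal = spectrum_curve(freq, horiz, kind = "nps",
                                   axis = "horizontal"),
       vertical = spectrum_curve(freq, vert, kind = "nps",
                                 axis = "vertical"),
       nps2d = nps2d, n_rois = n_rois)
}
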