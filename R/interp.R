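# Separable image resampling primitives. All operate on plain matrices and
# are exact on constant images (kernels are renormalised at the borders).

# band-limited, row-normalised 1D Gaussian operator (n x n)
.gauss_op <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + off, 1L), n)  # replicate edges
    for (t in seq_along(j)) M[i, j[t]] <- M[i, j[t]] + w[t]
  }
  M / rowSums(M)
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian smoothing (kernel truncated at 3 sigma, edge
#' replication, renormalised so a constant image is exactly preserved).
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  Br <- .gauss_op(nrow(image), sigma)
  Bc <- .gauss_op(ncol(image), sigma)
  Br %*% image %*% t(Bc)
}

# Keys cubic-convolution kernel, a = -0.5
.cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# 1D bicubic interpolation operator mapping n_in samples to n_out
.cubic_op <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * n_in / n_out - 0.5 + 1  # source coordinate, 1-based
    base <- floor(x)
    taps <- (base - 1):(base + 2)
    w <- .cubic_kernel(x - taps)
    taps <- pmin(pmax(taps, 1L), n_in)
    for (t in seq_along(taps)) M[i, taps[t]] <- M[i, taps[t]] + w[t]
  }
  M / rowSums(M)
}

#' Bicubic resize of a 2D image
#'
#' Separable cubic-convolution (Keys, a = -0.5) resampling with edge
#' replication; used for the down/upscale pairs of the super-resolution
#' training set.
#'
#' @param image numeric matrix.
#' @param shape output `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_bicubic <- function(image, shape) {
  shape <- as.integer(rep(shape, length.out = 2L))
  stopifnot(all(shape >= 1L))
  Rr <- .cubic_op(shape[1], nrow(image))
  Rc <- .cubic_op(shape[2], ncol(image))
  Rr %*% image %*% t(Rc)
}

# bilinear sample of img at (non-integer, 1-based) coordinates, edge clamped
.bilinear_sample <- function(img, xi, yi) {
  nr <- nrow(img); nc <- ncol(img)
  xi <- pmin(pmax(xi, 1), nr); yi <- pmin(pmax(yi, 1), nc)
  x0 <- pmin(floor(xi), nr - 1L); y0 <- pmin(floor(yi), nc - 1L)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

# rotate (degrees, about the image centre) then shift (integer pixels) an
# image by bilinear resampling
.rotate_shift <- function(img, angle_deg, shift = c(0L, 0L)) {
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  gx <- matrix(seq_len(nr), nr, nc) - cx
  gy <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cy
  xi <- cos(th) * gx - sin(th) * gy + cx - shift[1]
  yi <- sin(th) * gx + cos(th) * gy + cy - shift[2]
  out <- .bilinear_sample(img, as.numeric(xi), as.numeric(yi))
  matrix(out, nr, nc)
}
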