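test_that("rmse obeys its closed forms and symmetry", {
  set.seed(1)
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 3.2), 3.2)
  expect_equal(rmse(a, a - 1.5), 1.5)
  b <- matrix(rnorm(64), 8, 8)
  expect_equal(rmse(a, b), rmse(b, a))
  # 2x2 hand-evaluated case: differences (1, 2, 2, 1)
  expect_equal(rmse(matrix(c(1, 2, 2, 1), 2), matrix(0, 2, 2)),
               sqrt((1 + 4 + 4 + 1) / 4))
  expect_error(rmse(a, matrix(0, 4, 4)), "mismatch")
})

test_that("sdnr matches its construction oracle and invariances", {
  set.seed(2)
  n <- 128
  img <- matrix(rnorm(n * n, mean = 1, sd = 0.5), n, n)
  nod <- roi_spec(c(40, 40), 6, "nodule")
  img[detomo:::.roi_mask(nod, c(n, n))] <- 2
  bg <- list(roi_spec(c(90, 40), 9), roi_spec(c(90, 90), 9),
             roi_spec(c(40, 90), 9))
  got <- sdnr(img, nod, bg)
  # disc of value 2 on background ~ N(1, 0.5): SDNR ~ (2-1)/0.5 = 2
  expect_lt(abs(got - 2), 0.35)
  # scale invariance
  expect_equal(sdnr(img * 7, nod, bg), got, tolerance = 1e-12)
  # zero numerator: nodule pixels set to the pooled background mean
  img2 <- img
  nmask <- detomo:::.roi_mask(nod, c(n, n))
  bmask <- detomo:::.roi_mask(bg[[1]], c(n, n)) |
    detomo:::.roi_mask(bg[[2]], c(n, n)) |
    detomo:::.roi_mask(bg[[3]], c(n, n))
  img2[nmask] <- mean(img2[bmask])
  expect_lt(sdnr(img2, nod, bg), 1e-12)
  expect_error(sdnr(img, nod, bg[1]), "2")
  expect_error(sdnr(img, nod, list(nod, nod)), "overlap")
})

test_that("gumbel rank plot uses the symmetry plotting positions", {
  # Q(1) = 0.5 / 23 for the reference sample size
  expect_equal(round((1 - 0.5) / 23, 5), 0.02174)
  maxima <- seq(0.005, 0.027, length.out = 23)
  win <- gumbel_window_from_maxima(maxima)
  got <- gumbel_ripple(win, c(1, 1), 24)
  expect_equal(got$n_profiles, 23L)
  expect_equal(sort(got$largest_variations), maxima, tolerance = 1e-12)
  expect_equal(got$mean, mean(maxima))
  # constant slice: degenerate, all maxima zero
  flat <- gumbel_ripple(matrix(1, 30, 30), c(2, 2), 24)
  expect_true(flat$degenerate)
  expect_equal(flat$mean, 0)
  expect_error(gumbel_ripple(matrix(0, 10, 10), c(1, 1), 24), "out of bounds")
})

test_that("the rank-plot fit recovers generating Gumbel parameters", {
  set.seed(3)
  loc0 <- 0.01; scl0 <- 0.002
  locs <- scls <- rs <- numeric(100)
  for (i in 1:100) {
    draws <- rgumbel(23, loc0, scl0)
    g <- gumbel_ripple(gumbel_window_from_maxima(abs(draws)), c(1, 1), 24)
    locs[i] <- g$location; scls[i] <- g$scale; rs[i] <- g$pearson_r
  }
  expect_lt(abs(median(locs) - loc0) / loc0, 0.3)
  expect_lt(abs(median(scls) - scl0) / scl0, 0.3)
  expect_gt(median(rs), 0.95)
})

test_that("ripple of growing amplitude raises the mean largest variation", {
  set.seed(4)
  base <- matrix(rnorm(40 * 40, sd = 0.001), 40, 40)
  means <- vapply(c(0, 0.01, 0.03, 0.1), function(amp) {
    rippled <- base + amp * sin(2 * pi * (1:40) / 4)  # along sweep axis
    gumbel_ripple(rippled, c(9, 9), 24)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("radial MTF of a Gaussian-blurred disc matches the analytic MTF", {
  n <- 129; ctr <- c(65, 65); R <- 24
  gx <- matrix(1:n, n, n); gy <- t(gx)
  disc <- 0 + ((gx - ctr[1])^2 + (gy - ctr[2])^2 <= R^2)
  # sigma >= 1.5: below that, discretisation of the blur kernel itself
  # departs from the continuous Gaussian by more than the comparison band
  for (sig in c(1.5, 2)) {
    blurred <- gaussian_blur(disc, sig)
    curve <- radial_mtf(blurred, ctr, radius_px = 40, pixel_size = 1,
                        radial_step = 0.1)
    expect_equal(curve$values[1], 1)
    oracle <- exp(-2 * pi^2 * sig^2 * curve$frequencies^2)
    band <- oracle >= 0.1
    expect_lt(max(abs(curve$values[band] - oracle[band])), 0.05)
  }
  # flat region flags a degenerate curve
  flat <- radial_mtf(matrix(1, 64, 64), c(32, 32), 9)
  expect_true(attr(flat, "degenerate"))
  expect_error(radial_mtf(disc, c(500, 500)), "outside")
})

test_that("a sharper reconstruction dominates a smoother one in MTF", {
  n <- 129; ctr <- c(65, 65)
  gx <- matrix(1:n, n, n); gy <- t(gx)
  disc <- 0 + ((gx - ctr[1])^2 + (gy - ctr[2])^2 <= 24^2)
  m1 <- radial_mtf(gaussian_blur(disc, 1), ctr, 40)
  m2 <- radial_mtf(gaussian_blur(disc, 2), ctr, 40)
  band <- m1$frequencies <= 0.4  # meaningful transfer band
  expect_true(all(m1$values[band] >= m2$values[band] - 1e-9))
})

test_that("nps is flat for white noise and satisfies Parseval", {
  # zero-noise uniform slice: spectrum at machine-zero scale
  z <- nps(matrix(5, 140, 140), roi_size = 32L, step = 4L, n_grid = 8L)
  expect_equal(z$n_rois, 64L)
  expect_lt(max(z$nps2d[-1]), 1e-18)
  set.seed(6)
  ints <- replicate(20, {
    noise <- matrix(rnorm(140 * 140, sd = 0.3), 140, 140)
    out <- nps(noise, roi_size = 32L, step = 4L, n_grid = 8L,
               pixel_size = 0.5)
    df <- 1 / (32 * 0.5)
    sum(out$nps2d) * df^2
  })
  expect_lt(abs(mean(ints) - 0.3^2) / 0.3^2, 0.1)
  # flatness: axis cuts vary within a factor ~2 of their mean level
  set.seed(7)
  noise <- matrix(rnorm(140 * 140), 140, 140)
  out <- nps(noise, roi_size = 32L, step = 4L, n_grid = 8L)
  for (cut in list(out$horizontal, out$vertical)) {
    expect_lt(max(cut$values) / mean(cut$values), 2)
    expect_gt(min(cut$values) / mean(cut$values), 0.4)
  }
})

test_that("anisotropic noise separates the two nps axis cuts", {
  set.seed(8)
  noise <- matrix(rnorm(140 * 140), 140, 140)
  # smooth along dim 1 ("horizontal" cut axis) only
  sm <- detomo:::.gauss_op(140, 1.5) %*% noise
  out <- nps(sm, roi_size = 32L, step = 4L, n_grid = 8L)
  hf <- 11:16
  expect_lt(mean(out$horizontal$values[hf]),
            0.3 * mean(out$vertical$values[hf]))
})

test_that("nps rejects geometry that cannot host the ROI grid", {
  expect_error(nps(matrix(0, 50, 50), roi_size = 32L, step = 4L,
                   n_grid = 8L), "does not fit")
})
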