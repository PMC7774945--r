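test_that("unsharp mask reduces to the identity in its degenerate cases", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(unsharp_mask(img, sigma = 2.5, k = 0), img)
  flat <- matrix(3.7, 24, 24)
  expect_equal(unsharp_mask(flat, sigma = 2.5, k = 5), flat,
               tolerance = 1e-12)
  expect_error(unsharp_mask(img, sigma = -1), "positive")
  # default configuration carries the reference UM sigma
  expect_equal(sr_net_config()$um_sigma, 2.5)
})

test_that("unsharp mask adds the scaled high-pass component", {
  set.seed(1)
  img <- matrix(rnorm(20 * 20), 20, 20)
  got <- unsharp_mask(img, sigma = 1.5, k = 2)
  expect_equal(got, 2 * (img - gaussian_blur(img, 1.5)) + img)
})

test_that("training pairs obey the construction identity and provenance", {
  set.seed(2)
  frames <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  cfg <- sr_net_config(depth = 3, width = 4, patch_size = 17)
  pairs <- make_training_pairs(frames, cfg, n_patches = 12L, seed = 7)
  expect_length(pairs, 12L)
  expect_true(all(vapply(pairs, function(p)
    p$provenance$scale %in% c(2L, 3L, 4L), logical(1))))
  # residual + input reproduces the HR patch exactly (recomputed from
  # provenance through the same augmentation chain)
  for (p in pairs[c(1, 6, 12)]) {
    pv <- p$provenance
    hr <- detomo:::.rotate_shift(
      unsharp_mask(frames[, , pv$frame], cfg$um_sigma, cfg$um_k),
      pv$angle, pv$shift)
    hr_patch <- hr[pv$origin[1]:(pv$origin[1] + 16),
                   pv$origin[2]:(pv$origin[2] + 16)]
    expect_equal(p$input + p$target, hr_patch, tolerance = 1e-12)
  }
  # determinism
  pairs2 <- make_training_pairs(frames, cfg, n_patches = 12L, seed = 7)
  expect_identical(pairs, pairs2)
  expect_error(make_training_pairs(frames, sr_net_config(patch_size = 65),
                                   n_patches = 2L), "smaller")
})

test_that("super-Nyquist detail of a downscale/upscale pair lands in the residual", {
  # sinusoid above the scale-2 Nyquist (period 3 px): the down/up chain
  # cannot carry it, so the residual retains (nearly) the full component at
  # that frequency, plus its aliasing products; checked against a direct
  # FFT oracle
  n <- 64
  x <- matrix(sin(2 * pi * (1:n) / 3), n, n)
  lo <- resize_bicubic(x, c(n / 2, n / 2))
  up <- resize_bicubic(lo, c(n, n))
  res <- x - up
  spec <- function(v) Mod(stats::fft(v))^2
  f <- c(0:(n / 2), (n / 2 - 1):1) / n
  f0_bin <- which.min(abs(f - 1 / 3))
  sx <- rowMeans(apply(x, 2, spec))
  sr <- rowMeans(apply(res, 2, spec))
  # most of the original f0 component lands in the residual (bicubic
  # resampling is not an ideal low-pass, so retention is partial)
  expect_gt(sr[f0_bin] / sx[f0_bin], 0.6)
  # and most residual energy sits above the downscale Nyquist
  expect_gt(sum(sr[f > 0.25]) / sum(sr), 0.5)
})

test_that("a zero-residual network is the exact identity through the skip", {
  cfg <- sr_net_config(depth = 3, width = 4, seed = 2)
  net <- detomo:::.init_sr_network(cfg)
  last <- length(net$layers)
  net$layers[[last]]$w[] <- 0
  net$layers[[last]]$b[] <- 0
  img <- matrix(rnorm(24 * 24), 24, 24)
  expect_equal(apply_sr(net, img), img, tolerance = 1e-14)
})

test_that("apply_sr output equals input plus the predicted residual", {
  cfg <- sr_net_config(depth = 3, width = 4, seed = 3)
  net <- detomo:::.init_sr_network(cfg)
  img <- matrix(rnorm(20 * 20), 20, 20)
  x <- array(img, c(20, 20, 1, 1))
  pred <- detomo:::.sr_forward(net, x)$out[, , 1, 1]
  expect_equal(apply_sr(net, img), img + pred, tolerance = 1e-14)
})

test_that("conv backward matches numerical gradients", {
  set.seed(4)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3, sd = 0.3), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- detomo:::cpp_conv_forward(as.numeric(x), dim(x), as.numeric(w),
                                 dim(w), b)
  g <- array(rnorm(length(y)), dim(y))
  bk <- detomo:::cpp_conv_backward(as.numeric(x), dim(x), as.numeric(w),
                                   dim(w), as.numeric(g))
  loss <- function(xx, ww, bb) sum(detomo:::cpp_conv_forward(
    as.numeric(xx), dim(x), as.numeric(ww), dim(w), bb) * g)
  eps <- 1e-6
  for (probe in list(c(2, 3, 1, 1), c(5, 5, 2, 2))) {
    xp <- x; xp[matrix(probe, 1)] <- xp[matrix(probe, 1)] + eps
    num <- (loss(xp, w, b) - loss(x, w, b)) / eps
    expect_equal(array(bk$gx, dim(x))[matrix(probe, 1)], num,
                 tolerance = 1e-4)
  }
  for (probe in list(c(1, 1, 1, 1), c(3, 2, 2, 3))) {
    wp <- w; wp[matrix(probe, 1)] <- wp[matrix(probe, 1)] + eps
    num <- (loss(x, wp, b) - loss(x, w, b)) / eps
    expect_equal(array(bk$gw, dim(w))[matrix(probe, 1)], num,
                 tolerance = 1e-4)
  }
  bp <- b; bp[2] <- bp[2] + eps
  expect_equal(bk$gb[2], (loss(x, w, bp) - loss(x, w, b)) / eps,
               tolerance = 1e-4)
})

test_that("a small network overfits one repeated pair", {
  set.seed(5)
  base <- gaussian_blur(matrix(rnorm(21 * 21), 21, 21), 1.2)
  target <- 0.3 * base  # representable by the conv stack, borders included
  pairs <- rep(list(list(input = base, target = target)), 24)
  cfg <- sr_net_config(depth = 5, width = 16, epochs = 200, batch = 1,
                       lr = 0.2, seed = 6)
  net <- train_sr(pairs, cfg)
  expect_lt(net$loss_history[length(net$loss_history)],
            1e-4 * net$loss_history[1])
  # the trained net reproduces the memorised residual
  expect_equal(apply_sr(net, base), base + target, tolerance = 0.05)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(7)
  frames <- array(rnorm(48 * 48 * 2), c(48, 48, 2))
  cfg <- sr_net_config(depth = 3, width = 6, epochs = 2, batch = 4,
                       patch_size = 17, seed = 9)
  pairs <- make_training_pairs(frames, cfg, n_patches = 8L)
  n1 <- train_sr(pairs, cfg)
  n2 <- train_sr(pairs, cfg)
  expect_identical(n1$loss_history, n2$loss_history)
  expect_identical(n1$layers, n2$layers)
})

test_that("multiscale training generalises better across scales than single-scale", {
  set.seed(11)
  # smooth structured frames so down/up residuals are learnable
  frames <- array(0, c(48, 48, 3))
  for (k in 1:3)
    frames[, , k] <- gaussian_blur(matrix(rnorm(48 * 48), 48, 48), 1) +
      outer(sin((1:48) / (2 + k)), cos((1:48) / 3))
  multi <- sr_net_config(depth = 4, width = 8, epochs = 10, batch = 8,
                         patch_size = 17, seed = 13, scales = c(2L, 3L, 4L))
  single <- sr_net_config(depth = 4, width = 8, epochs = 10, batch = 8,
                          patch_size = 17, seed = 13, scales = 2L)
  train_m <- make_training_pairs(frames, multi, n_patches = 48L)
  train_s <- make_training_pairs(frames, single, n_patches = 48L)
  net_m <- train_sr(train_m, multi)
  net_s <- train_sr(train_s, single)
  # validation drawn from the scales the single-scale net never saw
  val_cfg <- multi; val_cfg$scales <- c(3L, 4L)
  val <- make_training_pairs(frames, val_cfg, n_patches = 32L, seed = 99L)
  vloss <- function(net) mean(vapply(val, function(p) {
    x <- array(p$input, c(dim(p$input), 1, 1))
    mean((detomo:::.sr_forward(net, x)$out[, , 1, 1] - p$target)^2)
  }, numeric(1)))
  expect_lt(vloss(net_m), vloss(net_s))
})

test_that("checkpoints round-trip the network and its config", {
  cfg <- sr_net_config(depth = 3, width = 4, seed = 21)
  net <- detomo:::.init_sr_network(cfg)
  f <- tempfile(fileext = ".ckpt")
  save_sr_network(net, f)
  net2 <- load_sr_network(f)
  expect_identical(net2$layers, net$layers)
  expect_identical(net2$config$depth, cfg$depth)
})
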