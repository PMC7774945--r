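#' Unsharp masking
#'
#' Adds a scaled high-pass component to the image:
#' `k * (V - V_lowpass) + V`, where `V_lowpass` is a Gaussian blur of
#' standard deviation `sigma`. With `k = 0`, or on a constant image, the
#' input is returned unchanged.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian SD of the low-pass, pixels (> 0; default 2.5, the
#'   setting that balances high-frequency noise against edge preservation).
#' @param k scaling contrast (default 1).
#' @return sharpened matrix of the same shape.
#' @export
unsharp_mask <- function(image, sigma = 2.5, k = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (k == 0) return(image)
  k * (image - gaussian_blur(image, sigma)) + image
}

#' Super-resolution network configuration
#'
#' Hyperparameters of the residual-learning convolutional network and its
#' training-pair generation. The default is a desk-scale network (depth 8,
#' width 32, 15 epochs) trainable in minutes on one CPU; `profile = "paper"`
#' selects the full-scale configuration (depth 20, width 64, 70 epochs,
#' mini-batch 128).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param depth number of weight layers (>= 2).
#' @param width filters per hidden layer.
#' @param kernel spatial filter size (odd).
#' @param scales training downscale factors (default `c(2, 3, 4)`).
#' @param lr initial learning rate (default 0.001).
#' @param batch mini-batch size.
#' @param epochs training epochs.
#' @param momentum SGDM momentum coefficient (default 0.9).
#' @param lr_decay multiplicative learning-rate decay factor applied every
#'   `lr_step` epochs (default 1 = constant rate; step decay is the
#'   standard schedule for this architecture).
#' @param lr_step epochs between decay steps.
#' @param seed integer seed for weight init, patch sampling and shuffling.
#' @param um_sigma Gaussian SD of the unsharp mask applied before pair
#'   generation (default 2.5).
#' @param um_k unsharp-mask scaling contrast (default 1).
#' @param clip_norm global gradient-norm clip (default `0.01 / lr`,
#'   the standard stabilisation for this architecture).
#' @param patch_size training patch edge length, pixels (default 41).
#' @return an object of class `sr_net_config`.
#' @export
sr_net_config <- function(profile = c("desk", "paper"), depth = NULL,
                          width = NULL, kernel = 3L, scales = c(2L, 3L, 4L),
                          lr = 0.001, batch = NULL, epochs = NULL,
                          momentum = 0.9, lr_decay = 1, lr_step = 20L,
                          seed = 1L, um_sigma = 2.5,
                          um_k = 1, clip_norm = 0.01 / lr,
                          patch_size = 41L) {
  profile <- match.arg(profile)
  def <- if (profile == "desk") list(depth = 8L, width = 32L, batch = 16L,
                                     epochs = 15L)
  else list(depth = 20L, width = 64L, batch = 128L, epochs = 70L)
  cfg <- list(
    depth = as.integer(if (is.null(depth)) def$depth else depth),
    width = as.integer(if (is.null(width)) def$width else width),
    kernel = as.integer(kernel), scales = as.integer(scales), lr = lr,
    batch = as.integer(if (is.null(batch)) def$batch else batch),
    epochs = as.integer(if (is.null(epochs)) def$epochs else epochs),
    momentum = momentum, lr_decay = lr_decay, lr_step = as.integer(lr_step),
    seed = as.integer(seed), um_sigma = um_sigma,
    um_k = um_k, clip_norm = clip_norm,
    patch_size = as.integer(patch_size))
  if (cfg$depth < 2L) stop("depth must be >= 2")
  if (cfg$kernel %% 2L != 1L) stop("kernel must be odd")
  with(cfg, stopifnot(width >= 1, lr > 0, batch >= 1, epochs >= 1,
                      momentum >= 0, lr_decay > 0, lr_decay <= 1,
                      lr_step >= 1, um_sigma > 0, clip_norm > 0,
                      patch_size >= 3))
  structure(cfg, class = "sr_net_config")
}

# He-initialised network: list of layers (w: [k,k,cin,cout], b: cout)
.init_sr_network <- function(config) {
  k <- config$kernel
  chans <- c(1L, rep(config$width, config$depth - 1L), 1L)
  layers <- .with_seed(config$seed, {
    lapply(seq_len(config$depth), function(l) {
      cin <- chans[l]; cout <- chans[l + 1L]
      sd <- sqrt(2 / (k * k * cin))
      list(w = array(stats::rnorm(k * k * cin * cout, sd = sd),
                     dim = c(k, k, cin, cout)),
           b = numeric(cout))
    })
  })
  structure(list(layers = layers, config = config, loss_history = NULL),
            class = "sr_network")
}

#' @export
print.sr_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sr_network> depth %d, width %d, %dx%d kernels",
              cfg$depth, cfg$width, cfg$kernel, cfg$kernel))
  if (!is.null(x$loss_history))
    cat(sprintf("; trained %d epochs, final loss %.4g",
                length(x$loss_history), x$loss_history[length(x$loss_history)]))
  cat("\n")
  invisible(x)
}

# forward pass; x: [H,W,1,B]; returns list(out, inputs, preact)
.sr_forward <- function(net, x, keep = FALSE) {
  L <- length(net$layers)
  inputs <- if (keep) vector("list", L) else NULL
  preact <- if (keep) vector("list", L) else NULL
  a <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    if (keep) inputs[[l]] <- a
    z <- cpp_conv_forward(as.numeric(a), dim(a), as.numeric(ly$w),
                          dim(ly$w), ly$b)
    if (keep) preact[[l]] <- z
    if (l < L) z[z < 0] <- 0  # ReLU (dim attribute preserved)
    a <- z
  }
  list(out = a, inputs = inputs, preact = preact)
}

# backward pass; returns list of per-layer list(gw, gb)
.sr_backward <- function(net, fw, gout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- gout
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    if (l < L) g <- g * (fw$preact[[l]] > 0)
    bk <- cpp_conv_backward(as.numeric(fw$inputs[[l]]), dim(fw$inputs[[l]]),
                            as.numeric(ly$w), dim(ly$w), as.numeric(g))
    grads[[l]] <- list(gw = bk$gw, gb = bk$gb)
    g <- bk$gx
  }
  grads
}

#' Generate multiscale residual training pairs
#'
#' Emulates the training-set construction for residual-learning
#' super-resolution: each frame is unsharp-masked, augmented by a small
#' random rotation (uniform in +/- 5 degrees) and integer shift (+/- 3 px),
#' downscaled by a randomly chosen scale factor (bicubic), upscaled back to
#' the original size (bicubic), and random congruent patches of the upscaled
#' image (input) and of the residual `HR - upscaled` (target) are extracted.
#' By construction `target + input` reproduces the HR patch exactly.
#'
#' @param vm_stack a [projection_stack()] (normally VM projections) or a 3D
#'   array of frames.
#' @param config an [sr_net_config()].
#' @param n_patches number of pairs to generate.
#' @param seed integer seed (defaults to `config$seed`).
#' @param patches_per_augmentation patches drawn from each augmented frame
#'   before a new frame/scale/rotation/shift is sampled (amortises the
#'   resampling cost).
#' @return list of class `sr_training_pairs`; each element has `input`,
#'   `target` (matrices `patch_size x patch_size`) and `provenance`
#'   (frame, origin, scale, angle, shift).
#' @export
make_training_pairs <- function(vm_stack, config = sr_net_config(),
                                n_patches = 64L, seed = config$seed,
                                patches_per_augmentation = 8L) {
  frames <- if (inherits(vm_stack, "projection_stack")) vm_stack$frames
  else vm_stack
  stopifnot(length(dim(frames)) == 3L)
  ps <- config$patch_size
  if (ps >= min(dim(frames)[1:2]))
    stop("patch_size must be smaller than the frame size")
  if (any(dim(frames)[1:2] %/% max(config$scales) < 4L))
    stop("frames too small for the configured scale factors")
  um_cache <- new.env(parent = emptyenv())
  pairs <- .with_seed(seed, {
    out <- vector("list", n_patches)
    made <- 0L
    while (made < n_patches) {
      fi <- sample.int(dim(frames)[3], 1L)
      key <- as.character(fi)
      if (is.null(um_cache[[key]]))
        um_cache[[key]] <- unsharp_mask(frames[, , fi], config$um_sigma,
                                        config$um_k)
      sc <- if (length(config$scales) > 1L)
        sample(config$scales, 1L) else config$scales
      ang <- stats::runif(1, -5, 5)
      shf <- sample(-3:3, 2L, replace = TRUE)
      hr <- .rotate_shift(um_cache[[key]], ang, shf)
      lo <- resize_bicubic(hr, dim(hr) %/% sc)
      up <- resize_bicubic(lo, dim(hr))
      res <- hr - up
      for (p in seq_len(min(patches_per_augmentation, n_patches - made))) {
        ox <- sample.int(nrow(hr) - ps + 1L, 1L)
        oy <- sample.int(ncol(hr) - ps + 1L, 1L)
        made <- made + 1L
        out[[made]] <- list(
          input = up[ox:(ox + ps - 1L), oy:(oy + ps - 1L)],
          target = res[ox:(ox + ps - 1L), oy:(oy + ps - 1L)],
          provenance = list(frame = fi, origin = c(ox, oy), scale = sc,
                            angle = ang, shift = shf))
      }
    }
    out
  })
  structure(pairs, class = "sr_training_pairs")
}

#' Train the residual super-resolution network
#'
#' Mini-batch stochastic gradient descent with momentum on the residual
#' regression loss `||target - f(input)||^2`, with global gradient-norm
#' clipping. A fixed seed reproduces the whole loss trajectory in
#' single-threaded BLAS.
#'
#' @param pairs training pairs from [make_training_pairs()].
#' @param config an [sr_net_config()].
#' @return a trained `sr_network` with per-epoch `loss_history`.
#' @export
train_sr <- function(pairs, config = sr_net_config()) {
  stopifnot(length(pairs) >= 1L)
  net <- .init_sr_network(config)
  ps <- nrow(pairs[[1]]$input)
  n <- length(pairs)
  X <- array(0, c(ps, ps, 1L, n)); Yt <- array(0, c(ps, ps, 1L, n))
  for (i in seq_len(n)) {
    X[, , 1L, i] <- pairs[[i]]$input
    Yt[, , 1L, i] <- pairs[[i]]$target
  }
  vel <- lapply(net$layers, function(ly)
    list(w = array(0, dim(ly$w)), b = numeric(length(ly$b))))
  history <- numeric(config$epochs)
  .with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$lr *
        config$lr_decay^((ep - 1L) %/% config$lr_step)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, n)]
        xb <- X[, , , idx, drop = FALSE]
        yb <- Yt[, , , idx, drop = FALSE]
        fw <- .sr_forward(net, xb, keep = TRUE)
        err <- fw$out - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        losses <- c(losses, loss)
        grads <- .sr_backward(net, fw, 2 * err / length(err))
        gn <- sqrt(sum(vapply(grads, function(g)
          sum(g$gw^2) + sum(g$gb^2), numeric(1))))
        scl <- if (gn > config$clip_norm) config$clip_norm / gn else 1
        for (l in seq_along(net$layers)) {
          vel[[l]]$w <- config$momentum * vel[[l]]$w -
            lr_ep * scl * grads[[l]]$gw
          vel[[l]]$b <- config$momentum * vel[[l]]$b -
            lr_ep * scl * grads[[l]]$gb
          net$layers[[l]]$w <- net$layers[[l]]$w + vel[[l]]$w
          net$layers[[l]]$b <- net$layers[[l]]$b + vel[[l]]$b
        }
      }
      history[ep] <- mean(losses)
    }
  })
  net$loss_history <- history
  net
}

#' Apply the residual network to an image
#'
#' Same-resolution enhancement: returns `image + f(image)`, the skip
#' connection adding the predicted high-frequency residual. A zero network
#' is therefore the identity map.
#'
#' @param network a trained `sr_network`.
#' @param image numeric matrix (finite).
#' @return enhanced matrix of the same shape.
#' @export
apply_sr <- function(network, image) {
  stopifnot(inherits(network, "sr_network"), all(is.finite(image)))
  x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
  fw <- .sr_forward(network, x, keep = FALSE)
  image + fw$out[, , 1L, 1L]
}

#' Apply unsharp masking and the residual network to every frame
#'
#' The projection-domain enhancement chain of the pipeline: each frame is
#' unsharp-masked with the network's configured `um_sigma`/`um_k`, then
#' passed through the skip-connection network.
#'
#' @param network a trained `sr_network`.
#' @param stack a [projection_stack()].
#' @return a [projection_stack()] with enhanced frames, tag suffixed
#'   `"+UM+SR"`.
#' @export
apply_sr_stack <- function(network, stack) {
  stopifnot(inherits(stack, "projection_stack"))
  cfg <- network$config
  f <- stack$frames
  for (a in seq_len(dim(f)[3]))
    f[, , a] <- apply_sr(network, unsharp_mask(f[, , a], cfg$um_sigma,
                                               cfg$um_k))
  projection_stack(f, stack$geometry, paste0(stack$energy_tag, "+UM+SR"),
                   stack$energy_kev)
}

#' Save / load a network checkpoint
#'
#' Single-file checkpoint containing the layer weights, the embedded
#' [sr_net_config()] and the training loss history.
#'
#' @param network an `sr_network`.
#' @param path checkpoint file path.
#' @return `save_sr_network` returns `path` invisibly; `load_sr_network`
#'   returns the `sr_network`.
#' @export
save_sr_network <- function(network, path) {
  stopifnot(inherits(network, "sr_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_sr_network
#' @export
load_sr_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "sr_network"))
  net
}
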