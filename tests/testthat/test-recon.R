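test_that("ramp kernel matches the textbook series and kills DC", {
  h <- ramp_kernel(8, pitch = 2)
  off <- -8:8
  want <- ifelse(off == 0, 1 / (4 * 2^2),
                 ifelse(off %% 2 == 0, 0, -1 / (pi * off * 2)^2))
  expect_equal(h, want, tolerance = 1e-15)
  # filtering a constant row removes (nearly all of) the DC component
  m <- matrix(1, 32, 4)
  filt <- detomo:::.ramp_filter_rows(m, pitch = 1)
  expect_lt(max(abs(filt[9:24, ])), 0.05)  # interior: DC removed
  # an impulse row reproduces the kernel taps (centre of linear convolution)
  imp <- matrix(0, 33, 1); imp[17, 1] <- 1
  got <- detomo:::.ramp_filter_rows(imp, pitch = 1)[, 1]
  expect_equal(got, ramp_kernel(16, 1)[1:33], tolerance = 1e-10)
})

test_that("fbp of a zero stack is a zero volume and kernels are validated", {
  geom <- toy_geometry(n_views = 3L, det = 16L, pitch = 8)
  stack <- projection_stack(array(0, c(16, 16, 3)), geom)
  grid <- recon_grid(c(12, 12, 8), 8)
  expect_true(all(fbp(stack, grid)$values == 0))
  expect_error(fbp(stack, grid, kernel = "shepp-logan"), "unknown kernel")
})

test_that("sart_sweep equals a dense-matrix implementation of the update", {
  geom <- acquisition_geometry(n_views = 2L, detector_shape = c(16L, 16L),
                               pitch = 8)
  grid <- recon_grid(c(16, 16, 16), 6)
  A <- memo("denseA_16", dense_system_matrix(grid, geom))
  set.seed(3)
  x0 <- array(rnorm(prod(grid$shape)), grid$shape)
  truth <- array(0, grid$shape)
  truth[5:12, 5:12, 5:12] <- 0.02
  g <- array(A %*% as.numeric(truth), c(16, 16, 2))
  stack <- projection_stack(g, geom)
  for (lam in c(1, 0.6)) {
    got <- sart_sweep(x0, stack, grid, sart_config(relaxation = lam))
    want <- dense_sart_sweep(as.numeric(x0), A, as.numeric(g), geom, lam)
    expect_lt(max(abs(as.numeric(got) - want)), 1e-10)
  }
})

test_that("consistent data at the true solution leaves SART stationary", {
  geom <- toy_geometry(n_views = 3L, det = 24L, pitch = 8)
  grid <- recon_grid(c(12, 12, 12), 8)
  truth <- array(0, grid$shape)
  truth[4:9, 4:9, 4:9] <- 0.015
  g <- detomo:::.project_volume(truth, grid, geom)
  stack <- projection_stack(g, geom)
  upd <- sart_sweep(truth, stack, grid)
  expect_lt(sqrt(sum((upd - truth)^2)), 1e-6)
})

test_that("tv_norm matches a brute-force evaluation and is homogeneous", {
  brute_tv <- function(v) {
    n <- dim(v); acc <- 0
    at <- function(i, j, k) v[i, j, k]
    for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
      dx <- if (i > 1) at(i, j, k) - at(i - 1, j, k) else 0
      dy <- if (j > 1) at(i, j, k) - at(i, j - 1, k) else 0
      dz <- if (k > 1) at(i, j, k) - at(i, j, k - 1) else 0
      acc <- acc + sqrt(dx^2 + dy^2 + dz^2)
    }
    acc
  }
  expect_equal(tv_norm(array(5, c(3, 3, 3))), 0)
  single <- array(0, c(2, 2, 2)); single[2, 2, 2] <- 1
  expect_equal(tv_norm(single), brute_tv(single), tolerance = 1e-12)
  for (seed in 1:3) {
    set.seed(seed)
    v <- array(rnorm(4^3), c(4, 4, 4))
    expect_equal(tv_norm(v), brute_tv(v), tolerance = 1e-10)
    expect_equal(tv_norm(-2 * v), 2 * tv_norm(v), tolerance = 1e-10)
  }
})

test_that("tv_descent honours its step rule and never increases TV", {
  cfg <- tv_config()
  expect_equal(cfg$beta, 1e-7)
  expect_equal(cfg$n_inner, 20L)
  set.seed(5)
  v <- array(rnorm(8^3), c(8, 8, 8))
  # d_p = 0: exact no-op
  expect_identical(tv_descent(v, v, cfg), v)
  # generic call decreases (or preserves) TV
  v0 <- v + array(rnorm(8^3, sd = 0.1), c(8, 8, 8))
  for (beta in c(1e-7, 1e-3)) {
    out <- tv_descent(v, v0, tv_config(beta = beta))
    expect_lte(tv_norm(out), tv_norm(v) + 1e-12)
  }
})

test_that("the FISTA t-recurrence matches a scalar oracle and extrapolates", {
  z <- array(0, c(2, 2, 2))
  st <- fista_state(z)
  expect_equal(st$t, 1)
  set.seed(6)
  cur <- array(rnorm(8), c(2, 2, 2))
  first <- fista_step(cur, st)
  # t = 1: momentum coefficient 0, extrapolation is the identity
  expect_equal(first$volume, cur)
  expect_equal(first$state$t, (1 + sqrt(5)) / 2, tolerance = 1e-14)
  # 10-step sequence vs an independent scalar loop, strictly increasing
  t_oracle <- 1
  ts <- numeric(10)
  for (m in 1:10) { t_oracle <- (1 + sqrt(1 + 4 * t_oracle^2)) / 2
    ts[m] <- t_oracle }
  st <- fista_state(z); cur2 <- z
  got <- numeric(10)
  for (m in 1:10) { r <- fista_step(cur2, st); st <- r$state
    got[m] <- st$t }
  expect_equal(got, ts, tolerance = 1e-13)
  expect_true(all(diff(got) > 0))
  # t_m ~ (m+1)/2: t_30 within 5% of 15.5
  t30 <- 1
  for (m in 1:29) t30 <- (1 + sqrt(1 + 4 * t30^2)) / 2
  expect_lt(abs(t30 - 15.5) / 15.5, 0.05)
})

test_that("reconstruct drives the residual down on a consistent toy system", {
  # well-sampled toy (9 views over 60 degrees) so 30 iterations suffice
  geom <- acquisition_geometry(n_views = 9L, detector_shape = c(32L, 32L),
                               pitch = 8, swing_deg = 60)
  grid <- recon_grid(c(12, 12, 6), c(8, 8, 12))
  truth <- array(0, grid$shape)
  truth[4:9, 4:9, 2:5] <- 0.02
  truth[6:7, 6:8, 3:4] <- 0.035
  g <- detomo:::.project_volume(truth, grid, geom)
  stack <- projection_stack(g, geom)
  vol <- reconstruct(stack, "sart_tv_fista", grid, log_residual = TRUE)
  res0 <- sqrt(sum(g^2))  # residual of the zero initialisation
  expect_lt(vol$log$residual[nrow(vol$log)], 0.01 * res0)
  # zero stack reconstructs to zero for every method
  zstack <- projection_stack(array(0, dim(g)), geom)
  for (meth in c("fbp", "sart", "sart_tv_fista")) {
    zv <- reconstruct(zstack, meth, grid,
                      sart = sart_config(n_iterations = 2L))
    expect_true(all(zv$values == 0))
  }
  expect_error(reconstruct(stack, "art", grid))
})

test_that("iteration defaults follow the optimised protocol", {
  expect_equal(sart_config()$n_iterations, 24L)
  geom <- toy_geometry(n_views = 2L, det = 8L, pitch = 12)
  stack <- projection_stack(array(0, c(8, 8, 2)), geom)
  grid <- recon_grid(c(6, 6, 4), 10)
  v1 <- reconstruct(stack, "sart_tv_fista", grid)
  expect_equal(nrow(v1$log), 30L)
  v2 <- reconstruct(stack, "sart", grid)
  expect_equal(nrow(v2$log), 24L)
})
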