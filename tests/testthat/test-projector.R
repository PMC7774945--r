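# analytic ray-box intersection length (slab method), mm
ray_box_length <- function(p, q, lo, hi) {
  d <- q - p
  tmin <- 0; tmax <- 1
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return(0)
    } else {
      t1 <- (lo[a] - p[a]) / d[a]; t2 <- (hi[a] - p[a]) / d[a]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  max(0, tmax - tmin) * sqrt(sum(d^2))
}

test_that("an all-air phantom projects to exactly zero", {
  geom <- toy_geometry()
  ph <- voxel_phantom(empty_frac(c(6, 6, 6)), 8)
  expect_true(all(forward_project(ph, geom, 60)$frames == 0))
})

test_that("single-voxel projections match the analytic ray-box oracle", {
  geom <- toy_geometry(n_views = 3L, det = 12L, pitch = 6)
  shape <- c(5, 5, 5); sp <- 8
  fr <- empty_frac(shape)
  fr$soft[3, 2, 4] <- 1
  ph <- voxel_phantom(fr, sp)
  mu <- linear_attenuation(attenuation_basis()$soft, 60)
  got <- forward_project(ph, geom, 60)$frames
  lo <- (c(3, 2, 4) - 1 - shape / 2) * sp
  hi <- lo + sp
  zdet <- -(geom$sdd - geom$sid)
  for (a in 1:3) {
    src <- c(geom$sid * tan(geom$angles_deg[a] * pi / 180), 0, geom$sid)
    for (iu in c(1L, 6L, 12L)) for (iv in c(1L, 7L, 12L)) {
      pix <- c((iu - 0.5 - 6) * geom$pitch, (iv - 0.5 - 6) * geom$pitch,
               zdet)
      want <- mu * ray_box_length(src, pix, lo, hi) * 0.1
      expect_equal(got[iu, iv, a], want, tolerance = 1e-10)
    }
  }
})

test_that("the full-scale profile echoes the system geometry", {
  g <- acquisition_geometry("full")
  expect_equal(g$sid, 924)
  expect_equal(g$sdd, 1100)
  expect_equal(g$swing_deg, 40)
  expect_equal(g$n_views, 37L)
  expect_equal(g$detector_shape, c(1024L, 1024L))
  expect_equal(range(g$angles_deg), c(-20, 20))
})

test_that("projection is linear in the phantom attenuation", {
  geom <- toy_geometry()
  shape <- c(8, 8, 8)
  fa <- empty_frac(shape); fa$soft[2:4, 3:5, 2:6] <- 1
  fb <- empty_frac(shape); fb$bone[6:7, 2:7, 3:4] <- 1
  fab <- empty_frac(shape)
  fab$soft <- fa$soft; fab$bone <- fb$bone
  pa <- forward_project(voxel_phantom(fa, 8), geom, 50)$frames
  pb <- forward_project(voxel_phantom(fb, 8), geom, 50)$frames
  pab <- forward_project(voxel_phantom(fab, 8), geom, 50)$frames
  expect_equal(pab, pa + pb, tolerance = 1e-12)
})

test_that("projector and backprojector are adjoint", {
  for (seed in 1:3) {
    set.seed(seed)
    geom <- toy_geometry(n_views = 3L, det = 16L, pitch = 8)
    grid <- recon_grid(c(16, 16, 16), 6)
    x <- array(rnorm(prod(grid$shape)), grid$shape)
    y <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
    lhs <- sum(detomo:::.project_volume(x, grid, geom) * y)
    rhs <- sum(x * backproject(y, grid, geom)$num)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("dual-energy stacks are ordered, aligned and seed-reproducible", {
  ph <- make_chest_phantom(c(24, 24, 24), 8, seed = 2,
                           nodules = list(list(center = c(0, 30, 0),
                                               diameter = 20)))
  geom <- toy_geometry(n_views = 3L, det = 24L, pitch = 12)
  de <- simulate_dual_energy(ph, geom, 40, 70)
  expect_true(all(de$low$frames >= de$high$frames - 1e-12))
  expect_equal(de$low$energy_tag, "low-kV")
  n1 <- simulate_dual_energy(ph, geom, 40, 70, n0 = 1e6, seed = 42)
  n2 <- simulate_dual_energy(ph, geom, 40, 70, n0 = 1e6, seed = 42)
  expect_identical(n1$low$frames, n2$low$frames)
  expect_identical(n1$high$frames, n2$high$frames)
  n3 <- simulate_dual_energy(ph, geom, 40, 70, n0 = 1e6, seed = 43)
  expect_false(identical(n1$low$frames, n3$low$frames))
  expect_error(simulate_dual_energy(ph, geom, 70, 40), "less than")
  expect_error(simulate_dual_energy(ph, geom, 40, 70, n0 = -1), "positive")
})

test_that("photon noise variance follows the delta-method prediction", {
  # uniform slab, ~1e5 rays: Var[-ln(Poisson(N0 e^-g)/N0)] ~ e^g / N0
  ph <- slab_phantom(c(16, 16, 16), 12)
  geom <- acquisition_geometry(n_views = 2L, detector_shape = c(256L, 256L),
                               pitch = 1.2)
  n0 <- 1e4
  clean <- simulate_dual_energy(ph, geom, 40, 70)
  noisy <- simulate_dual_energy(ph, geom, 40, 70, n0 = n0, seed = 8)
  g <- clean$high$frames
  keep <- g > 0.5  # restrict to rays through the slab
  emp <- mean((noisy$high$frames - g)[keep]^2)
  pred <- mean(exp(g[keep]) / n0)
  expect_lt(abs(emp - pred) / pred, 0.1)
})

test_that("an off-focus feature streaks along the sweep axis", {
  # high-attenuation voxel off the isocenter plane: naive backprojection
  # spreads replicas along the sweep (x) direction on the isocenter slice
  shape <- c(33, 33, 33)
  fr <- empty_frac(shape)
  fr$bone[17, 17, 29] <- 1
  ph <- voxel_phantom(fr, 4)
  geom <- acquisition_geometry(n_views = 7L, detector_shape = c(64L, 64L),
                               pitch = 4)
  stack <- forward_project(ph, geom, 60)
  grid <- recon_grid(shape, 4)
  bp <- backproject(stack$frames, grid, geom)
  naive <- bp$num
  naive[bp$den > 1e-9] <- naive[bp$den > 1e-9] / bp$den[bp$den > 1e-9]
  slice <- naive[, , 17]  # isocenter plane, away from the voxel's plane
  energy_sweep <- sum(slice[, 17]^2)
  energy_ortho <- sum(slice[17, ]^2)
  expect_gt(energy_sweep, 2 * energy_ortho)
})
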