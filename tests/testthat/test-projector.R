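test_that("psf width model is linear in distance and fits two points", {
  m <- tiny_model(sigma0 = 3, slope = 0.02)
  expect_equal(psf_sigma(0, m), 3)
  expect_equal(psf_sigma(c(100, 300), m), c(5, 9))
  expect_error(psf_sigma(-1, m), "non-negative")
  m0 <- tiny_model(slope = 0)
  expect_equal(psf_sigma(c(0, 50, 500), m0), rep(4, 3))
  # two-point FWHM solve reproduces both calibration points
  fit <- psf_from_fwhm(100, 14, 300, 26)
  k <- 2 * sqrt(2 * log(2))
  expect_equal(fit$sigma0_mm + fit$slope_mm_per_mm * 100, 14 / k,
               tolerance = 1e-9)
  expect_equal(fit$sigma0_mm + fit$slope_mm_per_mm * 300, 26 / k,
               tolerance = 1e-9)
})

test_that("forward projection handles degenerate inputs", {
  m <- tiny_model()
  z <- array(0, c(16, 16, 16))
  expect_true(all(forward_project(z, m) == 0))
  expect_error(forward_project(array(0, c(4, 4, 4)), m), "grid")
})

test_that("a centred hot voxel projects to one bin with the exact count scale", {
  n <- 15 # odd: the centre voxel is the rotation axis
  g <- voxel_grid(c(n, n, n), 6)
  acq <- acquisition_spec(n_projections = 6, bin_mm = 6, matrix = c(n, n),
                          orbit_mm = 100, t_p = 7, sensitivity = 11)
  m <- system_model(acq, g, resolution = FALSE, attenuation = FALSE)
  act <- array(0, c(n, n, n))
  act[8, 8, 8] <- 2.5
  sino <- forward_project(act, m)
  for (v in 1:6) {
    p <- sino[, , v]
    expect_equal(sum(p > 1e-9), 1)
    expect_equal(max(p), 2.5 * 11 * 7, tolerance = 1e-9)
  }
})

test_that("attenuation through a uniform slab follows Beer-Lambert", {
  n <- 16
  g <- voxel_grid(c(n, n, n), 6)
  acq <- acquisition_spec(n_projections = 1, bin_mm = 6, matrix = c(n, n),
                          angles_deg = 0, orbit_mm = 120, t_p = 1,
                          sensitivity = 1)
  act <- array(0, c(n, n, n))
  act[8, 4, 8] <- 1 # source plane y = 4
  mu_val <- 0.15
  mu <- array(0, c(n, n, n))
  mu[, 6:13, ] <- mu_val # slab of 8 planes between source and detector
  m_att <- system_model(acq, g, mu = mu, resolution = FALSE)
  m_free <- system_model(acq, g, resolution = FALSE, attenuation = FALSE)
  ratio <- sum(forward_project(act, m_att)) / sum(forward_project(act, m_free))
  L_cm <- 8 * 0.6
  expect_equal(ratio, exp(-mu_val * L_cm), tolerance = 0.01)
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(7)
  mu <- array(runif(16^3, 0, 0.15), c(16, 16, 16))
  m <- tiny_model(mu = mu)
  x <- array(runif(16^3), c(16, 16, 16))
  y <- array(runif(16 * 16 * 8), c(16, 16, 8))
  lhs <- sum(forward_project(x, m) * y)
  rhs <- sum(x * back_project(y, m))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # and with rebinning to coarser detector bins
  g <- voxel_grid(c(16, 16, 16), 6)
  acq <- acquisition_spec(n_projections = 5, bin_mm = 12, matrix = c(8, 8),
                          orbit_mm = 130, t_p = 3, sensitivity = 2)
  m2 <- system_model(acq, g, mu = mu, sigma0_mm = 5, slope_mm_per_mm = 0.02)
  y2 <- array(runif(8 * 8 * 5), c(8, 8, 5))
  lhs2 <- sum(forward_project(x, m2) * y2)
  rhs2 <- sum(x * back_project(y2, m2))
  expect_lt(abs(lhs2 - rhs2) / abs(lhs2), 1e-6)
})

test_that("projection is linear", {
  m <- tiny_model(mu = array(0.1, c(16, 16, 16)))
  x <- inscribed_volume(seed = 2)
  y <- inscribed_volume(seed = 3)
  p <- forward_project(2 * x + 3 * y, m)
  expect_equal(p, 2 * forward_project(x, m) + 3 * forward_project(y, m),
               tolerance = 1e-12)
})

test_that("counts are conserved per view without attenuation or blur", {
  m <- tiny_model(resolution = FALSE, attenuation = FALSE)
  x <- inscribed_volume()
  sino <- forward_project(x, m)
  per_view <- apply(sino, 3, sum)
  expected <- sum(x) * m$acquisition$sensitivity * m$acquisition$t_p
  expect_true(all(abs(per_view / expected - 1) < 0.005))
})

test_that("backprojection of a uniform sinogram is four-fold symmetric", {
  m <- tiny_model(n_views = 8, resolution = FALSE, attenuation = FALSE)
  vol <- back_project(array(1, c(16, 16, 8)), m)
  # rotate the volume 90 degrees in-plane: x -> y, y -> reversed x
  rot90 <- aperm(vol, c(2, 1, 3))[, 16:1, ]
  expect_lt(max(abs(vol - rot90)) / max(vol), 1e-6)
  expect_error(back_project(array(0, c(4, 4, 2)), m), "inconsistent")
})
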