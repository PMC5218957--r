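mw_from <- function(pw, lsw = NULL, usw = NULL) {
  structure(list(pw = pw, lsw = lsw, usw = usw, windows = energy_windows(),
                 poisson = FALSE), class = "mw_sinogram")
}

test_that("TEW estimate reproduces the trapezoid arithmetic", {
  d <- c(4, 3, 2)
  # with the study windows (w_ls 34.0, w_us 50.7, w_pw 41.6 keV),
  # C_ls = 34 and C_us = 50.7 give C_s = (1 + 1) * 41.6 / 2 = 41.6
  mw <- mw_from(array(100, d), array(34, d), array(50.7, d))
  est <- tew_estimate(mw)
  expect_equal(est$C_s, array(41.6, d), tolerance = 1e-12)
  expect_true(all(tew_estimate(mw_from(array(5, d), array(0, d),
                                       array(0, d)))$C_s == 0))
  expect_error(tew_estimate(mw_from(array(5, d))), "scatter windows")
  # independent per-bin loop oracle on random windows
  set.seed(4)
  lsw <- array(runif(prod(d), 0, 50), d)
  usw <- array(runif(prod(d), 0, 50), d)
  est2 <- tew_estimate(mw_from(array(100, d), lsw, usw))$C_s
  w <- energy_windows()
  for (i in seq_len(prod(d)))
    expect_equal(est2[i], (lsw[i] / w$w_ls + usw[i] / w$w_us) * w$w_pw / 2)
})

test_that("primary counts subtract the scatter estimate with a zero floor", {
  d <- c(3, 3, 1)
  est <- structure(list(C_s = array(41.6, d), method = "tew"),
                   class = "tew_estimate")
  expect_equal(primary_counts(array(100, d), est), array(58.4, d))
  est0 <- structure(list(C_s = array(0, d), method = "tew"),
                    class = "tew_estimate")
  expect_equal(primary_counts(array(7, d), est0), array(7, d))
  big <- structure(list(C_s = array(10, d), method = "tew"),
                   class = "tew_estimate")
  expect_true(all(primary_counts(array(4, d), big) == 0))
  expect_error(primary_counts(array(1, c(2, 2, 1)), est), "shapes differ")
})

test_that("OSEM converges to the fixed point of a single-voxel system", {
  g <- voxel_grid(c(1, 1, 1), 10)
  acq <- acquisition_spec(n_projections = 1, bin_mm = 10, matrix = c(1, 1),
                          angles_deg = 0, orbit_mm = 50, t_p = 1,
                          sensitivity = 1)
  m <- system_model(acq, g, resolution = FALSE, attenuation = FALSE)
  rec <- osem(array(7, c(1, 1, 1)), m, cfg = osem_config(1, 6))
  expect_equal(as.numeric(rec$counts), 7, tolerance = 1e-6)
})

test_that("noiseless matched-model reconstruction recovers total activity", {
  # inverse-crime control: simulate and reconstruct with the same model and
  # the exact scatter term
  n <- 24
  g <- voxel_grid(c(n, n, n), 6)
  acq <- acquisition_spec(n_projections = 20, bin_mm = 6, matrix = c(n, n),
                          orbit_mm = 150, t_p = 10, sensitivity = 8)
  ph <- build_phantom(study_config("ctrl", list(
    insert_spec("sphere", c(-15, 0, 0), 20, 2, "a"),
    insert_spec("cylinder", c(20, 5, 0), 12, 3, "b")), medium = "air"), g)
  mu <- array(mu_for_material("water") * 0.5, c(n, n, n)) # uniform medium
  m <- system_model(acq, g, mu = mu)
  primary <- forward_project(ph$activity, m)
  st <- simulate_scatter(primary, scatter_params(0.2, 40, 0.03),
                         energy_windows(), 6)
  mw <- structure(list(pw = primary + st$S_true + st$H_true, lsw = st$lsw,
                       usw = st$usw, truth = st, acquisition = acq,
                       windows = energy_windows(), poisson = FALSE),
                  class = "mw_sinogram")
  rec <- osem(mw, m, scatter = ideal_scatter(mw), cfg = osem_config(5, 6))
  A_hat <- sum(rec$counts) / (acq$sensitivity * acq$t_p * acq$n_projections)
  expect_lt(abs(A_hat - sum(ph$activity)) / sum(ph$activity), 0.01)
  # uncorrected reconstruction overestimates scatter-contaminated data
  rec_none <- osem(mw, m, scatter = NULL, cfg = osem_config(5, 6))
  expect_gt(sum(rec_none$counts), sum(rec$counts))
})

test_that("OSEM iterates stay nonnegative and leave exact zeros at zero", {
  m <- tiny_model(n_views = 8, mu = array(0.05, c(16, 16, 16)))
  x <- inscribed_volume(seed = 5)
  sino <- forward_project(x, m)
  init <- array(1, c(16, 16, 16))
  init[1:4, , ] <- 0
  rec <- osem(sino, m, cfg = osem_config(4, 2), init = init)
  expect_true(all(rec$counts >= 0))
  expect_true(all(rec$counts[1:4, , ] == 0))
})

test_that("TEW and ideal corrections agree at high counts with zero curvature", {
  n <- 24
  g <- voxel_grid(c(n, n, n), 6)
  acq <- acquisition_spec(n_projections = 20, bin_mm = 6, matrix = c(n, n),
                          orbit_mm = 150, t_p = 10, sensitivity = 10)
  ph <- build_phantom(study_config("hc", list(
    insert_spec("sphere", c(0, 0, 0), 60, 30, "a")), medium = "air"), g)
  m <- system_model(acq, g, mu = array(0.1, c(n, n, n)))
  primary <- forward_project(ph$activity, m)
  st <- simulate_scatter(primary, scatter_params(0.25, 40, 0.03,
                                                 spectral_curvature = 0),
                         energy_windows(), 6)
  pw <- primary + st$S_true + st$H_true
  expect_gt(sum(pw), 1e6) # high-count regime
  mw <- structure(list(pw = add_poisson(pw, 2), lsw = add_poisson(st$lsw, 3),
                       usw = add_poisson(st$usw, 4), truth = st,
                       acquisition = acq, windows = energy_windows(),
                       poisson = TRUE), class = "mw_sinogram")
  r_tew <- osem(mw, m, scatter = tew_estimate(mw), cfg = osem_config(5, 6))
  r_ideal <- osem(mw, m, scatter = ideal_scatter(mw), cfg = osem_config(5, 6))
  expect_lt(abs(sum(r_tew$counts) - sum(r_ideal$counts)) /
              sum(r_ideal$counts), 0.02)
})
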