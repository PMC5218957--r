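# Shared fixtures. The full-scale quantification study and the CNF study
# are expensive, so they are computed once on first use and cached for the
# whole test session.

.lq_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .lq_cache)) assign(name, expr, envir = .lq_cache)
  get(name, envir = .lq_cache)
}

# small projector test rig: 16^3 grid, 8 views
tiny_model <- function(n = 16, n_views = 8, voxel = 6, mu = NULL,
                       resolution = TRUE, attenuation = !is.null(mu),
                       sigma0 = 4, slope = 0.01, t_p = 5, sens = 10,
                       orbit = 120) {
  g <- voxel_grid(c(n, n, n), voxel)
  acq <- acquisition_spec(n_projections = n_views, bin_mm = voxel,
                          matrix = c(n, n), orbit_mm = orbit, t_p = t_p,
                          sensitivity = sens)
  system_model(acq, g, mu = mu, sigma0_mm = sigma0,
               slope_mm_per_mm = slope, attenuation = attenuation,
               resolution = resolution)
}

# volume with random content restricted to the inscribed cylinder (mass
# outside it is clipped by the rotating field of view)
inscribed_volume <- function(n = 16, seed = 1) {
  set.seed(seed)
  vol <- array(runif(n^3), c(n, n, n))
  cx <- (n - 1) / 2
  r2 <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2, "+")
  mask <- r2 <= (0.45 * n)^2
  vol * array(rep(mask, n), c(n, n, n))
}

# the full eight-configuration study at the acceptance problem size
acceptance_study <- function() {
  cached("study", run_study(configs = lu_study_presets(),
                            geom = study_geometry(), seed = 42,
                            n_realizations = 5, scatter_methods = "tew"))
}

# isotropic 3D Gaussian blur (separable; reuses the package's plane kernel;
# the singleton second plane axis makes each pass one-dimensional)
blur1d <- function(vol, sigma_vox, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dp <- dim(v)
  b <- luquant:::.lq_blur_planes(array(v, c(dp[1], 1, dp[2] * dp[3])),
                                 c(dp[1], 1L, dp[2] * dp[3]), sigma_vox)
  aperm(array(b, dp), order(perm))
}

blur3d <- function(vol, sigma_vox) {
  blur1d(blur1d(blur1d(vol, sigma_vox, 1), sigma_vox, 2), sigma_vox, 3)
}

# synthetic "reconstruction-like" activity image: blurred insert on a
# uniform background pedestal (MBq per voxel)
synthetic_scan <- function(grid, insert, sbr, sigma_mm = 9) {
  mask <- rasterize_insert(grid, insert)$mask
  conc <- insert$concentration
  bg <- if (is.finite(sbr)) conc / sbr else 0
  img <- (bg + (conc - bg) * mask) * grid$voxel_ml
  blur3d(img, sigma_mm / grid$voxel_mm)
}

cnf_result_for_test <- function(v) {
  structure(list(value = v, method = "planar2", provenance = list()),
            class = "cnf_result")
}

acceptance_cnf <- function() {
  cached("cnf", cnf_study(study_geometry(), seed = 42))
}
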