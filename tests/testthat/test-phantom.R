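test_that("sphere and cylinder rasterization reproduce nominal volumes", {
  g <- voxel_grid(c(100, 100, 90), 2.4)
  # largest study sphere (113 ml)
  r <- rasterize_insert(g, insert_spec("sphere", c(0, 0, 0), 113, 3.19, "S6"))
  expect_lt(abs(r$volume_ml - 113) / 113, 0.01)
  # cylinder against the analytic pi r^2 h volume
  ins <- insert_spec("cylinder", c(20, 10, 0), 34, 1, "T1")
  expect_equal(pi * ins$radius_mm^2 * 2 * ins$half_height_mm / 1000, 34,
               tolerance = 1e-10)
  r2 <- rasterize_insert(g, ins)
  expect_lt(abs(r2$volume_ml - 34) / 34, 0.01)
  # all-fractional values stay in [0, 1]
  expect_true(all(r2$mask >= 0 & r2$mask <= 1))
})

test_that("degenerate and out-of-grid inserts are handled", {
  g <- voxel_grid(c(20, 20, 20), 4)
  vanishing <- insert_spec("sphere", c(0, 0, 0), 1e-12, 1, "dot")
  expect_equal(sum(suppressWarnings(rasterize_insert(g, vanishing))$mask), 0)
  outside <- insert_spec("sphere", c(38, 0, 0), 8, 1, "edge")
  expect_error(rasterize_insert(g, outside), "edge")
})

test_that("attenuation coefficients are physical", {
  expect_lt(mu_for_material("air"), 1e-4)
  # independent check: log-log interpolation of water mass-attenuation
  # table values around the photopeak energy (cm^2/g), times 1.0 g/cm^3
  E <- c(150, 200, 300)
  mu_rho <- c(0.1505, 0.1370, 0.1186)
  oracle <- exp(approx(log(E), log(mu_rho), xout = log(208))$y)
  expect_equal(mu_for_material("water"), oracle, tolerance = 0.02)
  expect_true(mu_for_material("bone") > mu_for_material("water"))
  expect_true(mu_for_material("water") > mu_for_material("lung"))
  expect_true(mu_for_material("lung") > mu_for_material("air"))
  expect_error(mu_for_material("cheese"), "unknown")
})

test_that("built phantoms conserve activity and carry the configured background", {
  g <- voxel_grid(c(100, 100, 90), 2.4)
  cfgs <- lu_study_presets()
  ph <- build_phantom(cfgs$spheres_warm_water, g)
  # background voxels carry 0.49 MBq/ml * voxel volume
  bg <- ph$material == "water" &
    Reduce(`+`, ph$insert_masks) < 1e-9 & ph$activity > 0
  expect_gt(sum(bg), 1000)
  # interior background voxels (fully inside the body solid) carry exactly
  # the configured concentration; boundary voxels are fractional
  conc <- ph$activity[bg] / g$voxel_ml
  expect_equal(max(conc), 0.49, tolerance = 1e-9)
  expect_gt(mean(abs(conc - 0.49) < 1e-9), 0.9)
  # summation oracle: total = sum of insert truths + background total
  bg_total <- sum(ph$activity) - sum(ph$truth$true_MBq)
  expect_equal(sum(ph$activity),
               sum(ph$truth$true_MBq) + bg_total, tolerance = 1e-12)
  expect_true(all(ph$truth$true_MBq > 0))
  # per-insert activity within 1% of nominal volume x concentration
  for (i in seq_along(cfgs$spheres_warm_water$inserts)) {
    ins <- cfgs$spheres_warm_water$inserts[[i]]
    expect_lt(abs(ph$truth$true_MBq[i] - ins$volume_ml * ins$concentration) /
                (ins$volume_ml * ins$concentration), 0.01)
  }
  # air config: background identically zero
  pha <- build_phantom(cfgs$spheres_air, g)
  expect_equal(sum(pha$activity), sum(pha$truth$true_MBq), tolerance = 1e-12)
})

test_that("warm-config SBR equals the configured concentration ratio", {
  cfgs <- lu_study_presets()
  expect_equal(config_sbr(cfgs$bottles_warm_water, digits = NULL),
               5.11 / 0.104)
  expect_error(config_sbr(cfgs$spheres_air), "no background")
})

test_that("phantom construction is deterministic and rejects overlaps", {
  g <- voxel_grid(c(40, 40, 30), 4.8)
  cf <- study_config("t", list(
    insert_spec("sphere", c(-20, 0, 0), 8, 1, "a"),
    insert_spec("sphere", c(25, 0, 0), 8, 1, "b")), medium = "air")
  p1 <- suppressWarnings(build_phantom(cf, g))
  p2 <- suppressWarnings(build_phantom(cf, g))
  expect_identical(p1$activity, p2$activity)
  expect_identical(p1$mu, p2$mu)
  bad <- study_config("t2", list(
    insert_spec("sphere", c(0, 0, 0), 8, 1, "a"),
    insert_spec("sphere", c(5, 0, 0), 8, 1, "b")), medium = "air")
  expect_error(suppressWarnings(build_phantom(bad, g)), "overlap")
})

test_that("downsampling preserves means and sums", {
  v <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  expect_equal(sum(downsample_volume(v, 2, average = FALSE)), sum(v))
  expect_equal(mean(downsample_volume(v, 2, average = TRUE)), mean(v))
  expect_equal(dim(downsample_volume(v, 2)), c(4L, 3L, 2L))
})
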