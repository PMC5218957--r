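test_that("reference value is the mean of the 9 hottest VOI voxels", {
  img <- array(0, c(5, 5, 5))
  voi <- array(TRUE, c(5, 5, 5))
  img[voi] <- 3
  expect_equal(reference_value(img, voi), 3)
  img2 <- array(0, c(4, 5, 1))
  img2[1:20] <- 1:20
  expect_equal(reference_value(img2, array(TRUE, c(4, 5, 1))), mean(12:20))
  # adding a voxel below the current ninth maximum leaves the value fixed
  img3 <- array(c(1:20, 5), c(21, 1, 1))
  expect_equal(reference_value(img3, array(TRUE, c(21, 1, 1))), mean(12:20))
  expect_error(reference_value(img, array(c(rep(TRUE, 5), rep(FALSE, 120)),
                                          c(5, 5, 5))), "at least 9")
})

test_that("fixed-threshold masks match a brute-force voxel scan", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  img <- synthetic_scan(g, ins, sbr = Inf)
  voi <- array(TRUE, g$shape)
  s <- fixed_threshold_segment(img, voi, 0.40, g$voxel_ml)
  ref <- reference_value(img, voi)
  manual <- array(FALSE, g$shape)
  for (i in seq_along(img)) manual[i] <- img[i] >= 0.40 * ref
  expect_identical(s$mask, manual)
  expect_equal(s$activity_MBq, sum(img[manual]))
  # a vanishing threshold keeps the whole VOI on a positive image
  tiny <- fixed_threshold_segment(img + 1e-9, voi, 1e-9, g$voxel_ml)
  expect_true(all(tiny$mask))
  expect_error(fixed_threshold_segment(img, voi, 1.2, g$voxel_ml))
})

test_that("CT-based segmentation uses the physical geometry", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  mask <- rasterize_insert(g, ins)$mask
  img0 <- mask * 2 * g$voxel_ml # noiseless, unblurred
  s0 <- ct_based_segment(img0, mask, g$voxel_ml)
  # volume and mask are consistent and match the physical volume to within
  # the boundary-voxel discretization of the grid
  expect_equal(s0$volume_ml, sum(s0$mask) * g$voxel_ml)
  expect_lt(abs(s0$volume_ml - 34) / 34, 0.05)
  # summation oracle; recovery is exact up to the partial activity sitting
  # in boundary voxels whose centres fall outside the contour (the boundary
  # shell of a 34 ml sphere holds ~10% of its volume at this grid pitch)
  expect_equal(s0$activity_MBq, sum(img0[mask >= 0.5]))
  expect_lt(abs(s0$activity_MBq - 2 * 34) / (2 * 34), 0.10)
  # blur spills counts out: CT-restricted activity underestimates
  imgb <- blur3d(img0, 2)
  sb <- ct_based_segment(imgb, mask, g$voxel_ml)
  expect_lt(sb$activity_MBq, sum(img0))
  expect_error(ct_based_segment(imgb, array(0, g$shape), g$voxel_ml))
})

make_synthetic_curves <- function(grid, insert, sbrs = c(14, 8, 5.3, 4.1),
                                  sigma_mm = 9) {
  voi <- array(TRUE, grid$shape)
  scans <- lapply(sbrs, function(s) {
    img <- synthetic_scan(grid, insert, s, sigma_mm = sigma_mm)
    mask <- rasterize_insert(grid, insert)$mask
    list(image = img, voxel_ml = grid$voxel_ml, sbr = s,
         inserts = list(list(label = insert$label, voi = voi,
                             true_volume_ml = sum(mask) * grid$voxel_ml,
                             true_activity_MBq = insert$concentration *
                               sum(mask) * grid$voxel_ml)))
  })
  build_iadt_curves(scans)
}

test_that("IADT calibration curves are physically ordered and exact at knots", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  cv <- make_synthetic_curves(g, ins)
  k <- cv$knots
  expect_true(all(k$f_vol > 0 & k$f_vol < 1))
  expect_true(all(k$f_act > 0 & k$f_act < 1))
  # threshold fractions rise as the background pedestal rises (lower SBR)
  expect_true(all(diff(k$f_act) < 0)) # knots sorted by increasing SBR
  expect_true(all(diff(k$f_vol) < 0))
  # querying at a calibrated SBR returns the stored fraction exactly
  got <- iadt_lookup(cv, k$sbr[2])
  expect_equal(got$f_vol, k$f_vol[2], tolerance = 1e-12)
  expect_equal(got$f_act, k$f_act[2], tolerance = 1e-12)
  # clamped extrapolation
  expect_equal(iadt_lookup(cv, 1e6)$f_act, k$f_act[nrow(k)])
  expect_equal(iadt_lookup(cv, 1e-3)$f_act, k$f_act[1])
  expect_error(build_iadt_curves(list()), "at least two")
})

test_that("IADT recovers its own calibration insert and is deterministic", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  cv <- make_synthetic_curves(g, ins)
  voi <- array(TRUE, g$shape)
  img <- synthetic_scan(g, ins, 8)
  truth <- ins$concentration * sum(rasterize_insert(g, ins)$mask) * g$voxel_ml
  s1 <- iadt_segment(img, voi, cv, g$voxel_ml)
  s2 <- iadt_segment(img, voi, cv, g$voxel_ml)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$activity_MBq, s2$activity_MBq)
  expect_true(s1$converged)
  # recovery on the method's own calibration scan; the residual comes from
  # the interpolated-curve fixed point landing near, not exactly on, the
  # calibration knot
  expect_lt(abs(quant_error(s1$activity_MBq, truth)), 5)
})

test_that("a backgroundless image clamps IADT to the highest-SBR knot", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  cv <- make_synthetic_curves(g, ins)
  voi <- array(TRUE, g$shape)
  img <- synthetic_scan(g, ins, Inf)
  s <- iadt_segment(img, voi, cv, g$voxel_ml)
  k <- cv$knots[nrow(cv$knots), ]
  expect_equal(s$f_vol, k$f_vol)
  expect_equal(s$f_act, k$f_act)
  # equals a fixed dual-threshold segmentation at the clamped fractions
  ref <- reference_value(img, voi)
  expect_identical(s$mask, voi & (img >= k$f_vol * ref))
  expect_equal(s$activity_MBq, sum(img[voi & (img >= k$f_act * ref)]))
})

test_that("segmented activity never exceeds the VOI total", {
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  img <- synthetic_scan(g, ins, 6)
  voi <- array(TRUE, g$shape)
  cv <- make_synthetic_curves(g, ins)
  for (s in list(fixed_threshold_segment(img, voi, 0.40, g$voxel_ml),
                 iadt_segment(img, voi, cv, g$voxel_ml),
                 ct_based_segment(img, rasterize_insert(g, ins)$mask,
                                  g$voxel_ml)))
    expect_lte(s$activity_MBq, sum(img[voi]) + 1e-12)
})

test_that("warm-background accuracy orders 40% <= CT <= IADT", {
  # at reconstruction-scale resolution (PSF sigma near the object radius)
  # the 40% cut loses spill-out badly, the true-geometry mask loses only
  # the boundary spill, and the adaptive dual threshold compensates best --
  # the ordering reported for the warm-background scans
  g <- voxel_grid(c(30, 30, 30), 4.8)
  ins <- insert_spec("sphere", c(0, 0, 0), 34, 2, "s")
  cv <- make_synthetic_curves(g, ins, sigma_mm = 14)
  voi <- array(TRUE, g$shape)
  img <- synthetic_scan(g, ins, 6, sigma_mm = 14)
  mask <- rasterize_insert(g, ins)$mask
  truth <- ins$concentration * sum(mask) * g$voxel_ml
  e40 <- quant_error(fixed_threshold_segment(img, voi, 0.40,
                                             g$voxel_ml)$activity_MBq, truth)
  ect <- quant_error(ct_based_segment(img, mask, g$voxel_ml)$activity_MBq,
                     truth)
  eia <- quant_error(iadt_segment(img, voi, cv, g$voxel_ml)$activity_MBq,
                     truth)
  expect_lte(abs(ect), abs(e40))
  expect_lte(abs(eia), abs(ect))
})
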