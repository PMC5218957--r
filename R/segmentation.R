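#' Reference value of a volume of interest
#'
#' The mean of the 9 voxels with the highest values inside the VOI; all
#' threshold fractions are taken relative to this value. Ties are broken by
#' value only, so any 9 maximal values give the same mean.
#'
#' @param image 3D array.
#' @param voi logical array, at least 9 voxels.
#' @return scalar reference value.
#' @export
reference_value <- function(image, voi) {
  v <- image[voi]
  if (length(v) < 9) stop("VOI must contain at least 9 voxels")
  mean(sort(v, decreasing = TRUE)[1:9])
}

seg_result <- function(mask, voxel_ml, activity, method, sbr_estimate = NA,
                       converged = TRUE, extra = list()) {
  structure(c(list(mask = mask, volume_ml = sum(mask) * voxel_ml,
                   activity_MBq = activity, sbr_estimate = sbr_estimate,
                   method = method, converged = converged,
                   empty = !any(mask)), extra),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> %s: %.2f ml, %.2f MBq%s\n", x$method,
              x$volume_ml, x$activity_MBq,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Fixed-threshold segmentation
#'
#' Voxels inside the VOI at or above `fraction` times the 9-hottest-voxel
#' reference value. The study protocol uses 0.1% in air, 1% in cold water
#' (both low cuts chosen to capture counts spilled outside the physical
#' boundary) and 40% in radioactive background.
#'
#' @param image activity (or count) volume.
#' @param voi logical VOI array.
#' @param fraction threshold fraction in (0, 1).
#' @param voxel_ml voxel volume in ml.
#' @return a `seg_result`; an empty mask is flagged in `$empty`.
#' @export
fixed_threshold_segment <- function(image, voi, fraction, voxel_ml) {
  stopifnot(fraction > 0, fraction < 1)
  ref <- reference_value(image, voi)
  mask <- voi & (image >= fraction * ref)
  seg_result(mask, voxel_ml, sum(image[mask]), "fixed",
             extra = list(fraction = fraction, reference = ref))
}

#' CT-based (true geometry) segmentation
#'
#' Sums the image over the voxels of the physical insert geometry:
#' `true_mask` is the insert's fractional-fill mask resampled to the
#' reconstruction grid, binarized at half occupancy (voxel centres inside
#' the CT contour), so the segmented volume matches the physical volume to
#' within the boundary-voxel discretization. Spill beyond the physical
#' boundary is lost, so blurred objects are underestimated — the
#' characteristic partial-volume penalty of true-geometry segmentation.
#'
#' @param image activity volume.
#' @param true_mask fractional (0..1) physical-geometry mask on the same
#'   grid.
#' @param voxel_ml voxel volume in ml.
#' @return a `seg_result`.
#' @export
ct_based_segment <- function(image, true_mask, voxel_ml) {
  if (!identical(dim(image), dim(true_mask))) stop("grid mismatch")
  mask <- true_mask >= 0.5
  if (!any(mask)) stop("physical mask is empty after resampling")
  structure(list(mask = mask,
                 volume_ml = sum(mask) * voxel_ml,
                 activity_MBq = sum(image[mask]),
                 sbr_estimate = NA, method = "ct", converged = TRUE,
                 empty = FALSE),
            class = "seg_result")
}

# 6-neighbour binary dilation by one voxel
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

# SBR estimate: 9-hottest reference in the VOI over the mean of background
# voxels (VOI voxels at least one voxel clear of the current mask and, when
# a body mask is given, inside the attenuating body). Without the body
# restriction the background reading would depend on how much of the VOI
# falls outside the phantom/patient contour, i.e. on where the object sits.
measure_sbr <- function(image, voi, mask, body = NULL) {
  ref <- reference_value(image, voi)
  bg <- voi & !dilate_mask(mask)
  if (!is.null(body)) bg <- bg & body
  if (!any(bg)) return(Inf)
  m <- mean(image[bg])
  if (m <= ref * 1e-9) return(Inf)
  ref / m
}

# largest/smallest fraction reproducing a target by bisection on the
# monotone-decreasing profile value(fraction); NA if no crossing
bisect_fraction <- function(profile, target, lo = 0.02, hi = 0.98,
                            iters = 40) {
  vlo <- profile(lo)
  vhi <- profile(hi)
  if (target > vlo || target < vhi) return(NA_real_)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (profile(mid) >= target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build IADT calibration curves
#'
#' For every calibration scan and insert, finds by bisection the threshold
#' fraction that reproduces the true insert volume and the fraction that
#' reproduces the true insert activity, then aggregates (median across
#' inserts) into one volume curve and one activity curve as functions of the
#' signal-to-background ratio. The curve abscissa is the SBR measured in the
#' calibration image with the same estimator the segmenter applies at query
#' time (the true SBR is kept as provenance). Interpolation is piecewise
#' linear in log(SBR) with clamped extrapolation.
#'
#' @param scans list of calibration scans; each a list with `image`
#'   (activity volume), `voxel_ml`, `sbr` (true SBR), optionally `body` (a
#'   logical body-contour mask restricting the background sample), and
#'   `inserts`: a list of
#'   `list(label, voi, true_volume_ml, true_activity_MBq)`.
#' @return object of class `iadt_curves` with a `knots` data.frame
#'   (`sbr`, `sbr_true`, `f_vol`, `f_act`) and per-insert `detail`.
#' @export
build_iadt_curves <- function(scans) {
  if (length(scans) < 2) stop("at least two SBR levels are required")
  detail <- list()
  knots <- data.frame()
  for (sc in scans) {
    rows <- data.frame()
    for (ins in sc$inserts) {
      ref <- reference_value(sc$image, ins$voi)
      volf <- function(f) sum(ins$voi & (sc$image >= f * ref)) * sc$voxel_ml
      actf <- function(f) sum(sc$image[ins$voi & (sc$image >= f * ref)])
      f_v <- bisect_fraction(volf, ins$true_volume_ml)
      f_a <- bisect_fraction(actf, ins$true_activity_MBq)
      if (is.na(f_v) || is.na(f_a)) {
        warning(sprintf("insert '%s' at SBR %.1f excluded: no threshold reproduces truth",
                        ins$label, sc$sbr))
        next
      }
      mask_v <- ins$voi & (sc$image >= f_v * ref)
      sbr_m <- measure_sbr(sc$image, ins$voi, mask_v, sc$body)
      rows <- rbind(rows, data.frame(label = ins$label, sbr_true = sc$sbr,
                                     sbr_measured = sbr_m, f_vol = f_v,
                                     f_act = f_a))
    }
    if (nrow(rows) == 0)
      stop(sprintf("no usable inserts at SBR %.1f", sc$sbr))
    detail[[length(detail) + 1]] <- rows
    knots <- rbind(knots, data.frame(
      sbr = median(rows$sbr_measured), sbr_true = sc$sbr,
      f_vol = median(rows$f_vol), f_act = median(rows$f_act)))
  }
  knots <- knots[order(knots$sbr), ]
  if (any(knots$f_vol <= 0 | knots$f_vol >= 1) ||
      any(knots$f_act <= 0 | knots$f_act >= 1))
    stop("calibration produced fractions outside (0, 1)")
  structure(list(knots = knots, detail = do.call(rbind, detail)),
            class = "iadt_curves")
}

#' Look up the IADT threshold fractions at an SBR
#'
#' Piecewise-linear in log(SBR); outside the calibrated range the nearest
#' knot is used (clamped extrapolation).
#'
#' @param curves an [build_iadt_curves()] result.
#' @param sbr signal-to-background ratio (may be `Inf`: clamps to the
#'   highest knot).
#' @return list with `f_vol` and `f_act`.
#' @export
iadt_lookup <- function(curves, sbr) {
  stopifnot(inherits(curves, "iadt_curves"))
  k <- curves$knots
  x <- log(pmin(pmax(sbr, min(k$sbr)), max(k$sbr)))
  list(f_vol = approx(log(k$sbr), k$f_vol, xout = x, rule = 2)$y,
       f_act = approx(log(k$sbr), k$f_act, xout = x, rule = 2)$y)
}

#' @export
print.iadt_curves <- function(x, ...) {
  cat("<iadt_curves> knots:\n")
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Iterative adaptive dual-threshold segmentation
#'
#' Starting from a 40% fixed-threshold mask, iterates: estimate the SBR in
#' the VOI (9-hottest reference over the mean of background voxels one voxel
#' clear of the current mask), look up the volume- and activity-threshold
#' fractions at that SBR, and re-segment; stops when both fractions change
#' by less than `tol` or after `max_iter` iterations (the last iterate is
#' then returned with `converged = FALSE`). The volume is read from the
#' volume-threshold mask and the activity from the activity-threshold mask;
#' no a-priori knowledge of the object volume or SBR is used.
#'
#' @param image activity volume.
#' @param voi logical VOI array.
#' @param curves an [build_iadt_curves()] result.
#' @param voxel_ml voxel volume in ml.
#' @param body optional logical body-contour mask (e.g. attenuation map
#'   above half the water value); the background sample for the SBR
#'   estimate is restricted to it, keeping the estimate independent of how
#'   much of the VOI lies outside the phantom or patient.
#' @param tol convergence tolerance on the threshold fractions.
#' @param max_iter iteration cap.
#' @return a `seg_result` with `sbr_estimate`, fractions and iteration
#'   count attached.
#' @export
iadt_segment <- function(image, voi, curves, voxel_ml, body = NULL,
                         tol = 1e-3, max_iter = 20) {
  stopifnot(inherits(curves, "iadt_curves"))
  ref <- reference_value(image, voi)
  mask <- voi & (image >= 0.40 * ref)
  f_prev <- c(NA_real_, NA_real_)
  converged <- FALSE
  sbr <- NA_real_
  f <- NULL
  for (it in seq_len(max_iter)) {
    sbr <- measure_sbr(image, voi, mask, body)
    f <- iadt_lookup(curves, sbr)
    if (!any(is.na(f_prev)) &&
        abs(f$f_vol - f_prev[1]) < tol && abs(f$f_act - f_prev[2]) < tol) {
      converged <- TRUE
      break
    }
    f_prev <- c(f$f_vol, f$f_act)
    mask <- voi & (image >= f$f_vol * ref)
    if (!any(mask)) break
  }
  mask_v <- voi & (image >= f$f_vol * ref)
  mask_a <- voi & (image >= f$f_act * ref)
  seg_result(mask_v, voxel_ml, sum(image[mask_a]), "iadt",
             sbr_estimate = sbr, converged = converged,
             extra = list(f_vol = f$f_vol, f_act = f$f_act, n_iter = it,
                          reference = ref))
}
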