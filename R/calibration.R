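#' Planar calibration scan record
#'
#' Totals from a planar scan of a point source: counts per energy window,
#' source activity and scan duration. Decay correction of `A` to the scan
#' midpoint is the caller's responsibility.
#'
#' @param C_pw,C_ls,C_us total counts in the photopeak / lower / upper
#'   windows.
#' @param A source activity in MBq (> 0).
#' @param t_d scan duration in s (> 0).
#' @return object of class `planar_scan_record`.
#' @export
planar_scan_record <- function(C_pw, C_ls = 0, C_us = 0, A, t_d) {
  stopifnot(C_pw >= 0, C_ls >= 0, C_us >= 0, A > 0, t_d > 0)
  structure(list(C_pw = C_pw, C_ls = C_ls, C_us = C_us, A = A, t_d = t_d),
            class = "planar_scan_record")
}

#' Tomographic calibration scan record
#'
#' @param C_rec total counts in the reconstructed image.
#' @param A total activity in the phantom (MBq).
#' @param n_p number of projections.
#' @param t_p seconds per projection.
#' @return object of class `tomo_scan_record`.
#' @export
tomo_scan_record <- function(C_rec, A, n_p, t_p) {
  stopifnot(C_rec > 0, A > 0, n_p > 0, t_p > 0)
  structure(list(C_rec = C_rec, A = A, n_p = as.integer(n_p), t_p = t_p),
            class = "tomo_scan_record")
}

cnf_result <- function(value, method, provenance = list()) {
  if (!is.finite(value) || value <= 0) stop("CNF must be positive")
  structure(list(value = value, method = method, provenance = provenance),
            class = "cnf_result")
}

#' @export
print.cnf_result <- function(x, ...) {
  cat(sprintf("<cnf_result> %.4f counts/(MBq s) [%s]\n", x$value, x$method))
  invisible(x)
}

#' Camera normalization factor, planar method 1 (all photopeak counts)
#'
#' `CNF = C_pw / (A * t_d)`. No scatter correction: high-energy downscatter
#' inflates this value relative to method 2.
#'
#' @param rec a [planar_scan_record()].
#' @return a `cnf_result` in counts/(MBq s).
#' @export
cnf_planar_method1 <- function(rec) {
  stopifnot(inherits(rec, "planar_scan_record"))
  cnf_result(rec$C_pw / (rec$A * rec$t_d), "planar1")
}

#' Camera normalization factor, planar method 2 (TEW-corrected counts)
#'
#' Scatter in the photopeak window is estimated from the window totals,
#' `C_s = (C_ls/w_ls + C_us/w_us) * w_pw / 2`, the primaries are
#' `C_prim = C_pw - C_s` (floored at 0), and
#' `CNF = C_prim / (A * t_d)`.
#'
#' @param rec a [planar_scan_record()] with all three windows.
#' @param windows an [energy_windows()].
#' @return a `cnf_result`.
#' @export
cnf_planar_method2 <- function(rec, windows = energy_windows()) {
  stopifnot(inherits(rec, "planar_scan_record"))
  C_s <- (rec$C_ls / windows$w_ls + rec$C_us / windows$w_us) * windows$w_pw / 2
  if (C_s >= rec$C_pw)
    stop("scatter estimate exceeds photopeak counts; calibration scan unusable")
  cnf_result((rec$C_pw - C_s) / (rec$A * rec$t_d), "planar2",
             provenance = list(C_s = C_s))
}

#' Camera normalization factor, tomographic method
#'
#' `CNF = C_rec / (A * t_p * n_p)`, with `C_rec` the total counts in an
#' image reconstructed with attenuation correction, resolution recovery and
#' TEW scatter correction.
#'
#' @param rec a [tomo_scan_record()].
#' @return a `cnf_result`.
#' @export
cnf_tomographic <- function(rec) {
  stopifnot(inherits(rec, "tomo_scan_record"))
  cnf_result(rec$C_rec / (rec$A * rec$t_p * rec$n_p), "tomo")
}

#' Convert a reconstructed count image to activity
#'
#' Per-voxel MBq = counts / (CNF * total_time), with `total_time` the total
#' acquisition time (n_p * t_p for tomographic scans).
#'
#' @param img a [osem()] `recon_image` (or bare count array).
#' @param cnf a `cnf_result`.
#' @param total_time_s total scan duration in s; defaults to `n_p * t_p`
#'   from the image's acquisition metadata.
#' @return activity array in MBq per voxel.
#' @export
activity_from_image <- function(img, cnf, total_time_s = NULL) {
  stopifnot(inherits(cnf, "cnf_result"), cnf$value > 0)
  counts <- if (inherits(img, "recon_image")) img$counts else img
  if (is.null(total_time_s)) {
    if (!inherits(img, "recon_image"))
      stop("total_time_s required for bare arrays")
    total_time_s <- img$acquisition$n_projections * img$acquisition$t_p
  }
  counts / (cnf$value * total_time_s)
}

#' Simulate a planar point-source calibration scan
#'
#' A point source in air at `distance_mm` from the collimator face (far
#' enough that septal penetration is irrelevant; the sensitivity itself does
#' not depend on distance). Expected primaries `A * sensitivity * t_d` are
#' spread over a small planar image with the distance-dependent PSF;
#' self-scatter and high-energy components and the flanking windows follow
#' the same spectral model as the tomographic simulator; Poisson noise per
#' pixel.
#'
#' @param A source activity in MBq.
#' @param t_d scan duration in s.
#' @param distance_mm source-to-collimator distance.
#' @param sensitivity counts/(MBq s) of the simulated camera.
#' @param params a [scatter_params()] (air defaults).
#' @param windows an [energy_windows()].
#' @param npix planar image size (pixels per side).
#' @param bin_mm pixel pitch.
#' @param sigma0_mm,slope_mm_per_mm PSF parameters.
#' @param seed integer seed, or `NULL` for expected counts.
#' @return a [planar_scan_record()] with the window images attached as
#'   attribute `images`.
#' @export
simulate_planar_scan <- function(A = 11.7, t_d = 600, distance_mm = 300,
                                 sensitivity = 10,
                                 params = default_scatter_params("air"),
                                 windows = energy_windows(), npix = 64,
                                 bin_mm = 4.8, sigma0_mm = 3.0,
                                 slope_mm_per_mm = 0.02, seed = NULL) {
  stopifnot(A > 0, t_d > 0, distance_mm >= 0)
  img <- array(0, c(npix, npix, 1))
  ctr <- as.integer(ceiling(npix / 2))
  img[ctr, ctr, 1] <- A * sensitivity * t_d
  sig <- (sigma0_mm + slope_mm_per_mm * distance_mm) / bin_mm
  primary <- .lq_blur_planes(img, dim(img), sig)
  truth <- simulate_scatter(primary, params, windows, bin_mm)
  pw <- primary + truth$S_true + truth$H_true
  lsw <- truth$lsw
  usw <- truth$usw
  if (!is.null(seed)) {
    pw <- add_poisson(pw, seed)
    lsw <- add_poisson(lsw, seed + 1L)
    usw <- add_poisson(usw, seed + 2L)
  }
  rec <- planar_scan_record(C_pw = sum(pw), C_ls = sum(lsw),
                            C_us = sum(usw), A = A, t_d = t_d)
  attr(rec, "images") <- list(pw = pw, lsw = lsw, usw = usw)
  rec
}
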