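#' Energy window set
#'
#' Three acquisition energy windows around the 208 keV photopeak: lower
#' scatter window (LSW), photopeak window (PW), upper scatter window (USW).
#' The defaults are the windows used throughout the package: LSW
#' 153.0-187.0 keV, PW 187.2-228.8 keV, USW 229.5-280.2 keV, giving widths
#' w_ls = 34.0, w_pw = 41.6, w_us = 50.7 keV. Windows are half-open
#' [lower, upper) for spectral integration and must be ordered and
#' non-overlapping.
#'
#' @param lsw,pw,usw numeric `c(lower, upper)` in keV.
#' @return object of class `energy_windows` with per-window lower/centre/
#'   upper and widths `w_ls`, `w_pw`, `w_us`.
#' @export
energy_windows <- function(lsw = c(153.0, 187.0), pw = c(187.2, 228.8),
                           usw = c(229.5, 280.2)) {
  w <- rbind(lsw = lsw, pw = pw, usw = usw)
  if (any(w[, 2] <= w[, 1])) stop("window widths must be positive")
  if (lsw[2] > pw[1] || pw[2] > usw[1])
    stop("windows must be ordered LSW < PW < USW and non-overlapping")
  structure(list(
    lsw = list(lower = lsw[1], upper = lsw[2], centre = mean(lsw)),
    pw = list(lower = pw[1], upper = pw[2], centre = mean(pw)),
    usw = list(lower = usw[1], upper = usw[2], centre = mean(usw)),
    w_ls = diff(lsw), w_pw = diff(pw), w_us = diff(usw)
  ), class = "energy_windows")
}

#' Acquisition geometry and timing
#'
#' @param n_projections number of views (default 90, evenly spaced over 360
#'   degrees).
#' @param bin_mm detector bin pitch in mm.
#' @param matrix detector bins `c(nu, nv)` (transaxial, axial).
#' @param angles_deg per-view camera angles (degrees); default even spacing.
#' @param orbit_mm orbit radius per view in mm (scalar is recycled; a vector
#'   describes a non-circular orbit).
#' @param t_p seconds per projection.
#' @param sensitivity ideal-detector sensitivity in counts/(MBq s); this is
#'   the ground-truth camera normalization factor of the simulation.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_projections = 90, bin_mm = 4.8,
                             matrix = c(128, 128), angles_deg = NULL,
                             orbit_mm = 250, t_p = 20, sensitivity = 10) {
  stopifnot(n_projections >= 1, t_p > 0, sensitivity > 0, bin_mm > 0)
  if (is.null(angles_deg))
    angles_deg <- seq(0, 360, length.out = n_projections + 1)[seq_len(n_projections)]
  stopifnot(length(angles_deg) == n_projections)
  orbit_mm <- rep_len(orbit_mm, n_projections)
  structure(list(n_projections = as.integer(n_projections), bin_mm = bin_mm,
                 matrix = as.integer(matrix), angles_deg = angles_deg,
                 orbit_mm = orbit_mm, t_p = t_p, sensitivity = sensitivity),
            class = "acquisition_spec")
}

#' SPECT system model
#'
#' The analytic system operator used both to simulate primary-photon
#' projections and as the system matrix inside OSEM: rotation-based
#' projection with cumulative attenuation along the ray and a
#' distance-dependent Gaussian collimator-detector response
#' `sigma(d) = sigma0 + slope * d` applied per emission plane.
#'
#' The detector bin pitch must be an integer multiple (`rebin`) of the volume
#' voxel pitch; volume x/z dims must be divisible by `rebin`.
#'
#' @param acquisition an [acquisition_spec()].
#' @param grid [voxel_grid()] of the volumes this model projects.
#' @param mu attenuation map (cm^-1) on `grid`, or `NULL` for none.
#' @param sigma0_mm PSF sigma at the collimator face (mm).
#' @param slope_mm_per_mm PSF sigma growth per mm distance.
#' @param attenuation,resolution enable attenuation weighting / resolution
#'   modelling.
#' @return object of class `system_model`.
#' @export
system_model <- function(acquisition, grid, mu = NULL, sigma0_mm = 3.0,
                         slope_mm_per_mm = 0.02, attenuation = !is.null(mu),
                         resolution = TRUE) {
  stopifnot(inherits(acquisition, "acquisition_spec"),
            inherits(grid, "voxel_grid"),
            sigma0_mm >= 0, slope_mm_per_mm >= 0)
  rebin <- acquisition$bin_mm / grid$voxel_mm
  if (abs(rebin - round(rebin)) > 1e-9)
    stop("detector bin pitch must be an integer multiple of the voxel pitch")
  rebin <- as.integer(round(rebin))
  if (grid$shape[1] %% rebin != 0 || grid$shape[3] %% rebin != 0)
    stop("grid x/z dims must be divisible by the voxel-to-bin rebin factor")
  nu <- grid$shape[1] %/% rebin
  nv <- grid$shape[3] %/% rebin
  if (!is.null(mu) && !identical(as.integer(dim(mu)), grid$shape))
    stop("mu map is not on the model grid")
  if (attenuation && is.null(mu)) stop("attenuation requested but no mu map")
  structure(list(acquisition = acquisition, grid = grid, mu = mu,
                 sigma0 = sigma0_mm, slope = slope_mm_per_mm,
                 attenuation = attenuation, resolution = resolution,
                 rebin = rebin, nu = nu, nv = nv),
            class = "system_model")
}

#' Distance-dependent PSF width
#'
#' `sigma(d) = sigma0 + slope * d`, monotone non-decreasing in distance.
#'
#' @param distance_mm source-to-collimator distance(s) in mm, >= 0.
#' @param model a [system_model()].
#' @return sigma in mm.
#' @export
psf_sigma <- function(distance_mm, model) {
  if (any(distance_mm < 0)) stop("distance must be non-negative")
  if (!model$resolution) return(rep(0, length(distance_mm)))
  model$sigma0 + model$slope * distance_mm
}

#' Fit PSF parameters from two FWHM calibration points
#'
#' Solves `sigma0 + slope * d = fwhm/2.3548` at two distances.
#'
#' @param d1_mm,fwhm1_mm,d2_mm,fwhm2_mm calibration distances and FWHMs (mm).
#' @return list with `sigma0_mm` and `slope_mm_per_mm`.
#' @export
psf_from_fwhm <- function(d1_mm, fwhm1_mm, d2_mm, fwhm2_mm) {
  k <- 2 * sqrt(2 * log(2))
  s1 <- fwhm1_mm / k
  s2 <- fwhm2_mm / k
  slope <- (s2 - s1) / (d2_mm - d1_mm)
  list(sigma0_mm = s1 - slope * d1_mm, slope_mm_per_mm = slope)
}

#' Forward project an activity volume
#'
#' Expected primary-photon counts per detector bin and view: the volume is
#' resampled into each view frame, each emission plane is weighted by the
#' cumulative attenuation towards the detector (half-voxel offset), blurred
#' with the distance-dependent Gaussian response, summed along the ray,
#' block-summed to detector bins, and scaled by
#' `sensitivity * t_p`.
#'
#' @param activity MBq-per-voxel array on the model grid.
#' @param model a [system_model()].
#' @param views optional integer subset of views to project.
#' @param scale multiply by `sensitivity * t_p` (set `FALSE` for the raw
#'   geometric operator used inside OSEM).
#' @return array `[nu, nv, n_views]` of expected counts, with the view
#'   angles as attribute `views`.
#' @export
forward_project <- function(activity, model, views = NULL, scale = TRUE) {
  stopifnot(inherits(model, "system_model"))
  if (!identical(as.integer(dim(activity)), model$grid$shape))
    stop("activity volume is not on the model grid")
  acq <- model$acquisition
  if (is.null(views)) views <- seq_len(acq$n_projections)
  sino <- .lq_forward(activity,
                      if (model$attenuation) model$mu else numeric(0),
                      model$grid$shape, model$grid$voxel_mm,
                      acq$angles_deg[views] * pi / 180, acq$orbit_mm[views],
                      model$sigma0, model$slope, model$rebin,
                      model$attenuation, model$resolution)
  if (scale) sino <- sino * acq$sensitivity * acq$t_p
  attr(sino, "views") <- views
  sino
}

#' Back project a sinogram (exact adjoint of [forward_project()])
#'
#' @param sino array `[nu, nv, n_views]`.
#' @param model a [system_model()].
#' @param views integer view subset matching `dim(sino)[3]`.
#' @param scale include the `sensitivity * t_p` factor (to stay the exact
#'   adjoint of the scaled forward operator).
#' @return volume array on the model grid.
#' @export
back_project <- function(sino, model, views = NULL, scale = TRUE) {
  stopifnot(inherits(model, "system_model"))
  acq <- model$acquisition
  if (is.null(views)) views <- seq_len(acq$n_projections)
  d <- dim(sino)
  if (length(d) != 3 || d[1] != model$nu || d[2] != model$nv ||
      d[3] != length(views))
    stop("sinogram shape inconsistent with the system model")
  vol <- .lq_back(sino, if (model$attenuation) model$mu else numeric(0),
                  model$grid$shape, model$grid$voxel_mm,
                  acq$angles_deg[views] * pi / 180, acq$orbit_mm[views],
                  model$sigma0, model$slope, model$rebin,
                  model$attenuation, model$resolution)
  if (scale) vol <- vol * acq$sensitivity * acq$t_p
  vol
}
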