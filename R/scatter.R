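#' Scatter simulation parameters
#'
#' Projection-space scatter model: the photopeak-window self-scatter
#' component S is a scaled, spatially broadened copy of the primary
#' sinogram, and the high-energy downscatter component H a scaled copy
#' broadened twice as much (high-energy photons mostly scatter in the
#' crystal and are spread more diffusely). The default H magnitude is 3% of
#' the primary photopeak counts. The flanking-window counts are generated
#' from a spectral-density model (see [simulate_scatter()]) whose curvature
#' term is the single knob controlling the bias of triple-energy-window
#' scatter estimation.
#'
#' @param self_scatter_fraction S-to-primary count ratio in the photopeak
#'   window (defaults: 0.25 in water-filled media, 0.05 in air; see
#'   [default_scatter_params()]).
#' @param kernel_fwhm_mm FWHM of the S broadening kernel.
#' @param he_fraction H-to-primary count ratio in the photopeak window.
#' @param spectral_slope per-keV linear coefficient of the scatter spectral
#'   density across the photopeak window.
#' @param spectral_curvature per-keV^2 quadratic coefficient; 0 makes the
#'   TEW estimate exact in expectation.
#' @return object of class `scatter_params`.
#' @export
scatter_params <- function(self_scatter_fraction = 0.25, kernel_fwhm_mm = 60,
                           he_fraction = 0.03, spectral_slope = -0.002,
                           spectral_curvature = 5e-5) {
  if (self_scatter_fraction < 0 || he_fraction < 0)
    stop("scatter fractions must be non-negative")
  if (kernel_fwhm_mm <= 0) stop("kernel FWHM must be positive")
  structure(list(self_scatter_fraction = self_scatter_fraction,
                 kernel_fwhm_mm = kernel_fwhm_mm,
                 he_fraction = he_fraction,
                 spectral_slope = spectral_slope,
                 spectral_curvature = spectral_curvature),
            class = "scatter_params")
}

#' Default scatter parameters by medium
#'
#' Water-filled media scatter substantially more into the photopeak window
#' than objects in air; the self-scatter fraction defaults to 0.25 (water,
#' thorax, bed-with-bags) and 0.05 (air, bare bed).
#'
#' @param medium a [study_config()] medium string.
#' @param water_bags whether the bed configuration includes water bags.
#' @return a [scatter_params()] object.
#' @export
default_scatter_params <- function(medium, water_bags = FALSE) {
  watery <- medium %in% c("cold_water", "warm_water", "thorax") ||
    (medium == "bed" && water_bags)
  scatter_params(self_scatter_fraction = if (watery) 0.25 else 0.05)
}

# spectral-density window factors: the scatter spectral density around the
# photopeak is modelled as rho(E) = rho0 * (1 + s*(E-c) + q*(E-c)^2) across
# the PW (centre c), with flat flanking shelves pinned at the PW-edge values
# rho(lower) and rho(upper). Because the PW is symmetric about its centre,
# the TEW trapezoid (heights rho(lower), rho(upper), width w_pw) integrates
# the linear part exactly: zero curvature -> unbiased TEW for any slope.
spectral_factors <- function(params, windows) {
  s <- params$spectral_slope
  q <- params$spectral_curvature
  w <- windows$w_pw
  cen <- windows$pw$centre
  pw_int <- w * (1 + q * w^2 / 12) # integral of the quadratic over the PW
  edge <- function(E) 1 + s * (E - cen) + q * (E - cen)^2
  lo <- edge(windows$pw$lower)
  hi <- edge(windows$pw$upper)
  if (pw_int <= 0 || lo < 0 || hi < 0)
    stop("spectral model parameters produce a negative density")
  list(rho0_per_SH = 1 / pw_int, # rho0 for unit PW scatter counts
       lsw = lo * windows$w_ls / pw_int,
       usw = hi * windows$w_us / pw_int)
}

#' Simulate scatter components and flanking-window sinograms
#'
#' Given an expected-count primary photopeak sinogram, produces the
#' self-scatter (S) and high-energy (H) photopeak contributions plus the
#' lower/upper scatter-window sinograms, all as expected counts:
#' `S = f_s * blur(primary, fwhm)`, `H = f_he * blur(primary, 2*fwhm)`;
#' LSW/USW follow the spectral-density model normalised per bin so the
#' photopeak-window scatter integral equals `S + H`.
#'
#' @param primary expected-count sinogram array `[nu, nv, n_views]`
#'   (pre-noise).
#' @param params a [scatter_params()].
#' @param windows an [energy_windows()].
#' @param bin_mm detector bin pitch (mm), used to express the kernel in bins.
#' @return object of class `scatter_truth`: `S_true`, `H_true`, `lsw`,
#'   `usw` sinograms.
#' @export
simulate_scatter <- function(primary, params, windows, bin_mm) {
  stopifnot(inherits(params, "scatter_params"),
            inherits(windows, "energy_windows"))
  if (any(primary < 0)) stop("primary sinogram must be non-negative")
  d <- dim(primary)
  stopifnot(length(d) == 3)
  k <- 2 * sqrt(2 * log(2))
  sig <- params$kernel_fwhm_mm / k / bin_mm
  S <- params$self_scatter_fraction * .lq_blur_planes(primary, d, sig)
  H <- params$he_fraction * .lq_blur_planes(primary, d, 2 * sig)
  fac <- spectral_factors(params, windows)
  SH <- S + H
  structure(list(S_true = S, H_true = H,
                 lsw = fac$lsw * SH, usw = fac$usw * SH,
                 windows = windows, params = params),
            class = "scatter_truth")
}

#' Add Poisson counting noise
#'
#' Independent Poisson draw per bin, reproducible for a fixed seed. The
#' caller's RNG state is left untouched.
#'
#' @param expected array of expected counts (>= 0).
#' @param seed integer seed.
#' @return array of integer-valued counts with the shape of `expected`.
#' @export
add_poisson <- function(expected, seed) {
  if (any(expected < 0)) stop("expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- rpois(length(expected), lambda = as.numeric(expected))
  array(as.numeric(out), dim(expected))
}

#' Simulate a full three-window tomographic acquisition
#'
#' Forward projects the phantom activity through the system model, adds the
#' scatter model components to populate the photopeak and flanking windows,
#' and (optionally) draws Poisson noise. The expected-count scatter ground
#' truth is retained for the ideal-scatter-correction reconstruction mode.
#'
#' @param phantom a [build_phantom()] result.
#' @param model a [system_model()] on the phantom grid.
#' @param params a [scatter_params()] (default chosen by the phantom medium).
#' @param windows an [energy_windows()].
#' @param seed integer seed for Poisson noise, or `NULL` for expected counts.
#' @return object of class `mw_sinogram`: window arrays `pw`, `lsw`, `usw`
#'   (`[nu, nv, n_views]`), `truth` ([simulate_scatter()] output plus
#'   `primary`), `acquisition`, `windows`, `poisson` flag.
#' @export
simulate_acquisition <- function(phantom, model, params = NULL,
                                 windows = energy_windows(), seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(model, "system_model"))
  if (is.null(params))
    params <- default_scatter_params(phantom$config$medium,
                                     phantom$config$water_bags)
  primary <- forward_project(phantom$activity, model)
  truth <- simulate_scatter(primary, params, windows,
                            model$acquisition$bin_mm)
  truth$primary <- primary
  pw <- primary + truth$S_true + truth$H_true
  lsw <- truth$lsw
  usw <- truth$usw
  poisson <- !is.null(seed)
  if (poisson) {
    pw <- add_poisson(pw, seed)
    lsw <- add_poisson(lsw, seed + 1L)
    usw <- add_poisson(usw, seed + 2L)
  }
  structure(list(pw = pw, lsw = lsw, usw = usw, truth = truth,
                 acquisition = model$acquisition, windows = windows,
                 poisson = poisson),
            class = "mw_sinogram")
}

#' @export
print.mw_sinogram <- function(x, ...) {
  d <- dim(x$pw)
  cat(sprintf("<mw_sinogram> %d x %d bins, %d views, %s counts (PW total %.3g)\n",
              d[1], d[2], d[3], if (x$poisson) "Poisson" else "expected",
              sum(x$pw)))
  invisible(x)
}
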