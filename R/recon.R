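#' Triple-energy-window scatter estimate
#'
#' Per-bin photopeak scatter estimate from the flanking windows:
#' `C_s = (C_ls / w_ls + C_us / w_us) * w_pw / 2`, clamped at 0. No
#' smoothing is applied to any energy window.
#'
#' @param sino an `mw_sinogram` (all three windows required).
#' @param windows an [energy_windows()] (defaults to the sinogram's own).
#' @return object of class `tew_estimate`: `C_s` array, `method = "tew"`.
#' @export
tew_estimate <- function(sino, windows = NULL) {
  stopifnot(inherits(sino, "mw_sinogram"))
  if (is.null(sino$lsw) || is.null(sino$usw))
    stop("sinogram does not carry both scatter windows")
  if (is.null(windows)) windows <- sino$windows
  C_s <- (sino$lsw / windows$w_ls + sino$usw / windows$w_us) * windows$w_pw / 2
  C_s[C_s < 0] <- 0
  structure(list(C_s = C_s, method = "tew", windows = windows),
            class = "tew_estimate")
}

#' Ground-truth scatter term (ideal scatter correction)
#'
#' Packs the simulator's expected S + H photopeak contribution as the
#' scatter term for reconstruction, bypassing TEW estimation entirely.
#'
#' @param sino an `mw_sinogram` carrying its `truth` component.
#' @return a `tew_estimate`-shaped object with `method = "ideal"`.
#' @export
ideal_scatter <- function(sino) {
  stopifnot(inherits(sino, "mw_sinogram"))
  if (is.null(sino$truth)) stop("sinogram carries no scatter ground truth")
  structure(list(C_s = sino$truth$S_true + sino$truth$H_true,
                 method = "ideal", windows = sino$windows),
            class = "tew_estimate")
}

#' Scatter-corrected primary counts
#'
#' `C_prim = C_pw - C_s`, clamped at 0 per bin. Used for planar calibration;
#' tomographic reconstruction keeps the scatter term in the forward model
#' instead of subtracting it.
#'
#' @param sino an `mw_sinogram` (or a bare photopeak array).
#' @param tew a [tew_estimate()].
#' @return array of primary counts.
#' @export
primary_counts <- function(sino, tew) {
  pw <- if (inherits(sino, "mw_sinogram")) sino$pw else sino
  stopifnot(inherits(tew, "tew_estimate"))
  if (!identical(dim(pw), dim(tew$C_s)))
    stop("photopeak and scatter-estimate shapes differ")
  pmax(pw - tew$C_s, 0)
}

#' OSEM configuration
#'
#' @param n_subsets number of ordered subsets (default 10); views are
#'   assigned angle-interleaved (view i to subset i mod n_subsets).
#' @param n_iterations full passes over all subsets (default 6).
#' @param epsilon relative denominator floor (times the maximum forward
#'   projection).
#' @return object of class `osem_config`.
#' @export
osem_config <- function(n_subsets = 10, n_iterations = 6, epsilon = 1e-10) {
  stopifnot(n_subsets >= 1, n_iterations >= 1, epsilon > 0)
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations), epsilon = epsilon),
            class = "osem_config")
}

#' Ordered-subsets expectation maximization reconstruction
#'
#' Multiplicative OSEM with attenuation correction and resolution recovery
#' in the system matrix and the scatter term added in the forward-model
#' denominator (never subtracted from the data):
#' per subset, `X <- X / s * Ct(Y / (C X + S))` with `s` the subset
#' sensitivity image. Voxels with zero sensitivity are masked from the
#' update. Nonnegativity is preserved by construction.
#'
#' The returned image is count-preserving: the system matrix is the per-view
#' geometric projector scaled by 1/n_views, so total image counts
#' approximate the total counts acquired over the whole scan and voxel
#' values convert to MBq as `counts / (CNF * n_p * t_p)`.
#'
#' @param sino an `mw_sinogram`, or a bare photopeak count array.
#' @param model a [system_model()] on the reconstruction grid.
#' @param scatter a [tew_estimate()] / [ideal_scatter()] object, a bare
#'   array, or `NULL` for no scatter term.
#' @param cfg an [osem_config()].
#' @param init optional initial image (default: ones on the full grid).
#' @return object of class `recon_image`: `counts` array, `grid`,
#'   `scatter_method`, `acquisition`, `cfg`.
#' @export
osem <- function(sino, model, scatter = NULL, cfg = osem_config(),
                 init = NULL) {
  stopifnot(inherits(model, "system_model"), inherits(cfg, "osem_config"))
  Y <- if (inherits(sino, "mw_sinogram")) sino$pw else sino
  nviews <- model$acquisition$n_projections
  d <- dim(Y)
  if (length(d) != 3 || d[1] != model$nu || d[2] != model$nv ||
      d[3] != nviews)
    stop("sinogram shape inconsistent with the system model")
  scatter_method <- "none"
  S <- NULL
  if (!is.null(scatter)) {
    if (inherits(scatter, "tew_estimate")) {
      scatter_method <- scatter$method
      S <- scatter$C_s
    } else {
      scatter_method <- "array"
      S <- scatter
    }
    if (!identical(dim(S), d)) stop("scatter term shape mismatch")
  }

  subsets <- split(seq_len(nviews), (seq_len(nviews) - 1L) %% cfg$n_subsets)
  # subset sensitivity images (geometric operator, sens * t_p excluded)
  sens_img <- lapply(subsets, function(v)
    back_project(array(1, c(model$nu, model$nv, length(v))), model,
                 views = v, scale = FALSE))
  X <- if (is.null(init)) array(1, model$grid$shape) else init
  stopifnot(identical(as.integer(dim(X)), model$grid$shape))

  for (it in seq_len(cfg$n_iterations)) {
    for (k in seq_along(subsets)) {
      v <- subsets[[k]]
      fp <- forward_project(X, model, views = v, scale = FALSE)
      if (!is.null(S)) fp <- fp + S[, , v, drop = FALSE]
      eps <- cfg$epsilon * max(fp)
      if (eps == 0) eps <- .Machine$double.xmin
      ratio <- Y[, , v, drop = FALSE] / pmax(fp, eps)
      corr <- back_project(ratio, model, views = v, scale = FALSE)
      s <- sens_img[[k]]
      upd <- s > 0
      X[upd] <- X[upd] * corr[upd] / s[upd]
      X[!upd] <- 0
    }
  }
  structure(list(counts = X * nviews, grid = model$grid,
                 scatter_method = scatter_method,
                 acquisition = model$acquisition, cfg = cfg),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s, scatter = %s, total counts %.4g\n",
              paste(x$grid$shape, collapse = " x "), x$scatter_method,
              sum(x$counts)))
  invisible(x)
}
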