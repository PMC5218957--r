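#' Study geometry: grids, orbit, timing and camera response
#'
#' Bundles the simulation/reconstruction geometry used across a study. The
#' phantom is voxelized at half the detector bin pitch (so simulated data do
#' not live on the reconstruction grid), the detector bins are formed by
#' block-summing (`recon_factor`), and reconstruction runs at the detector
#' bin pitch.
#'
#' @param phantom_shape phantom grid dims (x, y, z); x and z must be
#'   divisible by `recon_factor`.
#' @param phantom_voxel_mm phantom voxel pitch.
#' @param recon_factor detector-bin / phantom-voxel pitch ratio (integer).
#' @param n_projections views over 360 degrees.
#' @param orbit_mm orbit radius (scalar or per view).
#' @param sensitivity camera sensitivity in counts/(MBq s) — the
#'   ground-truth normalization factor of the simulation.
#' @param sigma0_mm,slope_mm_per_mm distance-dependent PSF parameters,
#'   shared by simulator and reconstructor.
#' @param n_subsets,n_iterations OSEM settings.
#' @return object of class `study_geometry`.
#' @export
study_geometry <- function(phantom_shape = c(100, 100, 90),
                           phantom_voxel_mm = 2.4, recon_factor = 2,
                           n_projections = 90, orbit_mm = 250,
                           sensitivity = 10, sigma0_mm = 3.0,
                           slope_mm_per_mm = 0.02, n_subsets = 10,
                           n_iterations = 6) {
  phantom_grid <- voxel_grid(phantom_shape, phantom_voxel_mm)
  recon_factor <- as.integer(recon_factor)
  stopifnot(all(phantom_shape %% recon_factor == 0))
  recon_grid <- voxel_grid(as.integer(phantom_shape) %/% recon_factor,
                           phantom_voxel_mm * recon_factor)
  structure(list(phantom_grid = phantom_grid, recon_grid = recon_grid,
                 recon_factor = recon_factor,
                 bin_mm = phantom_voxel_mm * recon_factor,
                 n_projections = n_projections, orbit_mm = orbit_mm,
                 sensitivity = sensitivity, sigma0_mm = sigma0_mm,
                 slope_mm_per_mm = slope_mm_per_mm,
                 osem = osem_config(n_subsets, n_iterations)),
            class = "study_geometry")
}

acquisition_for <- function(geom, t_p) {
  acquisition_spec(n_projections = geom$n_projections, bin_mm = geom$bin_mm,
                   matrix = c(geom$recon_grid$shape[1],
                              geom$recon_grid$shape[3]),
                   orbit_mm = geom$orbit_mm, t_p = t_p,
                   sensitivity = geom$sensitivity)
}

#' Simulate a study configuration
#'
#' Builds the phantom and generates the expected-count (or Poisson)
#' three-window sinogram through the fine-grid system model.
#'
#' @param config a [study_config()].
#' @param geom a [study_geometry()].
#' @param params scatter parameters (default by medium).
#' @param windows energy windows.
#' @param seed Poisson seed or `NULL` for expected counts.
#' @return list with `phantom`, `model` (fine-grid) and `mw`
#'   (`mw_sinogram`).
#' @export
simulate_config <- function(config, geom, params = NULL,
                            windows = energy_windows(), seed = NULL) {
  phantom <- build_phantom(config, geom$phantom_grid)
  model <- system_model(acquisition_for(geom, config$projection_duration_s),
                        geom$phantom_grid, mu = phantom$mu,
                        sigma0_mm = geom$sigma0_mm,
                        slope_mm_per_mm = geom$slope_mm_per_mm)
  mw <- simulate_acquisition(phantom, model, params = params,
                             windows = windows, seed = seed)
  list(phantom = phantom, model = model, mw = mw)
}

#' Draw a Poisson realization of an expected-count sinogram
#'
#' @param mw an expected-count `mw_sinogram`.
#' @param seed integer seed.
#' @return an `mw_sinogram` with Poisson counts (scatter truth retained).
#' @export
poissonize <- function(mw, seed) {
  stopifnot(inherits(mw, "mw_sinogram"))
  if (mw$poisson) stop("sinogram already carries Poisson counts")
  mw$pw <- add_poisson(mw$pw, seed)
  mw$lsw <- add_poisson(mw$lsw, seed + 1L)
  mw$usw <- add_poisson(mw$usw, seed + 2L)
  mw$poisson <- TRUE
  mw
}

#' Reconstruct a simulated acquisition on the coarse grid
#'
#' Downsamples the phantom attenuation map to the reconstruction grid
#' (standing in for the CT-derived map) and runs OSEM with the requested
#' scatter handling.
#'
#' @param mw an `mw_sinogram`.
#' @param phantom the phantom the data came from (for the mu map).
#' @param geom a [study_geometry()].
#' @param scatter `"tew"`, `"ideal"` or `"none"`.
#' @param cfg OSEM configuration (defaults to the geometry's).
#' @return a `recon_image`.
#' @export
reconstruct_config <- function(mw, phantom, geom,
                               scatter = c("tew", "ideal", "none"),
                               cfg = NULL) {
  scatter <- match.arg(scatter)
  mu_rec <- downsample_volume(phantom$mu, geom$recon_factor, average = TRUE)
  model <- system_model(mw$acquisition, geom$recon_grid, mu = mu_rec,
                        sigma0_mm = geom$sigma0_mm,
                        slope_mm_per_mm = geom$slope_mm_per_mm)
  sterm <- switch(scatter, tew = tew_estimate(mw), ideal = ideal_scatter(mw),
                  none = NULL)
  osem(mw, model, scatter = sterm, cfg = if (is.null(cfg)) geom$osem else cfg)
}

#' Per-insert volumes of interest on a grid
#'
#' Programmatic stand-in for the manually drawn per-object ROIs: a bounding
#' box around each insert centre padded to three times the insert's
#' equivalent radius plus a fixed resolution margin (`pad_mm`, default one
#' reconstructed-PSF diameter, so spilled counts of small objects stay
#' inside their VOI), intersected with the insert's surface-distance
#' nearest-insert (Voronoi) cell so neighbouring objects never share a VOI.
#'
#' @param config a [study_config()].
#' @param grid the grid (normally the reconstruction grid).
#' @param pad_mm fixed padding added to the 3x-radius box half-width.
#' @return named list of logical arrays.
#' @export
insert_vois <- function(config, grid, pad_mm = 24) {
  n <- grid$shape
  ax <- lapply(1:3, function(k) grid$origin[k] + (seq_len(n[k]) - 1) * grid$voxel_mm)
  ins <- config$inserts
  req <- vapply(ins, function(i) max(i$radius_mm, i$half_height_mm), numeric(1))
  # surface-distance fields (distance to centre minus equivalent radius)
  best <- array(Inf, n)
  assign_id <- array(0L, n)
  for (i in seq_along(ins)) {
    dx2 <- (ax[[1]] - ins[[i]]$centre[1])^2
    dy2 <- (ax[[2]] - ins[[i]]$centre[2])^2
    dz2 <- (ax[[3]] - ins[[i]]$centre[3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - req[i]
    upd <- d < best
    best[upd] <- d[upd]
    assign_id[upd] <- i
  }
  out <- lapply(seq_along(ins), function(i) {
    pad <- 3 * req[i] + pad_mm
    inbox <- abs(ax[[1]] - ins[[i]]$centre[1]) <= pad
    inboy <- abs(ax[[2]] - ins[[i]]$centre[2]) <= pad
    inboz <- abs(ax[[3]] - ins[[i]]$centre[3]) <= pad
    box <- outer(outer(inbox, inboy, "&"), inboz, "&")
    box & (assign_id == i)
  })
  names(out) <- vapply(ins, `[[`, character(1), "label")
  out
}

#' True-geometry (CT) insert masks on a grid
#'
#' Fractional-fill rasterization of each insert directly at the target grid
#' resolution, playing the role of CT-based physical-volume segmentation
#' masks.
#'
#' @param config a [study_config()].
#' @param grid target grid.
#' @param nsub supersampling factor.
#' @return named list of fractional arrays.
#' @export
ct_masks <- function(config, grid, nsub = 6) {
  out <- lapply(config$inserts, function(i)
    suppressWarnings(rasterize_insert(grid, i, nsub = nsub)$mask))
  names(out) <- vapply(config$inserts, `[[`, character(1), "label")
  out
}

# analysis group: which fixed threshold / method set a configuration gets
config_group <- function(config) {
  if (config$medium == "warm_water") return("warm")
  if (config$medium %in% c("cold_water", "thorax")) return("cold")
  if (config$medium == "bed" && config$water_bags) return("cold")
  "air"
}

group_threshold <- c(air = 0.001, cold = 0.01)

# CT-derived body contour on the reconstruction grid: voxels whose
# downsampled attenuation exceeds half the water value
body_contour <- function(phantom, geom) {
  downsample_volume(phantom$mu, geom$recon_factor) > mu_for_material("water") / 2
}

#' Build IADT calibration curves from simulated multi-SBR scans
#'
#' Simulates the multi-SBR calibration acquisitions, reconstructs them with
#' the same settings as the study scans, converts to activity and derives
#' the volume/activity threshold curves.
#'
#' @param geom a [study_geometry()].
#' @param cnf `cnf_result` used for count-to-activity conversion.
#' @param seed integer seed (Poisson noise of the calibration scans).
#' @param sbrs calibration SBR levels.
#' @param windows energy windows.
#' @param scatter scatter correction used in the calibration
#'   reconstructions (curves are tagged with it).
#' @return an `iadt_curves` object.
#' @export
iadt_calibration_curves <- function(geom, cnf, seed = 1,
                                    sbrs = c(14.0, 8.0, 5.3, 4.1),
                                    windows = energy_windows(),
                                    scatter = "tew") {
  configs <- iadt_calibration_configs(sbrs = sbrs)
  scans <- list()
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    sim <- simulate_config(cf, geom, windows = windows)
    mw <- poissonize(sim$mw, seed + 100L * k)
    rec <- reconstruct_config(mw, sim$phantom, geom, scatter = scatter)
    act <- activity_from_image(rec, cnf)
    vois <- insert_vois(cf, geom$recon_grid)
    truth <- sim$phantom$truth
    inserts <- lapply(seq_len(nrow(truth)), function(i)
      list(label = truth$label[i], voi = vois[[truth$label[i]]],
           true_volume_ml = truth$volume_ml[i],
           true_activity_MBq = truth$true_MBq[i]))
    scans[[k]] <- list(image = act, voxel_ml = geom$recon_grid$voxel_ml,
                       sbr = config_sbr(cf, digits = NULL),
                       body = body_contour(sim$phantom, geom),
                       inserts = inserts)
  }
  cv <- build_iadt_curves(scans)
  cv$scatter <- scatter
  cv
}

#' Camera normalization factor study
#'
#' Simulates the calibration acquisitions: a planar point-source scan
#' (methods 1 and 2) and three tomographic scans of the six-bottle phantom
#' at different total activity levels (in air and at two warm-background
#' levels), reconstructed with TEW-corrected OSEM. Returns all CNF values
#' plus their mutual agreement metrics.
#'
#' @param geom a [study_geometry()].
#' @param seed integer seed.
#' @param windows energy windows.
#' @param planar_A,planar_t_d planar source activity (MBq) and duration (s).
#' @param tomo_totals target total activities (MBq) of the three
#'   tomographic scans.
#' @return list with `planar1`, `planar2`, `tomo` (list of `cnf_result`),
#'   `max_dev_from_mean_pct` (planar 2 + tomographic values vs their common
#'   mean) and `tomo_max_pairwise_pct`.
#' @export
cnf_study <- function(geom, seed = 1, windows = energy_windows(),
                      planar_A = 11.7, planar_t_d = 600,
                      tomo_totals = c(233.4, 489.1, 681.3)) {
  prec <- simulate_planar_scan(A = planar_A, t_d = planar_t_d,
                               sensitivity = geom$sensitivity,
                               windows = windows,
                               sigma0_mm = geom$sigma0_mm,
                               slope_mm_per_mm = geom$slope_mm_per_mm,
                               seed = seed * 13L + 5L)
  planar1 <- cnf_planar_method1(prec)
  planar2 <- cnf_planar_method2(prec, windows)

  base <- iadt_calibration_configs(sbrs = 14)$cal_sbr14.0 # bottle template
  vols <- vapply(base$inserts, `[[`, numeric(1), "volume_ml")
  vtot <- sum(vols)
  jasz_ml <- pi * 11.1^2 * 19.5 # Jaszczak cylinder volume in ml
  conc_ins <- 0.62
  tomo <- list()
  for (k in seq_along(tomo_totals)) {
    tot <- tomo_totals[k]
    if (k == 1) { # in air: all activity in the bottles
      inserts <- lapply(base$inserts, function(i) {
        i$concentration <- tot / vtot
        i
      })
      cf <- study_config(name = "cnf_air", inserts = inserts,
                         medium = "air", background_concentration = 0,
                         projection_duration_s = 20)
    } else { # warm background making up the total
      bgc <- (tot - conc_ins * vtot) / (jasz_ml - vtot)
      inserts <- lapply(base$inserts, function(i) {
        i$concentration <- conc_ins
        i
      })
      cf <- study_config(name = sprintf("cnf_warm%d", k - 1),
                         inserts = inserts, medium = "warm_water",
                         background_concentration = bgc,
                         projection_duration_s = 30)
    }
    sim <- simulate_config(cf, geom, windows = windows)
    mw <- poissonize(sim$mw, seed * 31L + 7L * k)
    rec <- reconstruct_config(mw, sim$phantom, geom, scatter = "tew")
    A <- phantom_total_activity(sim$phantom)
    tomo[[k]] <- cnf_tomographic(tomo_scan_record(
      C_rec = sum(rec$counts), A = A,
      n_p = mw$acquisition$n_projections, t_p = mw$acquisition$t_p))
  }
  vals <- c(planar2$value, vapply(tomo, `[[`, numeric(1), "value"))
  tv <- vapply(tomo, `[[`, numeric(1), "value")
  pair <- outer(tv, tv, function(a, b) abs(a - b) / pmin(a, b))
  list(planar1 = planar1, planar2 = planar2, tomo = tomo,
       max_dev_from_mean_pct = 100 * max(abs(vals - mean(vals)) / mean(vals)),
       tomo_max_pairwise_pct = 100 * max(pair))
}

#' Run the quantification study
#'
#' End-to-end driver: for every configuration, build the phantom, simulate
#' the three-window acquisition, draw Poisson realizations, reconstruct
#' with the requested scatter corrections, convert counts to activity with
#' the planar-method-2 normalization factor, segment each analyzed insert
#' with the configuration-appropriate method(s) (air: 0.1% fixed threshold;
#' cold water: 1%; warm background: 40% fixed, CT-based and IADT), and
#' collect per-insert quantification errors, group summaries and
#' nonparametric comparisons.
#'
#' @param configs named list of [study_config()] (default: the eight
#'   presets).
#' @param geom a [study_geometry()].
#' @param seed master integer seed; every random stage derives its own seed
#'   from it.
#' @param n_realizations Poisson noise realizations per configuration.
#' @param scatter_methods subset of `c("tew", "ideal", "none")`.
#' @param windows energy windows.
#' @param cnf optional precomputed `cnf_result` (default: simulate a planar
#'   scan and use method 2).
#' @param curves optional precomputed `iadt_curves` (default: built from
#'   the simulated multi-SBR calibration scans when a warm configuration is
#'   present).
#' @param progress print per-configuration progress.
#' @return object of class `study_report`: `records` (one row per insert,
#'   realization, scatter and segmentation method), `summary`
#'   ([summarise_errors()]), `tests` (Mann-Whitney between scatter methods
#'   per configuration; Mood's median across segmentation methods on warm
#'   configurations), `cnf`, `curves`, `seed`, `geometry`.
#' @export
run_study <- function(configs = lu_study_presets(), geom = study_geometry(),
                      seed = 1, n_realizations = 5,
                      scatter_methods = "tew", windows = energy_windows(),
                      cnf = NULL, curves = NULL, progress = FALSE) {
  seed <- as.integer(seed)
  if (is.null(cnf)) {
    prec <- simulate_planar_scan(sensitivity = geom$sensitivity,
                                 windows = windows,
                                 sigma0_mm = geom$sigma0_mm,
                                 slope_mm_per_mm = geom$slope_mm_per_mm,
                                 seed = seed * 13L + 5L)
    cnf <- cnf_planar_method2(prec, windows)
  }
  any_warm <- any(vapply(configs, function(cf) config_group(cf) == "warm",
                         logical(1)))
  if (any_warm && is.null(curves))
    curves <- iadt_calibration_curves(geom, cnf, seed = seed * 7L + 3L,
                                      windows = windows)

  records <- list()
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    if (progress) message("config ", cf$name)
    sim <- simulate_config(cf, geom, windows = windows)
    group <- config_group(cf)
    vois <- insert_vois(cf, geom$recon_grid)
    ctm <- if (group == "warm") ct_masks(cf, geom$recon_grid)
    body <- if (group == "warm") body_contour(sim$phantom, geom)
    truth <- sim$phantom$truth
    analyzed <- setdiff(truth$label, cf$excluded)
    total_time <- geom$n_projections * cf$projection_duration_s
    for (r in seq_len(n_realizations)) {
      mw <- poissonize(sim$mw, seed + 1000L * ci + 10L * r)
      for (sm in scatter_methods) {
        rec <- reconstruct_config(mw, sim$phantom, geom, scatter = sm)
        act <- activity_from_image(rec, cnf, total_time)
        for (lab in analyzed) {
          tr <- truth[truth$label == lab, ]
          voi <- vois[[lab]]
          segs <- if (group == "warm") {
            list(fixed40 = fixed_threshold_segment(act, voi, 0.40,
                                                   geom$recon_grid$voxel_ml),
                 ct = ct_based_segment(act, ctm[[lab]],
                                       geom$recon_grid$voxel_ml),
                 iadt = iadt_segment(act, voi, curves,
                                     geom$recon_grid$voxel_ml,
                                     body = body))
          } else {
            f <- group_threshold[[group]]
            setNames(list(fixed_threshold_segment(
              act, voi, f, geom$recon_grid$voxel_ml)),
              sprintf("fixed%g", 100 * f))
          }
          for (sg in names(segs)) {
            s <- segs[[sg]]
            records[[length(records) + 1]] <- data.frame(
              config = cf$name, group = group, scatter = sm,
              realization = r, label = lab, volume_ml = tr$volume_ml,
              true_MBq = tr$true_MBq, segmentation = sg,
              est_MBq = s$activity_MBq, volume_est_ml = s$volume_ml,
              error_pct = quant_error(s$activity_MBq, tr$true_MBq),
              sbr_est = if (is.null(s$sbr_estimate)) NA_real_ else
                as.numeric(s$sbr_estimate),
              converged = isTRUE(s$converged))
          }
        }
      }
    }
  }
  records <- do.call(rbind, records)

  tests <- list()
  if (length(scatter_methods) >= 2) {
    pairs <- utils::combn(scatter_methods, 2, simplify = FALSE)
    for (cfname in unique(records$config)) {
      for (p in pairs) {
        sub <- records[records$config == cfname, ]
        pi_err <- function(m) {
          s <- sub[sub$scatter == m, ]
          agg <- aggregate(error_pct ~ label + segmentation, s, mean)
          agg$error_pct
        }
        a <- pi_err(p[1])
        b <- pi_err(p[2])
        if (length(a) >= 3 && length(b) >= 3)
          tests[[sprintf("mw_%s_%s_vs_%s", cfname, p[1], p[2])]] <-
            mann_whitney(a, b)
      }
    }
  }
  warm <- records[records$group == "warm", ]
  if (nrow(warm) > 0) {
    for (sm in unique(warm$scatter)) {
      s <- warm[warm$scatter == sm, ]
      agg <- aggregate(error_pct ~ config + label + segmentation, s, mean)
      groups <- split(agg$error_pct, agg$segmentation)
      tests[[sprintf("moods_segmentation_%s", sm)]] <-
        tryCatch(moods_median(groups), error = function(e) e$message)
    }
  }
  structure(list(records = records, summary = summarise_errors(records),
                 tests = tests, cnf = cnf, curves = curves, seed = seed,
                 geometry = geom),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d records, %d configs, CNF %.3f counts/(MBq s)\n",
              nrow(x$records), length(unique(x$records$config)),
              x$cnf$value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-insert mean errors from a study report
#'
#' Averages the signed percent error over noise realizations for every
#' (configuration, scatter, segmentation, insert) cell.
#'
#' @param report a [run_study()] report (or its `records`).
#' @return data.frame with `config`, `scatter`, `segmentation`, `label`,
#'   `volume_ml`, `error_pct`.
#' @export
per_insert_errors <- function(report) {
  rec <- if (inherits(report, "study_report")) report$records else report
  aggregate(error_pct ~ config + group + scatter + segmentation + label +
              volume_ml, data = rec, FUN = mean)
}
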