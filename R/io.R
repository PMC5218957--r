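#' Write phantom volumes as NIfTI files
#'
#' Writes the activity (MBq/voxel), attenuation (cm^-1) and insert-label
#' maps as separate NIfTI files with the voxel pitch recorded in the
#' header.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default: the configuration name).
#' @return invisibly, the written paths.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = phantom$config$name) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- rep(phantom$grid$voxel_mm, 3)
  label <- array(0L, phantom$grid$shape)
  for (i in seq_along(phantom$insert_masks))
    label[phantom$insert_masks[[i]] >= 0.5] <- i
  paths <- c(activity = file.path(dir, paste0(prefix, "_activity.nii.gz")),
             mu = file.path(dir, paste0(prefix, "_mu.nii.gz")),
             labels = file.path(dir, paste0(prefix, "_labels.nii.gz")))
  as_nii <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vx
    img
  }
  RNifti::writeNifti(as_nii(phantom$activity), paths["activity"])
  RNifti::writeNifti(as_nii(phantom$mu), paths["mu"])
  RNifti::writeNifti(as_nii(label), paths["labels"])
  invisible(paths)
}

#' Write a reconstructed image as NIfTI
#'
#' @param img a `recon_image` (or bare array).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel pitch; taken from the image grid when available.
#' @return invisibly, `path`.
#' @export
write_recon_nifti <- function(img, path, voxel_mm = NULL) {
  arr <- if (inherits(img, "recon_image")) img$counts else img
  if (is.null(voxel_mm) && inherits(img, "recon_image"))
    voxel_mm <- img$grid$voxel_mm
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return numeric array with attribute `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Persist a multi-window sinogram (binary container + JSON sidecar)
#'
#' The counts of the three windows are stored back to back as little-endian
#' doubles in `<path>.bin` (order pw, lsw, usw; column-major
#' `[nu, nv, n_views]` each); `<path>.json` records the layout, window
#' limits, angles, orbit, timing and noise flag. The scatter ground truth
#' (simulation-only) is not persisted.
#'
#' @param mw an `mw_sinogram`.
#' @param path output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_sinogram <- function(mw, path) {
  stopifnot(inherits(mw, "mw_sinogram"))
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con))
  for (w in c("pw", "lsw", "usw"))
    writeBin(as.numeric(mw[[w]]), con, size = 8, endian = "little")
  acq <- mw$acquisition
  meta <- list(
    format = "luquant-sinogram-v1", dtype = "float64-le",
    dim = dim(mw$pw), windows_order = c("pw", "lsw", "usw"),
    poisson = mw$poisson,
    energy_windows = list(lsw = c(mw$windows$lsw$lower, mw$windows$lsw$upper),
                          pw = c(mw$windows$pw$lower, mw$windows$pw$upper),
                          usw = c(mw$windows$usw$lower, mw$windows$usw$upper)),
    angles_deg = acq$angles_deg, orbit_mm = acq$orbit_mm, t_p = acq$t_p,
    bin_mm = acq$bin_mm, sensitivity = acq$sensitivity)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(bin = bin, json = paste0(path, ".json")))
}

#' Read a multi-window sinogram written by [write_sinogram()]
#'
#' @param path path without extension.
#' @return an `mw_sinogram` (without simulation ground truth).
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "luquant-sinogram-v1"))
    stop("not a luquant sinogram container")
  d <- as.integer(meta$dim)
  n <- prod(d)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  arrs <- lapply(1:3, function(i)
    array(readBin(con, "double", n, size = 8, endian = "little"), d))
  ew <- energy_windows(lsw = meta$energy_windows$lsw,
                       pw = meta$energy_windows$pw,
                       usw = meta$energy_windows$usw)
  acq <- acquisition_spec(n_projections = d[3], bin_mm = meta$bin_mm,
                          matrix = d[1:2], angles_deg = meta$angles_deg,
                          orbit_mm = meta$orbit_mm, t_p = meta$t_p,
                          sensitivity = meta$sensitivity)
  structure(list(pw = arrs[[1]], lsw = arrs[[2]], usw = arrs[[3]],
                 truth = NULL, acquisition = acq, windows = ew,
                 poisson = isTRUE(meta$poisson)),
            class = "mw_sinogram")
}

#' Persist IADT calibration curves as JSON
#'
#' @param curves an `iadt_curves` object.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_iadt_curves <- function(curves, path) {
  stopifnot(inherits(curves, "iadt_curves"))
  jsonlite::write_json(list(knots = curves$knots, scatter = curves$scatter),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read IADT calibration curves from JSON
#'
#' @param path JSON file written by [write_iadt_curves()].
#' @return an `iadt_curves` object.
#' @export
read_iadt_curves <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(knots = as.data.frame(x$knots), detail = NULL,
                 scatter = x$scatter),
            class = "iadt_curves")
}

#' Write study records and summaries as CSV
#'
#' @param report a [run_study()] report.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.csv"),
             summary = file.path(dir, "summary.csv"))
  write.csv(report$records, paths["records"], row.names = FALSE)
  write.csv(report$summary, paths["summary"], row.names = FALSE)
  invisible(paths)
}

#' Write / read a study configuration as YAML
#'
#' @param config a [study_config()].
#' @param path YAML file.
#' @return invisibly `path`; [read_study_config()] returns the
#'   [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  inserts <- lapply(config$inserts, function(i)
    list(label = i$label, kind = i$kind, volume_ml = i$volume_ml,
         concentration = i$concentration, centre = i$centre))
  yaml::write_yaml(list(name = config$name, medium = config$medium,
                        background_concentration = config$background_concentration,
                        projection_duration_s = config$projection_duration_s,
                        water_bags = config$water_bags,
                        excluded = config$excluded, inserts = inserts), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cf <- yaml::read_yaml(path)
  inserts <- lapply(cf$inserts, function(i)
    insert_spec(kind = i$kind, centre = unlist(i$centre),
                volume_ml = i$volume_ml,
                concentration_MBq_ml = i$concentration, label = i$label))
  study_config(name = cf$name, inserts = inserts, medium = cf$medium,
               background_concentration = cf$background_concentration,
               projection_duration_s = cf$projection_duration_s,
               water_bags = isTRUE(cf$water_bags),
               excluded = as.character(unlist(cf$excluded)))
}
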