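#' Load the named study configuration presets
#'
#' The eight acquisition conditions of the quantification study, read from
#' the packaged YAML preset file: Jaszczak spheres in air / cold water /
#' warm water, bottles in air / warm water, a thorax body with four bottles
#' in cold water, and bottles on the camera bed with and without water
#' bags. See the preset file for the exact insert volumes, concentrations
#' and placements.
#'
#' @param file path to a preset YAML file (defaults to the packaged one).
#' @return named list of [study_config()] objects.
#' @export
lu_study_presets <- function(file = system.file("extdata", "presets.yaml",
                                                package = "luquant")) {
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw$configs), function(nm) {
    cf <- raw$configs[[nm]]
    inserts <- lapply(cf$inserts, function(i) {
      conc <- if (!is.null(i$concentration)) i$concentration else
        i$activity_MBq / i$volume_ml
      insert_spec(kind = i$kind, centre = unlist(i$centre),
                  volume_ml = i$volume_ml, concentration_MBq_ml = conc,
                  label = i$label)
    })
    study_config(name = nm, inserts = inserts, medium = cf$medium,
                 background_concentration = cf$background_concentration,
                 projection_duration_s = cf$projection_duration_s,
                 water_bags = isTRUE(cf$water_bags),
                 excluded = as.character(unlist(cf$excluded)))
  })
  names(out) <- names(raw$configs)
  out
}

#' IADT calibration configurations (multi-SBR bottle scans)
#'
#' Six bottles (17 to 199.5 ml) at 0.62 MBq/ml inside the Jaszczak
#' cylinder, with the background concentration set to produce the requested
#' signal-to-background ratios. The same phantom with no background ("in
#' air") serves as a tomographic normalization scan.
#'
#' @param sbrs background levels as SBR values (`Inf`/`NA` entries give the
#'   air scan).
#' @param concentration insert concentration in MBq/ml.
#' @param projection_duration_s seconds per projection.
#' @return named list of [study_config()] objects (`cal_sbr<value>` /
#'   `cal_air`).
#' @export
iadt_calibration_configs <- function(sbrs = c(14.0, 8.0, 5.3, 4.1),
                                     concentration = 0.62,
                                     projection_duration_s = 20) {
  vols <- c(199.5, 17, 90, 30, 140, 50) # alternating sizes around the ring
  ang <- (seq_along(vols) - 1) * pi / 3
  inserts <- lapply(seq_along(vols), function(i)
    insert_spec("cylinder", centre = c(66 * cos(ang[i]), 66 * sin(ang[i]), 0),
                volume_ml = vols[i], concentration_MBq_ml = concentration,
                label = paste0("V", i)))
  out <- lapply(sbrs, function(s) {
    if (!is.finite(s))
      study_config(name = "cal_air", inserts = inserts, medium = "cold_water",
                   background_concentration = 0,
                   projection_duration_s = projection_duration_s)
    else
      study_config(name = sprintf("cal_sbr%.1f", s), inserts = inserts,
                   medium = "warm_water",
                   background_concentration = concentration / s,
                   projection_duration_s = projection_duration_s)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
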