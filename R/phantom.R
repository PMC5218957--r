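#' Voxel grid description
#'
#' A regular isotropic voxel grid. Physical coordinates are in mm with the
#' origin at the grid centre: the centre of voxel `(i, j, k)` (1-based) is at
#' `origin + (c(i, j, k) - 1) * voxel_mm`, with
#' `origin = -(shape - 1)/2 * voxel_mm`.
#'
#' @param shape integer triple (nx, ny, nz), all >= 1.
#' @param voxel_mm voxel pitch in mm (> 0), identical on all axes.
#' @return object of class `voxel_grid` with fields `shape`, `voxel_mm`,
#'   `origin` (mm coordinates of the first voxel centre) and `voxel_ml`
#'   (voxel volume in ml).
#' @export
voxel_grid <- function(shape, voxel_mm) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(voxel_mm) == 1, voxel_mm > 0)
  structure(list(
    shape = shape,
    voxel_mm = as.numeric(voxel_mm),
    origin = -(shape - 1) / 2 * voxel_mm,
    voxel_ml = (voxel_mm / 10)^3 # mm^3 -> cm^3 = ml
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %.2f mm (FOV %.0f x %.0f x %.0f mm)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm,
              x$shape[1] * x$voxel_mm, x$shape[2] * x$voxel_mm,
              x$shape[3] * x$voxel_mm))
  invisible(x)
}

#' Hot insert description
#'
#' Spheres and (z-aligned) cylindrical bottles. A cylinder's radius defaults
#' to the "equal aspect" shape height = 2 * radius, i.e.
#' `r = (V / (2 pi))^(1/3)`, unless `radius_mm` is given.
#'
#' @param kind `"sphere"` or `"cylinder"`.
#' @param centre mm triple (grid-centred coordinates).
#' @param volume_ml insert volume in ml (> 0).
#' @param concentration_MBq_ml activity concentration in MBq/ml (>= 0).
#' @param label insert name.
#' @param radius_mm optional cylinder radius override (height derived from
#'   the volume).
#' @return object of class `insert_spec`.
#' @export
insert_spec <- function(kind = c("sphere", "cylinder"), centre, volume_ml,
                        concentration_MBq_ml, label,
                        radius_mm = NULL) {
  kind <- match.arg(kind)
  stopifnot(volume_ml > 0, concentration_MBq_ml >= 0, length(centre) == 3)
  v_mm3 <- volume_ml * 1000
  if (kind == "sphere") {
    r <- (3 * v_mm3 / (4 * pi))^(1 / 3)
    hh <- r
  } else {
    r <- if (is.null(radius_mm)) (v_mm3 / (2 * pi))^(1 / 3) else radius_mm
    hh <- v_mm3 / (pi * r^2) / 2
  }
  structure(list(kind = kind, centre = as.numeric(centre),
                 volume_ml = volume_ml,
                 concentration = concentration_MBq_ml,
                 label = label, radius_mm = r, half_height_mm = hh),
            class = "insert_spec")
}

#' Rasterize an insert onto a grid with fractional boundary fill
#'
#' Boundary voxels receive the fraction of their volume inside the solid,
#' estimated by `nsub^3` supersampling; interior voxels are 1. The voxelized
#' volume is required to agree with the nominal insert volume to 1%.
#'
#' @param grid a [voxel_grid()].
#' @param insert an [insert_spec()].
#' @param nsub supersampling factor per axis (>= 3).
#' @return list with `mask` (array of inside fractions in [0, 1]) and
#'   `volume_ml` (rasterized volume).
#' @export
rasterize_insert <- function(grid, insert, nsub = 4) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(insert, "insert_spec"),
            nsub >= 3)
  half_fov <- (grid$shape * grid$voxel_mm) / 2
  ext <- c(insert$radius_mm, insert$radius_mm,
           if (insert$kind == "sphere") insert$radius_mm else insert$half_height_mm)
  if (any(abs(insert$centre) + ext > half_fov))
    stop(sprintf("insert '%s' extends beyond the phantom grid", insert$label))
  kind <- if (insert$kind == "sphere") "ellipsoid" else "ecylinder"
  radii <- if (insert$kind == "sphere") rep(insert$radius_mm, 3) else
    c(insert$radius_mm, insert$radius_mm, insert$half_height_mm)
  m <- .lq_rasterize(grid$shape, grid$voxel_mm, grid$origin, kind,
                     insert$centre, radii, as.integer(nsub))
  vol <- sum(m) * grid$voxel_ml
  if (abs(vol - insert$volume_ml) / insert$volume_ml > 0.01)
    warning(sprintf("rasterized volume of '%s' off by %.2f%%", insert$label,
                    100 * (vol - insert$volume_ml) / insert$volume_ml))
  list(mask = m, volume_ml = vol)
}

# fractional-fill rasterizer for background/body solids (not inserts)
rasterize_solid <- function(grid, kind, centre, radii, nsub = 3) {
  .lq_rasterize(grid$shape, grid$voxel_mm, grid$origin, kind,
                as.numeric(centre), as.numeric(radii), as.integer(nsub))
}

# axis-aligned box with exact fractional edge fill (camera bed slab)
rasterize_box <- function(grid, lo, hi) {
  ax <- function(n, o, l, h) {
    cc <- o + (seq_len(n) - 1) * grid$voxel_mm
    pmax(0, pmin(1, (pmin(cc + grid$voxel_mm / 2, h) -
                       pmax(cc - grid$voxel_mm / 2, l)) / grid$voxel_mm))
  }
  fx <- ax(grid$shape[1], grid$origin[1], lo[1], hi[1])
  fy <- ax(grid$shape[2], grid$origin[2], lo[2], hi[2])
  fz <- ax(grid$shape[3], grid$origin[3], lo[3], hi[3])
  outer(outer(fx, fy), fz)
}

#' Linear attenuation coefficient by material
#'
#' Frozen defaults for the 208 keV photopeak, taken once from standard
#' mass-attenuation tables (mu/rho interpolated at 208 keV, times nominal
#' density): water 0.136 cm^-1 (1.00 g/cm3), cortical bone 0.25 (1.92),
#' inflated lung 0.041 (0.30), patient bed 0.06 (carbon-fibre shell
#' equivalent), air 0 (vacuum approximation; the physical value,
#' ~1.6e-4 cm^-1, is negligible at this scale).
#'
#' @param material one of `"air"`, `"water"`, `"lung"`, `"bone"`, `"bed"`.
#' @param energy_keV photon energy; only 208 keV values are tabulated.
#' @return linear attenuation coefficient in cm^-1.
#' @export
mu_for_material <- function(material, energy_keV = 208) {
  tab <- c(air = 0.0, water = 0.136, lung = 0.041, bone = 0.25, bed = 0.06)
  if (energy_keV != 208)
    stop("only 208 keV attenuation coefficients are tabulated")
  if (any(!material %in% names(tab)))
    stop("unknown material: ", paste(setdiff(material, names(tab)),
                                     collapse = ", "))
  unname(tab[material])
}

#' Study configuration
#'
#' One named acquisition condition: a set of hot inserts, the surrounding
#' medium, the background activity concentration and the per-projection
#' duration.
#'
#' @param name configuration name.
#' @param inserts list of [insert_spec()].
#' @param medium `"air"`, `"cold_water"`, `"warm_water"`, `"thorax"` or
#'   `"bed"`.
#' @param background_concentration MBq/ml in the background medium; must be 0
#'   unless `medium == "warm_water"`.
#' @param projection_duration_s seconds per projection.
#' @param water_bags add water bags around the inserts (bed medium only).
#' @param excluded labels of inserts excluded from quantification analysis.
#' @return object of class `study_config`.
#' @export
study_config <- function(name, inserts,
                         medium = c("air", "cold_water", "warm_water",
                                    "thorax", "bed"),
                         background_concentration = 0,
                         projection_duration_s = 20,
                         water_bags = FALSE, excluded = character()) {
  medium <- match.arg(medium)
  stopifnot(projection_duration_s > 0, background_concentration >= 0)
  if (medium != "warm_water" && background_concentration != 0)
    stop("background activity is only allowed in the warm_water medium")
  structure(list(name = name, inserts = inserts, medium = medium,
                 background_concentration = background_concentration,
                 projection_duration_s = projection_duration_s,
                 water_bags = isTRUE(water_bags), excluded = excluded),
            class = "study_config")
}

#' Signal-to-background ratio of a warm configuration
#'
#' Insert activity concentration divided by the background concentration.
#' @param config a [study_config()] with nonzero background.
#' @param digits rounding applied to the returned ratio (`NULL` for none).
#' @return SBR (one value per distinct insert concentration, usually one).
#' @export
config_sbr <- function(config, digits = 1) {
  if (config$background_concentration <= 0)
    stop("configuration has no background activity")
  conc <- unique(vapply(config$inserts, `[[`, numeric(1), "concentration"))
  sbr <- conc / config$background_concentration
  if (!is.null(digits)) sbr <- round(sbr, digits)
  sbr
}

# body solids by medium: list of (material, kind, centre, radii) painted in
# order; later entries override earlier ones, inserts override all.
body_solids <- function(config) {
  jaszczak <- list(list(material = "water", kind = "ecylinder",
                        centre = c(0, 0, 0), radii = c(111, 111, 97.5)))
  switch(config$medium,
    air = list(),
    cold_water = jaszczak,
    warm_water = jaszczak,
    thorax = list(
      list(material = "water", kind = "ecylinder",
           centre = c(0, 0, 0), radii = c(108, 78, 90)),
      list(material = "lung", kind = "ellipsoid",
           centre = c(45, 18, 15), radii = c(30, 30, 60)),
      list(material = "lung", kind = "ellipsoid",
           centre = c(-45, 18, 15), radii = c(30, 30, 60)),
      list(material = "bone", kind = "ecylinder", # spine rod
           centre = c(0, -48, 0), radii = c(14, 14, 90)),
      list(material = "bone", kind = "ecylinder", # beef-bone surrogate
           centre = c(-40, -35, -50), radii = c(11, 11, 35))),
    bed = {
      s <- list(list(material = "bed", kind = "box",
                     lo = c(-110, -100, -105), hi = c(110, -86, 105)))
      if (config$water_bags)
        s <- c(s, lapply(list(c(0, -70, -45), c(0, -70, 45),
                              c(0, -10, -45), c(0, -10, 45)),
                         function(ctr) list(material = "water",
                                            kind = "ellipsoid", centre = ctr,
                                            radii = c(105, 35, 52))))
      s
    })
}

#' Build a voxelized phantom from a study configuration
#'
#' Produces co-registered activity (MBq/voxel), material and attenuation
#' (cm^-1 at 208 keV) maps. Inserts are water-filled and displace the
#' background medium; background activity fills the body solid outside the
#' inserts. Boundary voxels are filled fractionally.
#'
#' @param config a [study_config()].
#' @param grid a [voxel_grid()].
#' @param nsub supersampling factor for insert rasterization.
#' @return object of class `phantom`: `grid`, `activity`, `mu`, `material`
#'   (character codes), `insert_masks` (named list of fractional masks),
#'   `truth` (per-insert data.frame of rasterized volume and true activity),
#'   `config`.
#' @export
build_phantom <- function(config, grid, nsub = 4) {
  stopifnot(inherits(config, "study_config"), inherits(grid, "voxel_grid"))
  dims <- grid$shape
  material <- array("air", dims)
  mu <- array(0, dims)
  bodyfrac <- array(0, dims)

  for (s in body_solids(config)) {
    f <- if (s$kind == "box") rasterize_box(grid, s$lo, s$hi) else
      rasterize_solid(grid, s$kind, s$centre, s$radii)
    mu <- mu * (1 - f) + mu_for_material(s$material) * f
    material[f >= 0.5] <- s$material
    if (s$material == "water") bodyfrac <- pmax(bodyfrac, f)
    else bodyfrac <- bodyfrac * (1 - f) # lungs/bone displace background water
  }

  labels <- vapply(config$inserts, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate insert labels")
  insert_masks <- list()
  activity <- array(0, dims)
  insfrac <- array(0, dims)
  truth <- data.frame(label = labels,
                      volume_ml = rep(NA_real_, length(labels)),
                      true_MBq = rep(NA_real_, length(labels)))
  for (ins in config$inserts) {
    r <- rasterize_insert(grid, ins, nsub = nsub)
    if (any(insfrac + r$mask > 1 + 1e-6))
      stop(sprintf("insert '%s' overlaps a previous insert", ins$label))
    insert_masks[[ins$label]] <- r$mask
    activity <- activity + ins$concentration * grid$voxel_ml * r$mask
    mu <- mu * (1 - r$mask) + mu_for_material("water") * r$mask
    material[r$mask >= 0.5] <- "water"
    insfrac <- insfrac + r$mask
    truth[truth$label == ins$label, c("volume_ml", "true_MBq")] <-
      c(r$volume_ml, ins$concentration * grid$voxel_ml * sum(r$mask))
  }
  if (config$background_concentration > 0) {
    bg <- pmax(0, bodyfrac - insfrac)
    activity <- activity + config$background_concentration * grid$voxel_ml * bg
  }
  structure(list(grid = grid, activity = activity, mu = mu,
                 material = material, insert_masks = insert_masks,
                 truth = truth, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> '%s' (%s medium), %d inserts, total %.1f MBq\n",
              x$config$name, x$config$medium, length(x$insert_masks),
              sum(x$activity)))
  invisible(x)
}

#' Total phantom activity in MBq
#' @param phantom a [build_phantom()] result.
#' @export
phantom_total_activity <- function(phantom) sum(phantom$activity)

#' Block-average or block-sum downsampling of a volume
#'
#' Used to bring the fine phantom-grid attenuation map (and true-geometry
#' masks) onto the coarser reconstruction grid. Grid dims must be divisible
#' by `factor`.
#'
#' @param vol 3D array.
#' @param factor integer downsampling factor per axis.
#' @param average average (`TRUE`, e.g. mu maps) or sum (`FALSE`, e.g.
#'   activity in MBq/voxel) over each block.
#' @return downsampled array.
#' @export
downsample_volume <- function(vol, factor, average = TRUE) {
  factor <- as.integer(factor)
  d <- dim(vol)
  stopifnot(length(d) == 3, all(d %% factor == 0))
  if (factor == 1L) return(vol)
  nd <- d %/% factor
  idx <- function(n) rep(seq_len(n), each = factor)
  out <- array(0, nd)
  # accumulate by shifting over the factor^3 offsets (fast, vectorized)
  for (a in seq_len(factor)) for (b in seq_len(factor)) for (cc in seq_len(factor)) {
    out <- out + vol[seq(a, d[1], by = factor),
                     seq(b, d[2], by = factor),
                     seq(cc, d[3], by = factor)]
  }
  if (average) out / factor^3 else out
}
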