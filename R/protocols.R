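#' Site protocol presets
#'
#' Named bundles of acquisition, reconstruction, segmentation, calibration
#' and uncertainty settings mirroring the seven hospital protocols, plus an
#' \code{"ideal"} best-case protocol (truth-mask VOIs, true scatter term,
#' matched calibration, resolution recovery). Site-specific Monte-Carlo and
#' ESSE scatter corrections are emulated by the \code{"ideal"} scatter mode
#' (the simulator's stored true scatter), which is their best-case surrogate.
#'
#' @param id one of "H1".."H7", "ideal".
#' @return object of class \code{site_protocol}.
#' @export
site_protocol <- function(id = c("H1", "H2", "H3", "H4", "H5", "H6", "H7",
                                 "ideal")) {
  id <- match.arg(id)
  w208 <- default_windows(208)
  w113 <- default_windows(113)
  p <- switch(id,
    H1 = list(
      orbit = "contoured", photopeaks = 208, time = 30,
      windows = list("208" = list(pp = energy_window(208, 0.10, "photopeak"),
                                  ls = energy_window(176.8, 0.05,
                                                     "lower_scatter"),
                                  us = energy_window(239.2, 0.05,
                                                     "upper_scatter"))),
      recon = recon_config(6, 6, "TEW", resolution_recovery = TRUE,
                           photopeaks = 208),
      segmentation = list(method = "ct_sphere_margin", margin = 10),
      calibration = "large_homogeneous",
      uncertainty = "poisson_activity"),
    H2 = list(
      orbit = "circular", photopeaks = c(113, 208), time = 30,
      windows = list("113" = list(pp = energy_window(113, 0.075,
                                                     "photopeak")),
                     "208" = list(pp = w208$pp)),
      recon = recon_config(8, 4, "none", resolution_recovery = FALSE,
                           photopeaks = c(113, 208)),
      segmentation = list(method = "iso_contour", inner_fraction = 0.35,
                          outer_fraction = 0.10, calibrate = TRUE),
      calibration = "shell_matched",
      uncertainty = "sd_calibration"),
    H3 = list(
      orbit = "contoured", photopeaks = c(113, 208), time = 30,
      windows = list("113" = list(pp = w113$pp),
                     "208" = list(pp = w208$pp)),
      recon = recon_config(16, 5, "ideal", resolution_recovery = TRUE,
                           photopeaks = c(113, 208)),
      segmentation = list(method = "ct_sphere_margin", margin = 0),
      calibration = "sphere16ml",
      uncertainty = "poisson_activity"),
    H4 = list(
      orbit = "contoured", photopeaks = c(113, 208), time = 30,
      windows = list("113" = w113, "208" = w208),
      recon = recon_config(24, 24, "TEW", resolution_recovery = TRUE,
                           photopeaks = c(113, 208)),
      segmentation = list(method = "manual_truth"),
      calibration = "sphere16ml_multi_position",
      uncertainty = "poisson_calib_voi"),
    H5 = list(
      orbit = "contoured", photopeaks = 208, time = 30,
      windows = list("208" = w208),
      recon = recon_config(5, 10, "TEW", resolution_recovery = FALSE,
                           photopeaks = 208, scatter_presubtract = TRUE),
      segmentation = list(method = "ct_sphere_margin", margin = 0),
      calibration = "sphere16ml_six_voi",
      uncertainty = "sd_calibration_activity"),
    H6 = list(
      orbit = "circular", photopeaks = 208, time = 30,
      windows = list("208" = list(pp = w208$pp)),
      recon = recon_config(5, 15, "ideal", resolution_recovery = TRUE,
                           post_filter_fwhm = 8, photopeaks = 208),
      segmentation = list(method = "fixed_sphere", diameter = 80,
                          inner_only = TRUE),
      calibration = "large_cylinder",
      uncertainty = "none"),
    H7 = list(
      orbit = "contoured", photopeaks = 208, time = 60,
      windows = list("208" = list(pp = w208$pp)),
      recon = recon_config(8, 10, "ideal", resolution_recovery = TRUE,
                           photopeaks = 208),
      segmentation = list(method = "otsu_manual"),
      calibration = "planar_petri",
      uncertainty = "sd_calibration_recovery"),
    ideal = list(
      orbit = "contoured", photopeaks = 208, time = 30,
      windows = list("208" = list(pp = w208$pp)),
      recon = recon_config(16, 10, "ideal", resolution_recovery = TRUE,
                           photopeaks = 208),
      segmentation = list(method = "truth"),
      calibration = "matched",
      uncertainty = "none")
  )
  p$id <- id
  structure(p, class = "site_protocol")
}

# ---- internal phantom helpers for calibration geometries -------------------

# zero-activity body phantom on the simulation grid
empty_body_phantom <- function(spacing, grid_n, in_air = FALSE) {
  spec <- body_phantom_spec()
  if (in_air) spec$water_density <- 0
  make_body_phantom(spec, source = NULL, spacing = spacing,
                    fov = grid_n * spacing)
}

# paint a homogeneous sphere into the activity map; returns phantom + truth
add_sphere_source <- function(phantom, centre, volume_ml, concentration) {
  g <- list(n = dim(phantom$activity$values),
            spacing = phantom$activity$spacing,
            origin = phantom$activity$origin)
  radius <- (3 * volume_ml / (4 * pi))^(1 / 3) * 10
  d2 <- dist2_array(g, centre)
  sel <- d2 <= radius^2
  if (any(phantom$activity$values[sel] > 0)) {
    stop("sphere overlaps existing activity", call. = FALSE)
  }
  phantom$activity$values[sel] <- concentration
  mask <- voxel_image(array(as.numeric(sel), dim = g$n), g$spacing,
                      g$origin, role = "mask")
  list(phantom = phantom, mask = mask, radius_mm = radius,
       volume_ml = mask_volume(mask),
       activity_mbq = mask_volume(mask) * concentration)
}

# 6.9-l cylindrical phantom with homogeneous activity
cylinder_phantom <- function(spacing, grid_n, radius = 108, height = 186,
                             total_activity = 120, water_density = 1.0) {
  n <- rep(grid_n, 3L)
  spacing3 <- rep(spacing, 3L)
  origin <- -(n - 1) / 2 * spacing3
  g <- list(n = n, spacing = spacing3, origin = origin)
  co <- grid_coords(g)
  inxy <- outer(co[[1]]^2, co[[2]]^2, "+") <= radius^2
  inz <- abs(co[[3]]) <= height / 2
  cyl <- array(FALSE, dim = n)
  cyl[, , inz] <- inxy
  conc <- total_activity / (pi * (radius / 10)^2 * (height / 10))
  density <- array(0, dim = n)
  density[cyl] <- water_density
  activity <- array(0, dim = n)
  activity[cyl] <- conc
  list(activity = voxel_image(activity, spacing3, origin, "activity"),
       density = voxel_image(density, spacing3, origin, "density"),
       mask = voxel_image(array(as.numeric(cyl), dim = n), spacing3, origin,
                          "mask"),
       concentration = conc)
}

# acquisition config for a protocol at the chosen desk scale
protocol_acquisition <- function(protocol, grid_n, n_projections, seed) {
  acquisition_config(n_projections = n_projections, matrix = grid_n,
                     time_per_projection = protocol$time,
                     orbit = protocol$orbit,
                     photopeaks = protocol$photopeaks,
                     windows = protocol$windows,
                     rng_seed = seed)
}

# recon config with subsets adapted to the desk-scale projection count
protocol_recon <- function(protocol, n_projections) {
  rc <- protocol$recon
  rc$subsets <- adapt_subsets(n_projections, rc$subsets)
  rc
}

# simulate + reconstruct one calibration object
sim_and_recon <- function(activity, density, acq, rcfg, noise) {
  proj <- acquire(activity, density, acq, noise = noise)
  osem_reconstruct(proj, density, rcfg)
}
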