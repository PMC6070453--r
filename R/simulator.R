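#' Gamma-camera simulator
#'
#' Parallel-beam projector standing in for the clinical SPECT systems:
#' attenuated line integrals of the activity map, depth-dependent Gaussian
#' collimator-detector response, a kernel/fraction scatter model populating
#' the photopeak and adjacent scatter windows, and Poisson counting noise.
#' The true primary and scatter components are stored alongside the noisy
#' counts so that "ideal" scatter correction (the surrogate for the sites'
#' Monte-Carlo and ESSE corrections) is available downstream.
#'
#' @name simulator
NULL

#' Energy window definition
#'
#' @param centre keV.
#' @param half_width_fraction half width as a fraction of the centre (e.g.
#'   0.10 for "+/- 10\%"). Full width in keV is
#'   \code{2 * centre * half_width_fraction}.
#' @param role \code{"photopeak"}, \code{"lower_scatter"} or
#'   \code{"upper_scatter"}.
#' @return object of class \code{energy_window} with derived \code{width_kev}.
#' @export
energy_window <- function(centre, half_width_fraction,
                          role = c("photopeak", "lower_scatter",
                                   "upper_scatter")) {
  role <- match.arg(role)
  stopifnot(centre > 0, half_width_fraction > 0)
  structure(list(centre = centre, half_width_fraction = half_width_fraction,
                 width_kev = 2 * centre * half_width_fraction, role = role),
            class = "energy_window")
}

# default window triplets per photopeak (TEW-style neighbours)
default_windows <- function(peak) {
  if (peak == 208) {
    list(pp = energy_window(208, 0.10, "photopeak"),
         ls = energy_window(178, 0.05, "lower_scatter"),
         us = energy_window(214, 0.05, "upper_scatter"))
  } else if (peak == 113) {
    list(pp = energy_window(113, 0.10, "photopeak"),
         ls = energy_window(98.7, 0.05, "lower_scatter"),
         us = energy_window(131, 0.05, "upper_scatter"))
  } else {
    stop("unsupported photopeak: ", peak, call. = FALSE)
  }
}

#' Acquisition configuration
#'
#' Bundles the gamma-camera settings. Defaults mirror the clinical protocols:
#' 120 projections of 30 s on a 128 x 128 matrix; at desk scale the grid and
#' number of projections are usually reduced (the matrix follows the phantom
#' grid). Sensitivities are free parameters (real cps/MBq values are camera
#' specific); the 113 keV value defaults to 0.6 x the 208 keV one, the ratio
#' of the emission probabilities (6\% vs 10\%), and the 113 keV PSF is
#' slightly wider.
#'
#' @param n_projections number of projection angles over 360 degrees.
#' @param matrix nominal matrix size (metadata; projections are simulated on
#'   the phantom grid).
#' @param time_per_projection seconds.
#' @param orbit \code{"contoured"} (body contour plus clearance) or
#'   \code{"circular"}.
#' @param orbit_radius mm, radius of a circular orbit (and fallback when the
#'   contour cannot be derived).
#' @param orbit_clearance mm added to the body contour for contoured orbits.
#' @param photopeaks subset of \code{c(113, 208)}.
#' @param windows named list (by photopeak) of window triplets; default TEW
#'   neighbours \code{178 +/- 5\%} and \code{214 +/- 5\%} around
#'   \code{208 +/- 10\%} (and \code{98.7/131 +/- 5\%} around 113 keV).
#' @param sensitivity named numeric, cps/MBq per photopeak.
#' @param psf_fwhm_intrinsic,psf_fwhm_slope named numeric per photopeak:
#'   FWHM(d) = sqrt(intrinsic^2 + (slope * d)^2), d = distance to collimator
#'   in mm.
#' @param scatter list: \code{photopeak_fraction} (scatter counts as a
#'   fraction of the unattenuated broad-beam projection in the photopeak
#'   window; the 0.08 default gives a scatter-to-detected-primary ratio of
#'   roughly 0.3 through the water phantom), \code{window_fraction} (idem
#'   for each narrow scatter window, chosen so the trapezoidal TEW estimate
#'   is approximately unbiased), \code{kernel_fwhm_mm} (width of the scatter
#'   blurring kernel).
#' @param rng_seed integer used for Poisson sampling in [acquire()].
#' @return object of class \code{acquisition_config}.
#' @export
acquisition_config <- function(n_projections = 120, matrix = 128,
                               time_per_projection = 30,
                               orbit = c("contoured", "circular"),
                               orbit_radius = 280, orbit_clearance = 30,
                               photopeaks = 208, windows = NULL,
                               sensitivity = c("113" = 6, "208" = 10),
                               psf_fwhm_intrinsic = c("113" = 4.5,
                                                      "208" = 4),
                               psf_fwhm_slope = c("113" = 0.055,
                                                  "208" = 0.05),
                               scatter = list(photopeak_fraction = 0.08,
                                              window_fraction = 0.037,
                                              kernel_fwhm_mm = 60),
                               rng_seed = 1L) {
  orbit <- match.arg(orbit)
  stopifnot(n_projections > 0, matrix > 0, time_per_projection > 0,
            all(photopeaks %in% c(113, 208)))
  if (is.null(windows)) {
    windows <- lapply(photopeaks, default_windows)
    names(windows) <- as.character(photopeaks)
  }
  structure(list(n_projections = as.integer(n_projections),
                 matrix = as.integer(matrix),
                 time_per_projection = time_per_projection,
                 orbit = orbit, orbit_radius = orbit_radius,
                 orbit_clearance = orbit_clearance,
                 photopeaks = photopeaks, windows = windows,
                 sensitivity = sensitivity,
                 psf_fwhm_intrinsic = psf_fwhm_intrinsic,
                 psf_fwhm_slope = psf_fwhm_slope,
                 scatter = scatter, rng_seed = as.integer(rng_seed)),
            class = "acquisition_config")
}

#' Projection angles of a configuration (degrees)
#' @param config an \code{acquisition_config}.
#' @return numeric vector, 0 deg at anterior, clockwise.
#' @export
projection_angles <- function(config) {
  seq(0, 360, length.out = config$n_projections + 1L)[seq_len(config$n_projections)]
}

# per-angle orbit radius (mm): ellipse support function + clearance, derived
# from the in-plane support of the attenuating object
orbit_radius_at <- function(config, angle_deg, mu = NULL) {
  if (config$orbit == "circular" || is.null(mu)) return(config$orbit_radius)
  nz <- which(mu$values > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(config$orbit_radius)
  xs <- abs(voxel_coords(mu, 1)[range(nz[, 1])])
  ys <- abs(voxel_coords(mu, 2)[range(nz[, 2])])
  a <- max(xs); b <- max(ys)
  th <- angle_deg * pi / 180
  sqrt((a * sin(th))^2 + (b * cos(th))^2) + config$orbit_clearance
}

check_sim_grid <- function(img) {
  d <- dim(img$values)
  if (d[1] != d[2] || abs(img$spacing[1] - img$spacing[2]) > 1e-9) {
    stop("the simulator requires nx == ny and dx == dy (rotating projector)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# core projector on per-voxel activity (MBq per voxel)
fp_counts <- function(act_voxel, mu, dim3, spacing_mm, theta_deg, sens_time,
                      orbit_mm, psf_int, psf_slope, use_psf, use_att) {
  .fp_angle(act_voxel, mu, as.integer(dim3), theta_deg * pi / 180,
            spacing_mm, sens_time, orbit_mm, psf_int, psf_slope,
            use_psf, use_att)
}

bp_counts <- function(proj, mu, dim3, spacing_mm, theta_deg, sens_time,
                      orbit_mm, psf_int, psf_slope, use_psf, use_att) {
  .bp_angle(proj, mu, as.integer(dim3), theta_deg * pi / 180,
            spacing_mm, sens_time, orbit_mm, psf_int, psf_slope,
            use_psf, use_att)
}

#' Forward-project the primary (unscattered) photons at one angle
#'
#' Attenuated parallel-beam line integrals of the activity map, blurred per
#' depth slab with the distance-dependent collimator-detector response and
#' scaled to mean counts by \code{sensitivity x time_per_projection}.
#'
#' @param activity \code{voxel_image}, MBq/ml.
#' @param mu \code{voxel_image}, 1/cm, on the same grid (pass a zero map for
#'   in-air geometry).
#' @param config an \code{acquisition_config}.
#' @param angle degrees.
#' @param peak photopeak (113 or 208) selecting sensitivity and PSF.
#' @param use_psf,use_att switch the response/attenuation model off for
#'   oracle-style checks.
#' @return matrix of mean counts (nx x nz).
#' @export
forward_project <- function(activity, mu, config, angle, peak = 208,
                            use_psf = TRUE, use_att = TRUE) {
  stop_if_grid_mismatch(activity, mu)
  check_sim_grid(activity)
  key <- as.character(peak)
  act_voxel <- activity$values * voxel_volume_ml(activity)
  fp_counts(act_voxel, mu$values, dim(activity$values),
            activity$spacing[1], angle,
            config$sensitivity[[key]] * config$time_per_projection,
            orbit_radius_at(config, angle, mu),
            config$psf_fwhm_intrinsic[[key]], config$psf_fwhm_slope[[key]],
            use_psf, use_att)
}

#' Scatter component at one angle, per energy window
#'
#' Kernel/fraction scatter model: each window's scatter is a fixed fraction
#' of the unattenuated broad-beam projection of the activity, convolved with
#' a wide Gaussian kernel. Spectral overlap between the upper scatter window
#' and the photopeak is not modelled.
#'
#' @inheritParams forward_project
#' @return named list of mean-count matrices, one per window of the peak
#'   (\code{pp}, \code{ls}, \code{us}).
#' @export
scatter_project <- function(activity, mu, config, angle, peak = 208) {
  stop_if_grid_mismatch(activity, mu)
  check_sim_grid(activity)
  key <- as.character(peak)
  act_voxel <- activity$values * voxel_volume_ml(activity)
  broad <- fp_counts(act_voxel, mu$values, dim(activity$values),
                     activity$spacing[1], angle,
                     config$sensitivity[[key]] * config$time_per_projection,
                     orbit_radius_at(config, angle, mu),
                     0, 0, FALSE, FALSE)
  sigma_px <- config$scatter$kernel_fwhm_mm / 2.354820045 /
    activity$spacing[1]
  blurred <- .conv2_gauss(broad, sigma_px)
  out <- list()
  for (wn in names(config$windows[[key]])) {
    w <- config$windows[[key]][[wn]]
    f <- if (w$role == "photopeak") config$scatter$photopeak_fraction else
      config$scatter$window_fraction
    out[[wn]] <- f * blurred
  }
  out
}

#' Simulate a full SPECT acquisition
#'
#' For every angle and configured energy window the mean counts are formed as
#' primary (photopeak windows only) plus scatter; Poisson noise is then drawn
#' with the configuration's seed. Pre-noise primary and scatter components
#' are retained per window.
#'
#' @param activity \code{voxel_image}, MBq/ml.
#' @param density \code{voxel_image}, g/ml (converted to per-photopeak mu
#'   maps internally).
#' @param config an \code{acquisition_config}.
#' @param noise draw Poisson counts (default) or return the means.
#' @return object of class \code{projection_set}: \code{counts} (named list
#'   of nx x nz x n_angles arrays keyed e.g. \code{"pp208"}),
#'   \code{components} (pre-noise \code{primary}/\code{scatter} stacks),
#'   \code{angles}, \code{config}, \code{grid}, \code{windows}.
#' @export
acquire <- function(activity, density, config = acquisition_config(),
                    noise = TRUE) {
  stop_if_grid_mismatch(activity, density)
  check_sim_grid(activity)
  angles <- projection_angles(config)
  d <- dim(activity$values)
  counts <- list(); primary <- list(); scatter <- list(); windows <- list()
  for (peak in config$photopeaks) {
    key <- as.character(peak)
    mu <- mu_map_from_density(density, peak)
    for (wn in names(config$windows[[key]])) {
      wname <- paste0(wn, key)
      counts[[wname]] <- array(0, dim = c(d[1], d[3], length(angles)))
      primary[[wname]] <- array(0, dim = c(d[1], d[3], length(angles)))
      scatter[[wname]] <- array(0, dim = c(d[1], d[3], length(angles)))
      windows[[wname]] <- c(config$windows[[key]][[wn]],
                            list(peak = peak, name = wname))
    }
    for (ai in seq_along(angles)) {
      prim <- forward_project(activity, mu, config, angles[ai], peak)
      sc <- scatter_project(activity, mu, config, angles[ai], peak)
      for (wn in names(config$windows[[key]])) {
        wname <- paste0(wn, key)
        if (config$windows[[key]][[wn]]$role == "photopeak") {
          primary[[wname]][, , ai] <- prim
        }
        scatter[[wname]][, , ai] <- sc[[wn]]
        counts[[wname]][, , ai] <- primary[[wname]][, , ai] + sc[[wn]]
      }
    }
  }
  if (noise) {
    set.seed(config$rng_seed)
    for (wname in names(counts)) {
      counts[[wname]] <- array(rpois(length(counts[[wname]]),
                                     counts[[wname]]),
                               dim = dim(counts[[wname]]))
    }
  }
  structure(list(counts = counts,
                 components = list(primary = primary, scatter = scatter),
                 angles = angles, config = config,
                 grid = list(dim = d, spacing = activity$spacing,
                             origin = activity$origin),
                 windows = windows),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d angles, windows: %s\n", length(x$angles),
              paste(names(x$counts), collapse = ", ")))
  for (w in names(x$counts)) {
    cat(sprintf("  %s: total counts %.4g\n", w, sum(x$counts[[w]])))
  }
  invisible(x)
}

#' Planar (static) acquisition
#'
#' Single parallel projection of a thin source at a fixed distance from the
#' collimator, with the distance-dependent response and no attenuation -- the
#' petri-dish calibration geometry.
#'
#' @param activity \code{voxel_image}, MBq/ml (a thin disc-like source).
#' @param config an \code{acquisition_config}.
#' @param distance mm from source plane to collimator.
#' @param peak photopeak.
#' @param noise draw Poisson counts.
#' @return matrix of counts (nx x nz).
#' @export
planar_acquire <- function(activity, config = acquisition_config(),
                           distance = 100, peak = 208, noise = FALSE) {
  stopifnot(inherits(activity, "voxel_image"))
  if (abs(activity$spacing[1] - activity$spacing[3]) > 1e-9) {
    stop("planar projection needs square detector pixels (dx == dz)",
         call. = FALSE)
  }
  key <- as.character(peak)
  act_voxel <- activity$values * voxel_volume_ml(activity)
  plane <- apply(act_voxel, c(1, 3), sum)
  fwhm <- sqrt(config$psf_fwhm_intrinsic[[key]]^2 +
                 (config$psf_fwhm_slope[[key]] * distance)^2)
  sigma_px <- fwhm / 2.354820045 / activity$spacing[1]
  mean_counts <- .conv2_gauss(plane, sigma_px) *
    config$sensitivity[[key]] * config$time_per_projection
  if (noise) {
    matrix(rpois(length(mean_counts), mean_counts), nrow = nrow(mean_counts))
  } else {
    mean_counts
  }
}

#' Thin disc (petri-dish) source
#'
#' @param activity_mbq total activity, MBq.
#' @param diameter mm.
#' @param spacing mm.
#' @param n grid size (n x 3 x n voxels; the disc occupies the middle slab).
#' @return \code{voxel_image} with role \code{"activity"}.
#' @export
disc_source <- function(activity_mbq, diameter = 60, spacing = 4.8, n = 48) {
  stopifnot(activity_mbq >= 0, diameter > 0)
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  in_disc <- outer(co^2, co^2, "+") <= (diameter / 2)^2
  vals <- array(0, dim = c(n, 3, n))
  nvox <- sum(in_disc)
  conc <- activity_mbq / (nvox * spacing^3 / 1000)
  slab <- vals[, 2, ]
  slab[in_disc] <- conc
  vals[, 2, ] <- slab
  voxel_image(vals, spacing, role = "activity")
}
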