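#' Run one site protocol end to end
#'
#' Executes calibrate -> simulate -> reconstruct -> segment -> quantify with
#' a protocol's settings on one simulated comparison source, at desk scale
#' (reduced grid and projection count; subsets are adapted to divide the
#' projection count). Deterministic under \code{seed}.
#'
#' @name run_protocol
NULL

# ---- calibration stage per method ------------------------------------------

calibrate_protocol <- function(protocol, acq, rcfg, spacing, grid_n, seed,
                               noise, comparison_source) {
  t_eff <- acq$time_per_projection
  method <- protocol$calibration
  extras <- list()

  run_sphere_positions <- function(positions, volume_ml, total_mbq,
                                   voi_deltas = 0) {
    # one acquisition + recon per sphere position; VOI(s) on the CT sphere
    factors <- c()
    poisson_rel <- c()
    conc <- total_mbq / volume_ml
    for (pi in seq_along(positions)) {
      pos <- positions[[pi]]
      ph <- empty_body_phantom(spacing, grid_n, in_air = isTRUE(pos$in_air))
      sp <- add_sphere_source(ph, pos$centre, volume_ml, conc)
      acq_i <- acq; acq_i$rng_seed <- as.integer(seed + 100 + pi)
      rec <- sim_and_recon(sp$phantom$activity, sp$phantom$density, acq_i,
                           rcfg, noise)
      for (dd in voi_deltas) {
        voi <- sphere_voi(pos$centre, 2 * sp$radius_mm + dd, 0,
                          rec)
        cps <- counts_in_voi(rec, voi)
        factors <- c(factors, (cps) / sp$activity_mbq)
        poisson_rel <- c(poisson_rel, 1 / sqrt(max(cps * t_eff, 1)))
      }
    }
    list(factors = factors, poisson_rel = poisson_rel)
  }

  if (method == "matched") {
    cal <- NULL # filled after the comparison recon (factor_truth)
  } else if (method == "large_homogeneous") {
    # 130-ml bottle plus the three largest NEMA spheres, one acquisition
    ph <- empty_body_phantom(spacing, grid_n)
    bottle <- add_sphere_source(ph, c(-95, 50, 0), 130, 2.0)
    ph <- bottle$phantom
    nema <- list()
    nema_d <- c(22, 28, 37)
    nema_pos <- list(c(-20, 60, 0), c(30, 60, 0), c(85, 45, 0))
    for (i in seq_along(nema_d)) {
      vol <- 4 / 3 * pi * (nema_d[i] / 20)^3
      nema[[i]] <- add_sphere_source(ph, nema_pos[[i]], vol, 2.0)
      ph <- nema[[i]]$phantom
    }
    acq_c <- acq; acq_c$rng_seed <- as.integer(seed + 101)
    rec <- sim_and_recon(ph$activity, ph$density, acq_c, rcfg, noise)
    voi <- sphere_voi(c(-95, 50, 0), 2 * bottle$radius_mm, 10, rec)
    cps <- counts_in_voi(rec, voi)
    counts <- cps * t_eff
    cal <- calib_factor_from_voi(counts, t_eff, bottle$activity_mbq,
                                 method = "large_homogeneous")
    # partial-volume check on the NEMA spheres: volume threshold for PVC
    rc_sphere <- vapply(seq_along(nema), function(i) {
      voi_i <- sphere_voi(nema_pos[[i]], 2 * nema[[i]]$radius_mm, 10, rec)
      est <- counts_in_voi(rec, voi_i) / cal$factor
      est / nema[[i]]$activity_mbq
    }, numeric(1))
    vols <- vapply(nema, function(s) s$volume_ml, numeric(1))
    ok <- which(rc_sphere >= 0.95)
    extras$nema_rc <- data.frame(volume_ml = vols, rc = rc_sphere)
    extras$pvc_threshold_ml <- if (length(ok)) min(vols[ok]) else Inf
    extras$poisson_rel_calib <- 1 / sqrt(counts)
  } else if (method == "shell_matched") {
    # same shell-sphere design, two depths; factor at the matched depth
    depths <- list(c(0, 0, 0), c(0, 60, 0))
    factors <- numeric(0)
    recs <- list()
    shells <- list()
    for (di in seq_along(depths)) {
      src <- shell_source_spec(site = "H2", centre = depths[[di]])
      ph <- make_body_phantom(source = src, spacing = spacing,
                              fov = grid_n * spacing)
      acq_i <- acq; acq_i$rng_seed <- as.integer(seed + 110 + di)
      rec <- sim_and_recon(ph$activity, ph$density, acq_i, rcfg, noise)
      voi <- sphere_voi(depths[[di]], 2 * src$r_outer, 5, rec)
      a_true <- total_activity(ph$activity)
      factors <- c(factors, counts_in_voi(rec, voi) / a_true)
      recs[[di]] <- rec
      shells[[di]] <- list(src = src, ph = ph)
    }
    # comparison source sits at the phantom centre: depth-match to depth 1
    dsurf <- vapply(depths, function(d) {
      1 - sqrt(sum((d[1:2] / c(305 / 2, 221 / 2))^2))
    }, numeric(1))
    tgt <- 1 - sqrt(sum((comparison_source$centre[1:2] /
                           c(305 / 2, 221 / 2))^2))
    pick <- which.min(abs(dsurf - tgt))
    cal <- calibration_result(factors[pick], stats::sd(factors),
                              "shell_matched", length(factors))
    # threshold selection against the known shell volumes
    src <- shells[[pick]]$src
    region <- sphere_voi(src$centre, 4 * src$r_outer, 0, recs[[pick]])
    extras$inner_fraction <- calibrate_iso_threshold(
      recs[[pick]], src$inner_volume, region)
    extras$outer_fraction <- calibrate_iso_threshold(
      recs[[pick]], src$inner_volume + src$outer_volume, region)
  } else if (method == "sphere16ml") {
    res <- run_sphere_positions(list(list(centre = c(0, 0, 0))), 16, 20)
    counts <- res$factors * 20 * t_eff # back out counts for the Poisson term
    cal <- calib_factor_from_voi(counts[1], t_eff, 20, method = "sphere16ml")
    extras$poisson_rel_calib <- res$poisson_rel
  } else if (method == "sphere16ml_multi_position") {
    positions <- list(list(centre = c(0, 0, 0), in_air = TRUE),
                      list(centre = c(0, 0, 0)),
                      list(centre = c(120, 0, 0)))
    res <- run_sphere_positions(positions, 16, 35)
    cal <- calibration_result(mean(res$factors), stats::sd(res$factors),
                              "sphere16ml_multi_position",
                              length(res$factors))
    extras$poisson_rel_calib <- mean(res$poisson_rel)
  } else if (method == "sphere16ml_six_voi") {
    positions <- list(list(centre = c(0, 0, 0), in_air = TRUE),
                      list(centre = c(0, 0, 0)),
                      list(centre = c(120, 0, 0)))
    res <- run_sphere_positions(positions, 16, 25,
                                voi_deltas = c(-spacing, spacing))
    cal <- calibration_result(mean(res$factors), stats::sd(res$factors),
                              "sphere16ml_six_voi", length(res$factors))
  } else if (method == "large_cylinder") {
    cyl <- cylinder_phantom(spacing, grid_n)
    acq_i <- acq; acq_i$rng_seed <- as.integer(seed + 120)
    rec <- sim_and_recon(cyl$activity, cyl$density, acq_i, rcfg, noise)
    voi <- sphere_voi(c(0, 0, 0), 100, 0, rec)
    a_voi <- cyl$concentration * mask_volume(voi)
    cal <- calibration_result(counts_in_voi(rec, voi) / a_voi, 0,
                              "large_cylinder", 1L)
  } else if (method == "planar_petri") {
    set.seed(seed + 130)
    imgs <- lapply(1:5, function(i) {
      planar_acquire(disc_source(40, spacing = spacing,
                                 n = min(grid_n, 48)),
                     acq, distance = 100, noise = noise)
    })
    cal <- calib_factor_planar(imgs, roi_diameter = 100,
                               activities = 40,
                               time = acq$time_per_projection,
                               pixel_mm = spacing)
    # recovery curve from SPECT images of spheres of known activity
    vols <- c(8, 16, 30, 100)
    rc <- numeric(length(vols))
    for (i in seq_along(vols)) {
      ph <- empty_body_phantom(spacing, grid_n)
      sp <- add_sphere_source(ph, c(0, 0, 0), vols[i], 2.0)
      acq_i <- acq; acq_i$rng_seed <- as.integer(seed + 140 + i)
      rec <- sim_and_recon(sp$phantom$activity, sp$phantom$density, acq_i,
                           rcfg, noise)
      region <- sphere_voi(c(0, 0, 0), 4 * sp$radius_mm + 40, 0, rec)
      voi <- otsu_voi(rec, region)
      est <- counts_in_voi(rec, voi) / cal$factor
      rc[i] <- min(est / sp$activity_mbq, 1.2)
    }
    extras$recovery_curve <- fit_recovery_curve(vols, rc)
    extras$recovery_rel_unc <-
      stats::sd(extras$recovery_curve$residuals) / mean(rc)
  } else {
    stop("unknown calibration method: ", method, call. = FALSE)
  }
  list(calibration = cal, extras = extras)
}

# ---- segmentation stage ----------------------------------------------------

segment_protocol <- function(protocol, rec, phantom, seed) {
  seg <- protocol$segmentation
  src <- phantom$source
  centre <- src$centre
  if (seg$method == "truth") {
    inner <- phantom$truth_masks$inner
    outer <- phantom$truth_masks$outer
  } else if (seg$method == "ct_sphere_margin") {
    inner <- sphere_voi(centre, 2 * src$r_inner, seg$margin, rec)
    outer_surf <- sphere_voi(centre, 2 * src$r_outer, seg$margin, rec)
    outer <- shell_subtract(outer_surf, inner)
  } else if (seg$method == "iso_contour") {
    region <- sphere_voi(centre, 4 * src$r_outer, 0, rec)
    inner <- iso_contour_voi(rec, seg$inner_fraction, region)
    outer_surf <- iso_contour_voi(rec, seg$outer_fraction, region)
    outer <- shell_subtract(outer_surf, inner)
  } else if (seg$method == "manual_truth") {
    set.seed(seed + 7)
    pert <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    inner <- perturb_mask(phantom$truth_masks$inner, pert[1])
    whole <- with_values(phantom$truth_masks$inner,
                         array(as.numeric(
                           phantom$truth_masks$inner$values > 0 |
                             phantom$truth_masks$outer$values > 0),
                           dim = dim(phantom$truth_masks$inner$values)))
    outer <- shell_subtract(perturb_mask(whole, pert[2]), inner)
  } else if (seg$method == "fixed_sphere") {
    inner <- fixed_sphere_voi(centre, seg$diameter, rec)
    outer <- NULL
  } else if (seg$method == "otsu_manual") {
    region <- sphere_voi(centre, 4 * src$r_outer, 0, rec)
    inner <- otsu_voi(rec, region)
    set.seed(seed + 7)
    pert <- sample(c(-1L, 0L, 1L), 1)
    whole <- with_values(phantom$truth_masks$inner,
                         array(as.numeric(
                           phantom$truth_masks$inner$values > 0 |
                             phantom$truth_masks$outer$values > 0),
                           dim = dim(phantom$truth_masks$inner$values)))
    outer <- list(whole = perturb_mask(whole, pert)) # activity by difference
  } else {
    stop("unknown segmentation method: ", seg$method, call. = FALSE)
  }
  list(inner = inner, outer = outer)
}

# ---- quantification + uncertainty stage ------------------------------------

quantify_protocol <- function(protocol, rec, vois, cal, extras, t_eff) {
  id <- protocol$id
  cps_inner <- counts_in_voi(rec, vois$inner)
  v_inner <- mask_volume(vois$inner)
  recovery <- extras$recovery_curve
  a_inner <- if (!is.null(recovery)) {
    activity_estimate(cps_inner, cal, recovery, v_inner)
  } else {
    activity_estimate(cps_inner, cal)
  }
  whole_diff <- is.list(vois$outer) && !is.null(vois$outer$whole)
  if (is.null(vois$outer)) {
    a_outer <- NA_real_; v_outer <- NA_real_; cps_outer <- NA_real_
  } else if (whole_diff) {
    # activity in the inner VOI subtracted from the whole-source VOI
    cps_whole <- counts_in_voi(rec, vois$outer$whole)
    v_outer <- mask_volume(vois$outer$whole) - v_inner
    a_outer <- max(activity_estimate(cps_whole, cal) - a_inner, 0)
    cps_outer <- max(cps_whole - cps_inner, 0)
  } else {
    cps_outer <- counts_in_voi(rec, vois$outer)
    v_outer <- mask_volume(vois$outer)
    a_outer <- activity_estimate(cps_outer, cal)
  }

  rel_unc <- function(compartment_cps) {
    counts <- max(compartment_cps * t_eff, 1e-9)
    switch(protocol$uncertainty,
      poisson_activity = sqrt(extras$poisson_rel_calib[1]^2 + 0.01^2),
      sd_calibration = cal$sigma / cal$factor,
      poisson_calib_voi = sqrt(extras$poisson_rel_calib[1]^2 + 1 / counts),
      sd_calibration_activity = sqrt((cal$sigma / cal$factor)^2 + 0.01^2),
      sd_calibration_recovery = sqrt((cal$sigma / cal$factor)^2 +
                                       extras$recovery_rel_unc^2),
      none = NA_real_)
  }

  rows <- quant_result(id, "inner", v_inner, a_inner,
                       a_inner * rel_unc(cps_inner))
  if (!is.null(vois$outer)) {
    rows <- rbind(rows, quant_result(id, "outer", v_outer, a_outer,
                                     a_outer * rel_unc(cps_outer)))
    sig_tot <- sqrt(sum(c(rows$sigma_mbq)^2))
    rows <- rbind(rows, quant_result(id, "total", v_inner + v_outer,
                                     a_inner + a_outer, sig_tot))
  }
  rows
}

#' Execute a full site protocol on a simulated comparison source
#'
#' @param protocol a \code{site_protocol} or protocol id string.
#' @param phantom optional phantom list from [make_body_phantom()] (with its
#'   \code{source}); by default the site's own shell source (measured
#'   volumes, 15:1 concentration ratio) at the phantom centre.
#' @param seed integer; drives every random stage (calibration noise,
#'   comparison noise, manual-VOI perturbations).
#' @param spacing mm, simulation voxel/pixel size.
#' @param grid_n simulation grid size per axis (grid is cubic).
#' @param n_projections desk-scale projection count (clinically 120).
#' @param noise Poisson noise on (default) or off.
#' @return list with \code{results} (data.frame of per-compartment volume,
#'   activity and uncertainty), \code{truth} (voxelized true volumes and
#'   activities), \code{calibration}, \code{vois}, \code{recon} and
#'   \code{extras}.
#' @export
run_protocol <- function(protocol, phantom = NULL, seed = 1,
                         spacing = 4.8, grid_n = 64, n_projections = 60,
                         noise = TRUE) {
  if (is.character(protocol)) protocol <- site_protocol(protocol)
  stopifnot(inherits(protocol, "site_protocol"))
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(phantom)) {
    site <- if (protocol$id %in% SHELL_SPHERE_VOLUMES$site) protocol$id
            else "H1"
    phantom <- make_body_phantom(source = shell_source_spec(site = site),
                                 spacing = spacing, fov = grid_n * spacing)
  }
  acq <- protocol_acquisition(protocol, grid_n, n_projections, seed)
  rcfg <- protocol_recon(protocol, n_projections)

  calst <- calibrate_protocol(protocol, acq, rcfg, spacing, grid_n, seed,
                              noise, phantom$source)
  cal <- calst$calibration
  extras <- calst$extras
  if (protocol$segmentation$method == "iso_contour" &&
      isTRUE(protocol$segmentation$calibrate) &&
      !is.null(extras$inner_fraction)) {
    protocol$segmentation$inner_fraction <- extras$inner_fraction
    protocol$segmentation$outer_fraction <- extras$outer_fraction
  }

  proj <- acquire(phantom$activity, phantom$density, acq, noise = noise)
  rec <- osem_reconstruct(proj, phantom$density, rcfg)
  if (is.null(cal)) { # matched calibration: the known simulated sensitivity
    cal <- calibration_result(rec$factor_truth, 0, "matched")
  }

  vois <- segment_protocol(protocol, rec, phantom, seed)
  results <- quantify_protocol(protocol, rec, vois, cal, extras,
                               acq$time_per_projection)

  a_in <- sum(phantom$truth_masks$inner$values * phantom$activity$values) *
    voxel_volume_ml(phantom$activity)
  a_out <- sum(phantom$truth_masks$outer$values * phantom$activity$values) *
    voxel_volume_ml(phantom$activity)
  truth <- list(
    volumes = c(inner = mask_volume(phantom$truth_masks$inner),
                outer = mask_volume(phantom$truth_masks$outer)),
    activities = c(inner = a_in, outer = a_out, total = a_in + a_out)
  )
  truth$volumes["total"] <- sum(truth$volumes)

  list(protocol = protocol$id, results = results, truth = truth,
       calibration = cal, vois = vois, recon = rec, extras = extras)
}
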