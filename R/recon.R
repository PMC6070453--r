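#' OSEM/MLEM reconstruction
#'
#' Ordered-subset EM with CT attenuation correction, selectable scatter
#' handling (none, triple-energy-window, or the simulator's true scatter as
#' an "ideal" surrogate for site-specific Monte-Carlo/ESSE corrections),
#' optional resolution recovery (depth-dependent PSF in the system model),
#' per-photopeak reconstruction with post-summation, and Gaussian
#' post-filtering. With \code{subsets = 1} the update is exact MLEM.
#'
#' @name recon
NULL

#' Reconstruction configuration
#'
#' @param iterations number of OSEM iterations (>= 1).
#' @param subsets number of angular subsets; must divide the number of
#'   projections.
#' @param scatter_correction \code{"none"}, \code{"TEW"} or \code{"ideal"}.
#' @param resolution_recovery include the collimator-detector response in the
#'   system model.
#' @param post_filter_fwhm mm, 3-D Gaussian post-filter (NULL for none).
#' @param photopeaks photopeaks to reconstruct and sum (subset of the
#'   acquired ones).
#' @param scatter_presubtract subtract the scatter estimate from the counts
#'   before reconstruction instead of adding it to the forward model (the
#'   H5-style workflow).
#' @param tew_smooth_px Gaussian smoothing (pixels) applied to TEW estimates
#'   before use.
#' @return object of class \code{recon_config}.
#' @export
recon_config <- function(iterations, subsets,
                         scatter_correction = c("none", "TEW", "ideal"),
                         resolution_recovery = FALSE,
                         post_filter_fwhm = NULL, photopeaks = 208,
                         scatter_presubtract = FALSE, tew_smooth_px = 2) {
  scatter_correction <- match.arg(scatter_correction)
  stopifnot(iterations >= 1, subsets >= 1)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 scatter_correction = scatter_correction,
                 resolution_recovery = resolution_recovery,
                 post_filter_fwhm = post_filter_fwhm,
                 photopeaks = photopeaks,
                 scatter_presubtract = scatter_presubtract,
                 tew_smooth_px = tew_smooth_px),
            class = "recon_config")
}

#' Triple-energy-window scatter estimate
#'
#' Trapezoidal TEW: pixelwise
#' \eqn{S = (C_{low}/w_{low} + C_{up}/w_{up})/2 \cdot w_{peak}} with the
#' window widths in keV, clipped at zero.
#'
#' @param projections a \code{projection_set}.
#' @param photopeak,lower,upper window names in the set (e.g. "pp208",
#'   "ls208", "us208").
#' @return array of per-angle scatter estimates, same shape as the photopeak
#'   counts.
#' @export
tew_estimate <- function(projections, photopeak = "pp208",
                         lower = "ls208", upper = "us208") {
  stopifnot(inherits(projections, "projection_set"))
  for (w in c(photopeak, lower, upper)) {
    if (!w %in% names(projections$counts)) {
      stop("window not present in projection set: ", w, call. = FALSE)
    }
  }
  w_pk <- projections$windows[[photopeak]]$width_kev
  w_lo <- projections$windows[[lower]]$width_kev
  w_up <- projections$windows[[upper]]$width_kev
  s <- (projections$counts[[lower]] / w_lo +
          projections$counts[[upper]] / w_up) / 2 * w_pk
  s[s < 0] <- 0
  s
}

# interleaved angle subsets: subset s gets angles s, s+nsub, s+2*nsub, ...
subset_indices <- function(n_angles, subsets) {
  lapply(seq_len(subsets), function(s) seq(s, n_angles, by = subsets))
}

#' Largest divisor of the projection count not exceeding a requested subset
#' count (used to adapt clinical subset settings to desk-scale acquisitions)
#' @param n_angles number of projections.
#' @param subsets requested subsets.
#' @return integer divisor of \code{n_angles}.
#' @export
adapt_subsets <- function(n_angles, subsets) {
  divs <- which(n_angles %% seq_len(n_angles) == 0)
  max(divs[divs <= subsets])
}

# single-photopeak OSEM, x in MBq per voxel
osem_single <- function(counts, mu_img, projections, peak, iterations,
                        subsets, use_psf, scatter_term = NULL,
                        track_loglik = FALSE) {
  cfg <- projections$config
  key <- as.character(peak)
  d <- projections$grid$dim
  spacing <- projections$grid$spacing[1]
  angles <- projections$angles
  n_angles <- length(angles)
  if (n_angles %% subsets != 0) {
    stop("subset count must divide the number of projections", call. = FALSE)
  }
  if (!is.null(scatter_term) && any(scatter_term < 0)) {
    stop("scatter term must be nonnegative", call. = FALSE)
  }
  sens_time <- cfg$sensitivity[[key]] * cfg$time_per_projection
  psf_int <- cfg$psf_fwhm_intrinsic[[key]]
  psf_slope <- cfg$psf_fwhm_slope[[key]]
  radii <- vapply(angles, function(a) orbit_radius_at(cfg, a, mu_img),
                  numeric(1))
  mu <- mu_img$values
  eps <- 1e-12

  # uniform-disk initial image: positive inside the inscribed cylinder
  nx <- d[1]; ny <- d[2]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  rin <- (min(nx, ny) / 2 - 1)^2
  disk <- outer((seq_len(nx) - 1 - cx)^2, (seq_len(ny) - 1 - cy)^2, "+") <= rin
  x <- array(0, dim = d)
  x[rep(disk, d[3])] <- 1

  subs <- subset_indices(n_angles, subsets)
  # per-subset sensitivity images
  sens_img <- lapply(subs, function(ix) {
    s <- array(0, dim = d)
    for (a in ix) {
      s <- s + bp_counts(matrix(1, nx, d[3]), mu, d, spacing, angles[a],
                         sens_time, radii[a], psf_int, psf_slope,
                         use_psf, TRUE)
    }
    s
  })
  loglik <- if (track_loglik) numeric(iterations) else NULL

  for (it in seq_len(iterations)) {
    ll <- 0
    for (s in seq_along(subs)) {
      back <- array(0, dim = d)
      for (a in subs[[s]]) {
        m <- fp_counts(x, mu, d, spacing, angles[a], sens_time, radii[a],
                       psf_int, psf_slope, use_psf, TRUE)
        if (!is.null(scatter_term)) m <- m + scatter_term[, , a]
        m <- pmax(m, eps)
        y <- counts[, , a]
        if (track_loglik) ll <- ll + sum(y * log(m) - m)
        back <- back + bp_counts(y / m, mu, d, spacing, angles[a],
                                 sens_time, radii[a], psf_int, psf_slope,
                                 use_psf, TRUE)
      }
      x <- x * back / pmax(sens_img[[s]], eps)
      x[sens_img[[s]] <= eps] <- 0
    }
    if (track_loglik) loglik[it] <- ll
  }
  list(x = x, loglik = loglik)
}

#' OSEM reconstruction of a projection set
#'
#' Reconstructs each requested photopeak with its own attenuation map and
#' scatter handling, converts the per-peak activity estimates to count-rate
#' (cps per voxel) with the corresponding sensitivity, sums the peaks and
#' applies the optional post-filter.
#'
#' @param projections a \code{projection_set} from [acquire()].
#' @param density \code{voxel_image} (g/ml) on the acquisition grid, used to
#'   derive the per-photopeak attenuation maps (the digital stand-in for the
#'   CT).
#' @param config a \code{recon_config}.
#' @param scatter_term optional explicit scatter estimate (named list by
#'   photopeak window) overriding \code{config$scatter_correction}.
#' @param track_loglik with \code{subsets = 1}, record the Poisson
#'   log-likelihood of the iterates (returned as \code{$loglik}).
#' @return object of class \code{c("recon_volume", "voxel_image")}: count-rate
#'   image (cps/voxel) with fields \code{config},
#'   \code{time_per_projection}, \code{factor_truth} (the matched cps/MBq
#'   factor, i.e. the summed sensitivities) and optionally \code{loglik}.
#' @export
osem_reconstruct <- function(projections, density, config,
                             scatter_term = NULL, track_loglik = FALSE) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(config, "recon_config"))
  if (!identical(dim(density$values), projections$grid$dim)) {
    stop("density map is not on the acquisition grid", call. = FALSE)
  }
  cps <- array(0, dim = projections$grid$dim)
  factor_truth <- 0
  loglik <- NULL
  for (peak in config$photopeaks) {
    key <- as.character(peak)
    wname <- paste0("pp", key)
    if (!wname %in% names(projections$counts)) {
      stop("photopeak window missing from the acquisition: ", wname,
           call. = FALSE)
    }
    counts <- projections$counts[[wname]] * 1.0
    term <- if (!is.null(scatter_term)) {
      scatter_term[[wname]]
    } else if (config$scatter_correction == "ideal") {
      projections$components$scatter[[wname]]
    } else if (config$scatter_correction == "TEW") {
      s <- tew_estimate(projections, wname, paste0("ls", key),
                        paste0("us", key))
      if (config$tew_smooth_px > 0) {
        for (a in seq_len(dim(s)[3])) {
          s[, , a] <- .conv2_gauss(s[, , a], config$tew_smooth_px)
        }
      }
      s
    } else {
      NULL
    }
    if (!is.null(term) && config$scatter_presubtract) {
      counts <- pmax(counts - term, 0)
      term <- NULL
    }
    mu_img <- mu_map_from_density(density, peak)
    fit <- osem_single(counts, mu_img, projections, peak,
                       config$iterations, config$subsets,
                       use_psf = config$resolution_recovery,
                       scatter_term = term, track_loglik = track_loglik)
    cps <- cps + fit$x * projections$config$sensitivity[[key]]
    factor_truth <- factor_truth + projections$config$sensitivity[[key]]
    if (!is.null(fit$loglik)) loglik <- fit$loglik
  }
  out <- voxel_image(cps, projections$grid$spacing, projections$grid$origin,
                     role = "counts")
  out$config <- config
  out$time_per_projection <- projections$config$time_per_projection
  out$factor_truth <- factor_truth
  out$loglik <- loglik
  class(out) <- c("recon_volume", "voxel_image")
  if (!is.null(config$post_filter_fwhm) && config$post_filter_fwhm > 0) {
    out <- gaussian_postfilter(out, config$post_filter_fwhm)
  }
  out
}

#' Sum individually reconstructed photopeak volumes
#' @param recons list of \code{recon_volume}s on one grid.
#' @return a \code{recon_volume} with voxelwise-summed count rates.
#' @export
sum_photopeaks <- function(recons) {
  stopifnot(length(recons) >= 1)
  out <- recons[[1]]
  if (length(recons) > 1) {
    for (r in recons[-1]) {
      stop_if_grid_mismatch(out, r)
      out$values <- out$values + r$values
      if (!is.null(out$factor_truth) && !is.null(r$factor_truth)) {
        out$factor_truth <- out$factor_truth + r$factor_truth
      }
    }
  }
  out
}

#' Gaussian post-filter
#' @param recon a \code{recon_volume} (or any \code{voxel_image}).
#' @param fwhm mm, >= 0 (0 is the identity).
#' @return filtered image of the same class.
#' @export
gaussian_postfilter <- function(recon, fwhm) {
  stopifnot(inherits(recon, "voxel_image"))
  if (fwhm < 0) stop("post-filter FWHM must be >= 0", call. = FALSE)
  if (fwhm == 0) return(recon)
  sigma_px <- fwhm / 2.354820045 / recon$spacing
  recon$values <- .conv3_gauss(recon$values, as.integer(dim(recon$values)),
                               sigma_px)
  recon
}
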