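#' Camera calibration and recovery-coefficient curves
#'
#' Converts measured counts into a cps/MBq calibration factor by the
#' geometries the sites used (large homogeneous source, 16-ml sphere at one
#' or several positions, a shell source matched to the comparison geometry,
#' or planar petri-dish imaging), and fits/applies a recovery-coefficient
#' curve RC(V) = 1 - exp(-(V / v0)^p) describing the partial-volume count
#' loss versus object volume.
#'
#' @name calibration
NULL

#' Calibration result container
#' @param factor cps/MBq (> 0).
#' @param sigma absolute standard uncertainty of the factor, cps/MBq.
#' @param method one of \code{"large_homogeneous"},
#'   \code{"sphere16ml_multi_position"}, \code{"shell_matched"},
#'   \code{"planar_petri"}, \code{"matched"}.
#' @param n_measurements number of measurements combined.
#' @return object of class \code{calibration_result}.
#' @export
calibration_result <- function(factor, sigma = 0, method = "matched",
                               n_measurements = 1L) {
  if (factor <= 0) stop("calibration factor must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(factor = factor, sigma = sigma, method = method,
                 n_measurements = as.integer(n_measurements)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %.4g +/- %.3g cps/MBq (%s, n=%d)\n",
              x$factor, x$sigma, x$method, x$n_measurements))
  invisible(x)
}

#' cps/MBq factor from VOI counts
#'
#' \code{factor = (counts / time) / activity}. With several measurements
#' (vectors), the factor is their mean and sigma their standard deviation;
#' with a single measurement sigma combines Poisson counting noise with the
#' relative uncertainty of the calibration activity in quadrature.
#'
#' @param counts total counts in the calibration VOI (vector for
#'   multi-position calibrations).
#' @param acquisition_time s (effective time such that counts/time is the
#'   VOI count rate).
#' @param true_activity MBq (scalar or per-measurement).
#' @param sigma_activity_rel relative standard uncertainty of the
#'   calibration activity.
#' @param method label stored in the result.
#' @return a \code{calibration_result}.
#' @export
calib_factor_from_voi <- function(counts, acquisition_time, true_activity,
                                  sigma_activity_rel = 0.01,
                                  method = "large_homogeneous") {
  if (any(counts <= 0) || acquisition_time <= 0 || any(true_activity <= 0)) {
    stop("counts, time and activity must be positive", call. = FALSE)
  }
  factors <- (counts / acquisition_time) / true_activity
  f <- mean(factors)
  sigma <- if (length(factors) > 1) {
    stats::sd(factors)
  } else {
    f * sqrt(1 / counts + sigma_activity_rel^2)
  }
  calibration_result(f, sigma, method, length(factors))
}

#' cps/MBq factor from planar petri-dish images
#'
#' Counts in a centred circular ROI around each dish, background-corrected
#' with the mean per-pixel counts outside the dish region, divided by time
#' and dispensed activity; the factor is the mean over sources and sigma
#' their standard deviation.
#'
#' @param planar_images list of count matrices from [planar_acquire()].
#' @param roi_diameter mm.
#' @param activities MBq per dish (recycled).
#' @param time s per image.
#' @param pixel_mm pixel size of the planar images.
#' @param background_margin mm between the ROI edge and the background
#'   region.
#' @return a \code{calibration_result} with method \code{"planar_petri"}.
#' @export
calib_factor_planar <- function(planar_images, roi_diameter = 100,
                                activities, time, pixel_mm,
                                background_margin = 20) {
  stopifnot(length(planar_images) >= 1)
  if (any(activities <= 0)) {
    stop("counts, time and activity must be positive", call. = FALSE)
  }
  activities <- rep_len(activities, length(planar_images))
  n <- nrow(planar_images[[1]])
  m <- ncol(planar_images[[1]])
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  d2 <- outer(((seq_len(n) - cx) * pixel_mm)^2,
              ((seq_len(m) - cy) * pixel_mm)^2, "+")
  roi <- d2 <= (roi_diameter / 2)^2
  if (!any(roi) || all(roi)) {
    stop("ROI does not fit inside the planar image", call. = FALSE)
  }
  bg_region <- d2 > (roi_diameter / 2 + background_margin)^2
  factors <- vapply(seq_along(planar_images), function(i) {
    img <- planar_images[[i]]
    bg_per_px <- if (any(bg_region)) mean(img[bg_region]) else 0
    c_net <- sum(img[roi]) - bg_per_px * sum(roi)
    (c_net / time) / activities[i]
  }, numeric(1))
  calibration_result(mean(factors),
                     if (length(factors) > 1) stats::sd(factors) else 0,
                     "planar_petri", length(factors))
}

#' Fit a recovery-coefficient curve
#'
#' Least-squares fit of RC(V) = 1 - exp(-(V / v0)^p) to measured
#' recovery-coefficient-versus-volume data. The form is monotone increasing,
#' RC(0) = 0 and RC -> 1 as V -> infinity.
#'
#' @param volumes ml, at least 3 distinct values.
#' @param measured_over_true recovery coefficients in (0, 1.2].
#' @return object of class \code{recovery_curve} with \code{v0}, \code{p},
#'   \code{residuals} and the data.
#' @export
fit_recovery_curve <- function(volumes, measured_over_true) {
  stopifnot(length(volumes) == length(measured_over_true))
  if (length(unique(volumes)) < 3) {
    stop("need at least 3 distinct volumes to fit a recovery curve",
         call. = FALSE)
  }
  if (any(measured_over_true <= 0) || any(measured_over_true > 1.2)) {
    stop("recovery coefficients must lie in (0, 1.2]", call. = FALSE)
  }
  rc <- pmin(measured_over_true, 0.999)
  # moment-style start: linearise log(-log(1 - RC)) = p log V - p log v0
  y <- log(-log(1 - rc))
  fit0 <- stats::lm(y ~ log(volumes))
  p0 <- max(unname(stats::coef(fit0)[2]), 0.2)
  v00 <- max(exp(-unname(stats::coef(fit0)[1]) / p0), 1e-3)
  df <- data.frame(v = volumes, rc = measured_over_true)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(rc ~ 1 - exp(-(v / v0)^p), data = df,
                 start = list(v0 = v00, p = p0),
                 algorithm = "port", lower = c(v0 = 1e-4, p = 0.05),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    v0 <- unname(cf["v0"]); p <- unname(cf["p"])
  } else {
    obj <- function(par) {
      sum((df$rc - (1 - exp(-(df$v / exp(par[1]))^exp(par[2]))))^2)
    }
    op <- stats::optim(c(log(v00), log(p0)), obj)
    v0 <- exp(op$par[1]); p <- exp(op$par[2])
  }
  pred <- 1 - exp(-(volumes / v0)^p)
  structure(list(v0 = v0, p = p, volumes = volumes,
                 rc = measured_over_true, residuals = measured_over_true - pred),
            class = "recovery_curve")
}

#' Evaluate a recovery curve
#' @param curve a \code{recovery_curve}.
#' @param volume ml.
#' @return RC(volume) in (0, 1).
#' @export
rc_value <- function(curve, volume) {
  stopifnot(inherits(curve, "recovery_curve"), all(volume > 0))
  1 - exp(-(volume / curve$v0)^curve$p)
}

#' Apply a recovery-coefficient correction
#'
#' Divides the activity estimate by RC(volume). Refuses to extrapolate into
#' the steep small-volume regime where RC falls below \code{rc_floor}.
#'
#' @param activity_estimate MBq.
#' @param volume ml of the measured object.
#' @param curve a \code{recovery_curve}.
#' @param rc_floor smallest usable RC.
#' @return corrected activity, MBq.
#' @export
apply_recovery <- function(activity_estimate, volume, curve,
                           rc_floor = 0.05) {
  stopifnot(volume > 0)
  rc <- rc_value(curve, volume)
  if (rc < rc_floor) {
    stop(sprintf("RC(%.3g ml) = %.3g below the extrapolation floor %.3g",
                 volume, rc, rc_floor), call. = FALSE)
  }
  activity_estimate / rc
}

#' Volume above which partial-volume correction is unnecessary
#'
#' Smallest volume with RC at least \code{rc_target} under the fitted curve
#' (closed form of the RC model).
#'
#' @param curve a \code{recovery_curve}.
#' @param rc_target RC considered "fully recovered" (default 0.95).
#' @return volume in ml.
#' @export
pvc_threshold_volume <- function(curve, rc_target = 0.95) {
  stopifnot(inherits(curve, "recovery_curve"), rc_target > 0, rc_target < 1)
  curve$v0 * (-log(1 - rc_target))^(1 / curve$p)
}
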