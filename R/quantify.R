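#' Counts-to-activity conversion and uncertainty budgets
#'
#' VOI count rates are converted to absolute activity through the protocol's
#' cps/MBq factor, optionally followed by a recovery-coefficient correction;
#' relative uncertainties combine Poisson counting statistics, the
#' calibration-factor uncertainty and any extra terms in quadrature.
#'
#' @name quantify
NULL

#' Count rate inside a VOI
#' @param recon a \code{recon_volume} (cps per voxel).
#' @param voi mask \code{voxel_image} on the same grid.
#' @return cps.
#' @export
counts_in_voi <- function(recon, voi) {
  stopifnot(inherits(recon, "voxel_image"), inherits(voi, "voxel_image"))
  if (voi$role != "mask") stop("`voi` must be a mask", call. = FALSE)
  stop_if_grid_mismatch(recon, voi)
  sum(recon$values * voi$values)
}

#' Activity estimate from a VOI count rate
#'
#' \code{A = cps / factor}, optionally divided by the recovery coefficient
#' at the VOI volume.
#'
#' @param cps VOI count rate.
#' @param calibration a \code{calibration_result}.
#' @param recovery optional \code{recovery_curve}.
#' @param volume ml, required with \code{recovery}.
#' @return MBq.
#' @export
activity_estimate <- function(cps, calibration, recovery = NULL,
                              volume = NULL) {
  stopifnot(inherits(calibration, "calibration_result"))
  if (calibration$factor <= 0) {
    stop("calibration factor must be positive", call. = FALSE)
  }
  a <- cps / calibration$factor
  if (!is.null(recovery)) {
    if (is.null(volume)) {
      stop("recovery correction needs the VOI volume", call. = FALSE)
    }
    a <- apply_recovery(a, volume, recovery)
  }
  a
}

#' Relative uncertainty of an activity estimate
#'
#' Quadrature combination
#' \eqn{\sigma_{rel} = \sqrt{1/N + (\sigma_F/F)^2 + \sum e_i^2}} of the
#' Poisson term of the measured counts N, the calibration-factor term and
#' any extra relative terms.
#'
#' @param counts total counts in the VOI (> 0).
#' @param calibration a \code{calibration_result}.
#' @param extra_terms numeric vector of additional relative sigmas.
#' @return relative standard uncertainty (dimensionless).
#' @export
uncertainty_estimate <- function(counts, calibration,
                                 extra_terms = numeric()) {
  stopifnot(inherits(calibration, "calibration_result"))
  if (counts <= 0) {
    stop("relative uncertainty undefined for zero counts", call. = FALSE)
  }
  sqrt(1 / counts + (calibration$sigma / calibration$factor)^2 +
         sum(extra_terms^2))
}

#' Quantification result row
#' @param protocol protocol id.
#' @param compartment \code{"inner"}, \code{"outer"} or \code{"total"}.
#' @param volume_ml VOI volume.
#' @param activity_mbq activity estimate.
#' @param sigma_mbq absolute uncertainty (NA when the protocol reports
#'   none).
#' @return one-row data.frame.
#' @export
quant_result <- function(protocol, compartment, volume_ml, activity_mbq,
                         sigma_mbq = NA_real_) {
  stopifnot(compartment %in% c("inner", "outer", "total"),
            activity_mbq >= 0, is.na(sigma_mbq) || sigma_mbq >= 0)
  data.frame(protocol = protocol, compartment = compartment,
             volume_ml = volume_ml, activity_mbq = activity_mbq,
             sigma_mbq = sigma_mbq, stringsAsFactors = FALSE)
}
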