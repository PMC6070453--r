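#' Volume-of-interest segmentation rules
#'
#' The four VOI families the sites used: CT-geometry spheres with an optional
#' radial margin, relative iso-contours on the reconstructed counts, Otsu
#' auto-thresholding, and fixed-diameter spheres; plus the shell-subtraction
#' arithmetic (outer-surface VOI minus inner VOI) and a truth-mask
#' perturbation standing in for freehand "manual" outlining. Intensity-based
#' masks keep their largest 6-connected component.
#'
#' @name segmentation
NULL

keep_largest_component <- function(vals, dims) {
  lab <- .label6(array(vals != 0, dim = dims), as.integer(dims))
  if (max(lab) <= 1) return(vals != 0)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Spherical VOI with a radial margin
#'
#' Voxels whose centre lies within \code{physical_diameter / 2 + margin} of
#' the centre. The clinical "+10 mm in each spatial direction" rule is a
#' radial margin: on the nominal 36-mm inner sphere it gives a 28-mm VOI
#' radius, leaving exactly the outermost 1 mm of the 29-mm physical shell
#' outside the inner VOI.
#'
#' @param centre numeric(3), mm (world coordinates).
#' @param physical_diameter mm.
#' @param margin mm added to the radius (>= 0).
#' @param grid a \code{voxel_image} defining the grid.
#' @return mask \code{voxel_image}.
#' @export
sphere_voi <- function(centre, physical_diameter, margin, grid) {
  stopifnot(inherits(grid, "voxel_image"), physical_diameter > 0,
            margin >= 0)
  radius <- physical_diameter / 2 + margin
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (dim(grid$values) - 0.5) * grid$spacing
  if (any(centre - radius < lo) || any(centre + radius > hi)) {
    stop("sphere VOI exceeds the grid bounds", call. = FALSE)
  }
  g <- list(n = dim(grid$values), spacing = grid$spacing,
            origin = grid$origin)
  d2 <- dist2_array(g, centre)
  voxel_image(array(as.numeric(d2 <= radius^2), dim = g$n), grid$spacing,
              grid$origin, role = "mask")
}

#' Fixed-diameter spherical VOI
#'
#' \code{sphere_voi()} with zero margin; e.g. the arbitrary 8-cm sphere used
#' in lieu of outlining the source.
#'
#' @inheritParams sphere_voi
#' @param diameter mm.
#' @return mask \code{voxel_image}.
#' @export
fixed_sphere_voi <- function(centre, diameter, grid) {
  sphere_voi(centre, diameter, 0, grid)
}

#' Relative iso-contour VOI
#'
#' Threshold at \code{threshold_fraction} times the maximum value inside the
#' search region; the largest 6-connected component is kept.
#'
#' @param recon \code{voxel_image} of reconstructed counts.
#' @param threshold_fraction in (0, 1].
#' @param search_region optional mask \code{voxel_image} restricting both the
#'   maximum search and the output.
#' @return mask \code{voxel_image}.
#' @export
iso_contour_voi <- function(recon, threshold_fraction, search_region = NULL) {
  stopifnot(inherits(recon, "voxel_image"),
            threshold_fraction > 0, threshold_fraction <= 1)
  region <- if (is.null(search_region)) {
    array(TRUE, dim = dim(recon$values))
  } else {
    stop_if_grid_mismatch(recon, search_region)
    search_region$values != 0
  }
  if (!any(region)) stop("empty search region", call. = FALSE)
  mx <- max(recon$values[region])
  if (mx <= 0) {
    stop("search region has no positive values to contour", call. = FALSE)
  }
  sel <- (recon$values >= threshold_fraction * mx) & region
  keep <- keep_largest_component(sel, dim(recon$values))
  voxel_image(array(as.numeric(keep), dim = dim(recon$values)),
              recon$spacing, recon$origin, role = "mask")
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based (256 bins over the data range) maximisation of the
#' between-class variance; the threshold is the upper edge of the optimal
#' bin.
#'
#' @param values numeric vector with at least two distinct values.
#' @param nbins number of histogram bins.
#' @return threshold value; voxels strictly above it form the foreground.
#' @export
otsu_threshold <- function(values, nbins = 256) {
  rng <- range(values)
  if (diff(rng) <= 0) {
    stop("degenerate histogram: region is constant", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(values, edges,
                                       rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids)
  mt <- sum(h * mids)
  # between-class variance for a cut after bin t
  valid <- which(w0 > 0 & w1 > 0)
  if (length(valid) == 0) {
    stop("degenerate histogram: region is constant", call. = FALSE)
  }
  bcv <- (mt * w0[valid] - m0[valid] * sum(h))^2 /
    (w0[valid] * w1[valid])
  edges[valid[which.max(bcv)] + 1]
}

#' Otsu auto-contour VOI
#'
#' @param recon \code{voxel_image} of reconstructed counts.
#' @param search_region optional mask \code{voxel_image}.
#' @return mask \code{voxel_image} (largest 6-connected component above the
#'   Otsu threshold).
#' @export
otsu_voi <- function(recon, search_region = NULL) {
  stopifnot(inherits(recon, "voxel_image"))
  region <- if (is.null(search_region)) {
    array(TRUE, dim = dim(recon$values))
  } else {
    stop_if_grid_mismatch(recon, search_region)
    search_region$values != 0
  }
  if (!any(region)) stop("empty search region", call. = FALSE)
  thr <- otsu_threshold(recon$values[region])
  sel <- (recon$values > thr) & region
  keep <- keep_largest_component(sel, dim(recon$values))
  voxel_image(array(as.numeric(keep), dim = dim(recon$values)),
              recon$spacing, recon$origin, role = "mask")
}

#' Shell subtraction
#'
#' Set difference of two masks on one grid: the outer-surface VOI minus the
#' inner-sphere VOI gives the shell VOI.
#'
#' @param outer_voi,inner_voi mask \code{voxel_image}s.
#' @return mask \code{voxel_image}.
#' @export
shell_subtract <- function(outer_voi, inner_voi) {
  stopifnot(inherits(outer_voi, "voxel_image"),
            inherits(inner_voi, "voxel_image"))
  stop_if_grid_mismatch(outer_voi, inner_voi)
  vals <- as.numeric(outer_voi$values != 0 & inner_voi$values == 0)
  voxel_image(array(vals, dim = dim(outer_voi$values)), outer_voi$spacing,
              outer_voi$origin, role = "mask")
}

# one 6-neighbourhood dilation (or erosion) step, implemented by shifts
shift_array <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0, dim = d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Morphological perturbation of a mask
#'
#' Dilates (\code{voxels > 0}) or erodes (\code{voxels < 0}) a mask by the
#' given number of 6-neighbourhood steps. Used to emulate operator
#' variability in "manual" freehand VOIs by perturbing the ground-truth mask
#' by about one voxel.
#'
#' @param mask mask \code{voxel_image}.
#' @param voxels integer, number of steps (sign = dilate/erode).
#' @return mask \code{voxel_image}.
#' @export
perturb_mask <- function(mask, voxels = 0) {
  stopifnot(inherits(mask, "voxel_image"))
  if (mask$role != "mask") stop("perturb_mask() needs a mask", call. = FALSE)
  a <- mask$values != 0
  n <- abs(as.integer(voxels))
  for (i in seq_len(n)) {
    nb <- a
    for (ax in 1:3) {
      nb <- nb | (shift_array(a, ax, 1) > 0) | (shift_array(a, ax, -1) > 0)
    }
    if (voxels > 0) {
      a <- nb
    } else {
      # erosion: voxels all of whose 6-neighbours are inside
      keep <- a
      for (ax in 1:3) {
        keep <- keep & (shift_array(a, ax, 1) > 0) &
          (shift_array(a, ax, -1) > 0)
      }
      a <- keep
    }
  }
  with_values(mask, array(as.numeric(a), dim = dim(mask$values)))
}

#' Calibrate an iso-contour threshold against a known volume
#'
#' Emulates the threshold-selection procedure of varying the relative
#' threshold until the segmented volume best matches a known volume,
#' on a calibration reconstruction.
#'
#' @param recon \code{voxel_image} of the calibration reconstruction.
#' @param target_volume_ml known volume to match.
#' @param search_region optional mask.
#' @param fractions candidate threshold fractions to scan.
#' @return the selected threshold fraction.
#' @export
calibrate_iso_threshold <- function(recon, target_volume_ml,
                                    search_region = NULL,
                                    fractions = seq(0.05, 0.9, by = 0.01)) {
  vols <- vapply(fractions, function(f) {
    mask_volume(iso_contour_voi(recon, f, search_region))
  }, numeric(1))
  fractions[which.min(abs(vols - target_volume_ml))]
}
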