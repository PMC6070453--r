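#' Voxelized 3-D scalar image
#'
#' Minimal container used throughout the package for activity concentration
#' maps (MBq/ml), attenuation maps (1/cm), density maps (g/ml), reconstructed
#' count-rate maps (cps per voxel) and binary masks. Values are stored as a
#' plain 3-D array; \code{spacing} is the voxel edge length per axis in mm and
#' \code{origin} is the world coordinate (mm) of the centre of voxel
#' \code{[1, 1, 1]}.
#'
#' @param values 3-D numeric array.
#' @param spacing numeric(3), voxel spacing in mm (all > 0). A scalar is
#'   recycled to the three axes.
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#' @param role one of \code{"activity"}, \code{"mu"}, \code{"density"},
#'   \code{"counts"}, \code{"mask"}.
#' @return an object of class \code{voxel_image}.
#' @export
voxel_image <- function(values, spacing, origin = NULL,
                        role = c("activity", "mu", "density", "counts",
                                 "mask")) {
  role <- match.arg(role)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive on all axes", call. = FALSE)
  }
  if (is.null(origin)) {
    # grid centred on the world origin
    origin <- -(dim(values) - 1) / 2 * spacing
  }
  origin <- rep_len(as.numeric(origin), 3L)
  if (role %in% c("activity", "density", "counts") &&
      any(values < 0, na.rm = TRUE)) {
    stop(sprintf("'%s' images must be nonnegative", role), call. = FALSE)
  }
  if (role == "mask") {
    values <- array(as.numeric(values != 0), dim = dim(values))
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 role = role),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> role=%s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$role, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g], total %.4g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Voxel volume in ml
#' @param img a \code{voxel_image}.
#' @return volume of one voxel in ml (= cm^3).
#' @export
voxel_volume_ml <- function(img) {
  stopifnot(inherits(img, "voxel_image"))
  prod(img$spacing) / 1000
}

#' World coordinates of voxel centres along one axis
#' @param img a \code{voxel_image}.
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm coordinates.
#' @export
voxel_coords <- function(img, axis) {
  stopifnot(inherits(img, "voxel_image"), axis %in% 1:3)
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - 1) * img$spacing[axis]
}

#' Volume of a binary mask
#'
#' Counts the 1-voxels and multiplies by the voxel volume.
#'
#' @param mask a \code{voxel_image} with role \code{"mask"}.
#' @return volume in ml.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_image"))
  if (mask$role != "mask") {
    stop("mask_volume() requires a 'mask' role image", call. = FALSE)
  }
  sum(mask$values) * voxel_volume_ml(mask)
}

# shared grid check
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("images are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

# replace the value array, keeping geometry; optionally change role
with_values <- function(img, values, role = img$role) {
  voxel_image(values, img$spacing, img$origin, role)
}
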