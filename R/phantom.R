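#' Digital inter-comparison phantom
#'
#' The physical set-up being emulated is an elliptical Jaszczak-style body
#' phantom (internal axes 305 x 221 mm, height 186 mm) with two low-density
#' lung inserts and a bone-equivalent spine insert, holding a dual-compartment
#' "shell sphere" source: a hot inner sphere (nominal diameter 36 mm)
#' surrounded by a concentric warm outer shell (nominal thickness 11 mm) at an
#' inner:outer concentration ratio of about 15:1. These builders voxelize the
#' geometry into activity, density and attenuation maps plus ground-truth
#' compartment masks.
#'
#' @name phantom
NULL

# nominal shell-sphere geometry (mm), kept for VOI-rule arithmetic
NOMINAL_INNER_DIAMETER_MM <- 36
NOMINAL_SHELL_THICKNESS_MM <- 11

# measured compartment volumes (ml) of the six shipped sources, by site
SHELL_SPHERE_VOLUMES <- data.frame(
  site  = c("H1", "H2", "H3", "H4", "H5", "H6", "H7"),
  inner = c(26.1, 26.0, 26.3, 26.7, 26.7, 26.0, 27.2),
  outer = c(80.8, 81.3, 80.8, 79.3, 79.3, 81.6, 80.7)
)

#' Shell-source specification
#'
#' Defines the dual-compartment concentric source by measured compartment
#' volumes and activity concentrations. Radii are derived from the volumes:
#' \eqn{r_{in} = (3 V_{in} / 4\pi)^{1/3}} and the outer radius solves
#' \eqn{(4\pi/3)(r_{out}^3 - r_{in}^3) = V_{out}}. Compartment walls are
#' modelled as zero-thickness.
#'
#' @param inner_volume ml, hot inner sphere volume (> 0).
#' @param outer_volume ml, warm outer shell volume (> 0).
#' @param inner_concentration MBq/ml in the inner sphere.
#' @param outer_concentration MBq/ml in the outer shell. Default is
#'   \code{inner_concentration / 15} (the nominal hot:warm ratio).
#' @param centre numeric(3), source centre in phantom coordinates (mm).
#' @param site optional site id "H1".."H7"; fills the measured volumes of the
#'   source shipped to that site.
#' @return object of class \code{shell_source_spec} with derived radii
#'   \code{r_inner}, \code{r_outer} (mm) and \code{ratio}.
#' @export
shell_source_spec <- function(inner_volume = 26.1, outer_volume = 80.8,
                              inner_concentration = 2.0,
                              outer_concentration = inner_concentration / 15,
                              centre = c(0, 0, 0), site = NULL) {
  if (!is.null(site)) {
    row <- SHELL_SPHERE_VOLUMES[SHELL_SPHERE_VOLUMES$site == site, ]
    if (nrow(row) != 1L) stop("unknown site id: ", site, call. = FALSE)
    inner_volume <- row$inner
    outer_volume <- row$outer
  }
  if (inner_volume <= 0 || outer_volume <= 0) {
    stop("compartment volumes must be positive", call. = FALSE)
  }
  if (inner_concentration < 0 || outer_concentration < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  r_in <- (3 * inner_volume / (4 * pi))^(1 / 3) * 10   # ml -> mm
  r_out <- (3 * (inner_volume + outer_volume) / (4 * pi))^(1 / 3) * 10
  if (r_out <= r_in) {
    stop("non-physical shell geometry: r_out <= r_in", call. = FALSE)
  }
  ratio <- if (outer_concentration > 0) {
    inner_concentration / outer_concentration
  } else {
    NA_real_
  }
  structure(list(inner_volume = inner_volume, outer_volume = outer_volume,
                 inner_concentration = inner_concentration,
                 outer_concentration = outer_concentration,
                 centre = rep_len(as.numeric(centre), 3L),
                 r_inner = r_in, r_outer = r_out, ratio = ratio),
            class = "shell_source_spec")
}

#' Body-phantom specification
#'
#' Elliptical body with two cylindrical lung inserts and a cylindrical
#' bone-equivalent spine insert. Defaults follow the physical phantom:
#' internal axes 305 x 221 mm, internal height 186 mm, lung filling density
#' about 0.3 g/ml (60:40 Styrofoam:water), spine 38 mm diameter x 152 mm
#' filled with dipotassium-phosphate solution (about 1.33 g/ml).
#'
#' @param major_axis,minor_axis,height internal body dimensions, mm.
#' @param lung_density g/ml.
#' @param lung_volumes ml, c(left, right).
#' @param lung_length mm, axial length of the lung cylinders.
#' @param lung_centres 2x2 matrix of (x, y) centres, mm.
#' @param spine_inner_diameter,spine_length mm.
#' @param spine_centre numeric(2), (x, y) of the spine axis, mm.
#' @param spine_material_density g/ml.
#' @param water_density g/ml.
#' @return object of class \code{body_phantom_spec}.
#' @export
body_phantom_spec <- function(major_axis = 305, minor_axis = 221,
                              height = 186,
                              lung_density = 0.3,
                              lung_volumes = c(900, 1100),
                              lung_length = 152,
                              lung_centres = rbind(c(-80, -30), c(80, -30)),
                              spine_inner_diameter = 38, spine_length = 152,
                              spine_centre = c(0, -70),
                              spine_material_density = 1.33,
                              water_density = 1.0) {
  stopifnot(major_axis > 0, minor_axis > 0, height > 0, lung_density >= 0,
            all(lung_volumes > 0), spine_inner_diameter > 0,
            spine_length > 0)
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 height = height, lung_density = lung_density,
                 lung_volumes = rep_len(lung_volumes, 2L),
                 lung_length = lung_length,
                 lung_centres = lung_centres,
                 spine_inner_diameter = spine_inner_diameter,
                 spine_length = spine_length,
                 spine_centre = rep_len(as.numeric(spine_centre), 2L),
                 spine_material_density = spine_material_density,
                 water_density = water_density),
            class = "body_phantom_spec")
}

# centred cubic/rectangular grid covering a half-extent (mm) per axis
make_grid <- function(half_extent, spacing) {
  half_extent <- rep_len(half_extent, 3L)
  spacing <- rep_len(spacing, 3L)
  n <- pmax(2L, as.integer(ceiling(2 * half_extent / spacing)))
  origin <- -(n - 1) / 2 * spacing
  list(n = n, spacing = spacing, origin = origin)
}

grid_coords <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$n[a]) - 1) * grid$spacing[a]
  })
}

# squared distance of every voxel centre from `centre`, as a 3-D array
dist2_array <- function(grid, centre) {
  co <- grid_coords(grid)
  dx2 <- (co[[1]] - centre[1])^2
  dy2 <- (co[[2]] - centre[2])^2
  dz2 <- (co[[3]] - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Voxelize the shell source as an activity-concentration map
#'
#' Voxel-centre sampling: voxels whose centre lies within the inner radius get
#' the inner concentration, within \code{[r_inner, r_outer)} the outer
#' concentration, else zero. The plastic wall between compartments is treated
#' as zero-thickness.
#'
#' @param spec a \code{shell_source_spec}.
#' @param spacing mm, must be <= 2 mm so the geometry is resolvable.
#' @param margin mm of empty padding around the outer radius.
#' @return a \code{voxel_image} with role \code{"activity"} (MBq/ml).
#' @export
make_shell_source <- function(spec, spacing = 1, margin = 5) {
  stopifnot(inherits(spec, "shell_source_spec"))
  spacing <- rep_len(spacing, 3L)
  if (any(spacing > 2)) {
    stop("make_shell_source() requires spacing <= 2 mm", call. = FALSE)
  }
  grid <- make_grid(spec$r_outer + margin, spacing)
  grid$origin <- grid$origin + spec$centre
  d2 <- dist2_array(grid, spec$centre)
  vals <- array(0, dim = grid$n)
  vals[d2 < spec$r_inner^2] <- spec$inner_concentration
  vals[d2 >= spec$r_inner^2 & d2 < spec$r_outer^2] <- spec$outer_concentration
  voxel_image(vals, grid$spacing, grid$origin, role = "activity")
}

#' Voxelize the full body phantom
#'
#' Builds aligned activity and density maps plus ground-truth compartment
#' masks (\code{inner}, \code{outer}, \code{lungs}, \code{spine},
#' \code{body}) on one grid. Water is 1.0 g/ml, lungs \code{lung_density},
#' spine \code{spine_material_density}, air outside the body 0. Activity is
#' nonzero only inside the shell source.
#'
#' @param spec a \code{body_phantom_spec}.
#' @param source a \code{shell_source_spec}; must fit inside the water
#'   compartment without touching the lung or spine inserts.
#' @param spacing mm (isotropic or per-axis).
#' @param margin mm of air padding beyond the body ellipse.
#' @param fov optional full field of view in mm, scalar or length 3. Forces a
#'   grid of \code{round(fov / spacing)} voxels per axis (e.g.
#'   \code{fov = 307.2, spacing = 4.8} gives the 64-cube used by the
#'   simulator, whose rotating projector needs nx == ny).
#' @return list with elements \code{activity}, \code{density} (both
#'   \code{voxel_image}) and \code{truth_masks} (named list of mask
#'   \code{voxel_image}s).
#' @export
make_body_phantom <- function(spec = body_phantom_spec(),
                              source = shell_source_spec(),
                              spacing = 4.8, margin = 5, fov = NULL) {
  stopifnot(inherits(spec, "body_phantom_spec"))
  if (!is.null(source)) stopifnot(inherits(source, "shell_source_spec"))
  a <- spec$major_axis / 2
  b <- spec$minor_axis / 2
  hz <- spec$height / 2

  if (!is.null(source)) {
    # placement check: source sphere vs inserts / body wall
    check_clear <- function(cxy, r_insert, what) {
      d <- sqrt(sum((source$centre[1:2] - cxy)^2))
      if (d < source$r_outer + r_insert) {
        stop("source placement overlaps the ", what, " insert",
             call. = FALSE)
      }
    }
    for (l in 1:2) {
      r_lung <- sqrt(spec$lung_volumes[l] * 1000 / (pi * spec$lung_length))
      check_clear(spec$lung_centres[l, ], r_lung, "lung")
    }
    check_clear(spec$spine_centre, spec$spine_inner_diameter / 2, "spine")
    e <- sum((source$centre[1:2] / c(a, b))^2)
    if (sqrt(e) + source$r_outer / min(a, b) > 1 ||
        abs(source$centre[3]) + source$r_outer > hz) {
      stop("source does not fit inside the body phantom", call. = FALSE)
    }
  }

  if (is.null(fov)) {
    grid <- make_grid(c(a, b, hz) + margin, spacing)
  } else {
    fov <- rep_len(fov, 3L)
    spacing3 <- rep_len(spacing, 3L)
    n <- pmax(2L, as.integer(round(fov / spacing3)))
    grid <- list(n = n, spacing = spacing3, origin = -(n - 1) / 2 * spacing3)
  }
  co <- grid_coords(grid)

  # body ellipse (prism along z)
  exy <- outer((co[[1]] / a)^2, (co[[2]] / b)^2, "+") <= 1
  inz <- abs(co[[3]]) <= hz
  body <- array(FALSE, dim = grid$n)
  body[, , inz] <- exy

  cyl_mask <- function(cxy, radius, length_mm) {
    inxy <- outer((co[[1]] - cxy[1])^2, (co[[2]] - cxy[2])^2, "+") <= radius^2
    inzc <- abs(co[[3]]) <= length_mm / 2
    m <- array(FALSE, dim = grid$n)
    m[, , inzc] <- inxy
    m & body
  }
  lungs <- array(FALSE, dim = grid$n)
  for (l in 1:2) {
    r_lung <- sqrt(spec$lung_volumes[l] * 1000 / (pi * spec$lung_length))
    lungs <- lungs | cyl_mask(spec$lung_centres[l, ], r_lung, spec$lung_length)
  }
  spine <- cyl_mask(spec$spine_centre, spec$spine_inner_diameter / 2,
                    spec$spine_length)

  if (!is.null(source)) {
    d2 <- dist2_array(grid, source$centre)
    inner <- (d2 < source$r_inner^2) & body
    outer_shell <- (d2 >= source$r_inner^2 & d2 < source$r_outer^2) & body
  } else {
    inner <- array(FALSE, dim = grid$n)
    outer_shell <- array(FALSE, dim = grid$n)
  }

  density <- array(0, dim = grid$n)
  density[body] <- spec$water_density
  density[lungs] <- spec$lung_density
  density[spine] <- spec$spine_material_density

  activity <- array(0, dim = grid$n)
  if (!is.null(source)) {
    activity[inner] <- source$inner_concentration
    activity[outer_shell] <- source$outer_concentration
  }

  as_mask <- function(m) voxel_image(array(as.numeric(m), dim = grid$n),
                                     grid$spacing, grid$origin, role = "mask")
  list(
    activity = voxel_image(activity, grid$spacing, grid$origin, "activity"),
    density = voxel_image(density, grid$spacing, grid$origin, "density"),
    truth_masks = list(inner = as_mask(inner), outer = as_mask(outer_shell),
                       lungs = as_mask(lungs), spine = as_mask(spine),
                       body = as_mask(body)),
    source = source, body_spec = spec
  )
}

# mass attenuation coefficient of water (cm^2/g) at the two main emissions
WATER_MASS_ATT <- c("113" = 0.165, "208" = 0.136)

#' Attenuation map from a density map
#'
#' Linear-in-density model: \eqn{\mu = \rho \kappa(E)} with \eqn{\kappa} the
#' mass attenuation coefficient of water at the photopeak energy. Only the two
#' main Lu-177 gamma emissions (113 and 208 keV) are supported.
#'
#' @param density \code{voxel_image} with role \code{"density"} (g/ml).
#' @param energy photopeak energy in keV, 113 or 208.
#' @param mass_att cm^2/g; default the water value at \code{energy}.
#' @return \code{voxel_image} with role \code{"mu"} (1/cm).
#' @export
mu_map_from_density <- function(density, energy = 208,
                                mass_att = NULL) {
  stopifnot(inherits(density, "voxel_image"))
  if (density$role != "density") {
    stop("mu_map_from_density() expects a 'density' image", call. = FALSE)
  }
  key <- as.character(energy)
  if (!key %in% names(WATER_MASS_ATT)) {
    stop("unsupported photopeak energy: ", energy,
         " (expected 113 or 208 keV)", call. = FALSE)
  }
  if (is.null(mass_att)) mass_att <- WATER_MASS_ATT[[key]]
  with_values(density, density$values * mass_att, role = "mu")
}

#' Total activity of an activity map, in MBq
#' @param activity \code{voxel_image} with role \code{"activity"} (MBq/ml).
#' @return MBq.
#' @export
total_activity <- function(activity) {
  stopifnot(inherits(activity, "voxel_image"))
  if (activity$role != "activity") {
    stop("total_activity() expects an 'activity' image", call. = FALSE)
  }
  sum(activity$values) * voxel_volume_ml(activity)
}
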