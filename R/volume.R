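#' Voxel volume container
#'
#' A 3D scalar grid with physical geometry: `voxel_size` in mm and `origin`,
#' the scanner-coordinate position (mm) of the low corner of voxel (1,1,1).
#' The isocenter is at coordinate (0,0,0). Used for activity maps (Bq/ml) and
#' 511 keV linear attenuation maps (1/mm).
#'
#' @param values 3D numeric array, finite.
#' @param voxel_size Length-3 positive numeric (dx, dy, dz) in mm (a scalar is
#'   recycled).
#' @param origin Length-3 numeric, mm offset of the corner of voxel (1,1,1)
#'   from the isocenter. Default centers the grid on the isocenter.
#' @param quantity `"activity"` or `"mu_511"`; attenuation values must be
#'   non-negative.
#' @return An object of class `tofsss_volume`.
#' @export
voxel_volume <- function(values, voxel_size, origin = NULL,
                         quantity = c("activity", "mu_511")) {
  quantity <- match.arg(quantity)
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  if (quantity == "mu_511" && any(values < 0))
    stop("mu_511 values must be non-negative")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin), quantity = quantity),
            class = "tofsss_volume")
}

#' @export
print.tofsss_volume <- function(x, ...) {
  cat(sprintf("<tofsss_volume> %s, %d x %d x %d voxels of %.3g x %.3g x %.3g mm\n",
              x$quantity, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

## Voxel center coordinates along one axis (1 = x, 2 = y, 3 = z).
voxel_centers <- function(volume, axis) {
  n <- dim(volume$values)[axis]
  volume$origin[axis] + (seq_len(n) - 0.5) * volume$voxel_size[axis]
}

#' NEMA-IEC-like phantom specification
#'
#' Describes a cylindrical body phantom with hot/cold spheres on a transaxial
#' circle and a central low-density lung insert, in the spirit of the NEMA IEC
#' image-quality phantom: warm background, four hot spheres at a fixed
#' activity ratio, the two largest spheres cold, and a lung-equivalent
#' cylinder whose attenuation is the water value scaled by the lung density
#' ratio. All dimensions in mm, activities in Bq/ml.
#'
#' @param body_radius_mm,body_length_mm Background cylinder dimensions.
#' @param sphere_diameters_mm Sphere diameters, largest-last.
#' @param sphere_ring_radius_mm Radius of the circle the sphere centers sit on.
#' @param hot_activity_ratio Hot-sphere to background activity ratio
#'   (default 4, i.e. 1:4 background:hot contrast).
#' @param n_cold Number of largest spheres left without activity (default 2).
#' @param lung_radius_mm Radius of the central lung-equivalent cylinder.
#' @param lung_density_ratio Lung density relative to water (default 0.30);
#'   lung attenuation is `mu_water * lung_density_ratio`.
#' @param background_activity Background activity concentration (Bq/ml).
#' @param mu_water Linear attenuation of water at 511 keV (1/mm).
#' @return A list of class `tofsss_phantom_spec`. The `spheres` element is a
#'   data frame with columns x, y, z, diameter_mm, activity_ratio.
#' @export
nema_phantom_spec <- function(body_radius_mm = 147, body_length_mm = 180,
                              sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                              sphere_ring_radius_mm = 57.2,
                              hot_activity_ratio = 4,
                              n_cold = 2,
                              lung_radius_mm = 25,
                              lung_density_ratio = 0.30,
                              background_activity = 5e6,
                              mu_water = 0.0096) {
  ns <- length(sphere_diameters_mm)
  stopifnot(all(sphere_diameters_mm > 0), n_cold <= ns)
  ang <- 2 * pi * (seq_len(ns) - 1) / ns
  ratio <- rep(hot_activity_ratio, ns)
  if (n_cold > 0) ratio[order(sphere_diameters_mm,
                              decreasing = TRUE)[seq_len(n_cold)]] <- 0
  spheres <- data.frame(x = sphere_ring_radius_mm * cos(ang),
                        y = sphere_ring_radius_mm * sin(ang),
                        z = 0,
                        diameter_mm = sphere_diameters_mm,
                        activity_ratio = ratio)
  if (any(sphere_ring_radius_mm + sphere_diameters_mm / 2 > body_radius_mm))
    stop("spheres must lie inside the phantom body")
  structure(list(body_radius_mm = body_radius_mm,
                 body_length_mm = body_length_mm,
                 spheres = spheres,
                 lung_radius_mm = lung_radius_mm,
                 lung_density_ratio = lung_density_ratio,
                 background_activity = background_activity,
                 mu_water = mu_water),
            class = "tofsss_phantom_spec")
}

## Fractional in-set membership of each voxel for a predicate on (x, y, z)
## voxel-center coordinates, optionally supersampled (s^3 sub-points per
## voxel; s = 1 means plain center membership, deterministic).
membership_fraction <- function(dims, voxel_size, origin, predicate,
                                supersample = 1L) {
  s <- as.integer(supersample)
  acc <- array(0, dims)
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  for (ox in off) for (oy in off) for (oz in off) {
    x <- origin[1] + (seq_len(dims[1]) - 0.5 + ox) * voxel_size[1]
    y <- origin[2] + (seq_len(dims[2]) - 0.5 + oy) * voxel_size[2]
    z <- origin[3] + (seq_len(dims[3]) - 0.5 + oz) * voxel_size[3]
    X <- array(rep(x, times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(z, each = dims[1] * dims[2]), dims)
    acc <- acc + predicate(X, Y, Z)
  }
  acc / s^3
}

#' Generate activity and attenuation maps of the NEMA-like phantom
#'
#' Rasterises a [nema_phantom_spec()] onto a voxel grid centered on the
#' isocenter: warm background cylinder at the background activity and the
#' water attenuation value, hot spheres at `activity_ratio` times background,
#' cold spheres at zero, and the lung insert at zero activity with attenuation
#' scaled by the lung density ratio. Voxels partially covered by a boundary
#' are resolved by voxel-center membership (`supersample = 1`, deterministic);
#' a supersample factor > 1 averages membership over subdivided voxels.
#'
#' @param spec A [nema_phantom_spec()].
#' @param voxel_size Length-3 (or scalar) voxel size in mm.
#' @param grid_shape Length-3 integer grid dimensions; must cover the phantom.
#' @param supersample Integer boundary supersampling factor (default 1).
#' @return List with elements `activity` and `mu`, both [voxel_volume()]s.
#' @export
make_nema_phantom <- function(spec, voxel_size, grid_shape, supersample = 1L) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  grid_shape <- as.integer(grid_shape)
  origin <- -grid_shape * voxel_size / 2
  half_extent <- grid_shape * voxel_size / 2
  if (spec$body_radius_mm > half_extent[1] + 1e-9 ||
      spec$body_radius_mm > half_extent[2] + 1e-9 ||
      spec$body_length_mm / 2 > half_extent[3] + 1e-9)
    stop("grid does not cover the phantom body")
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    if (any(abs(c(s$x, s$y, s$z)) + s$diameter_mm / 2 > half_extent + 1e-9))
      stop("sphere outside grid")
  }

  frac <- function(pred) membership_fraction(grid_shape, voxel_size, origin,
                                             pred, supersample)
  body <- frac(function(x, y, z)
    (x^2 + y^2 <= spec$body_radius_mm^2) &
      (abs(z) <= spec$body_length_mm / 2))
  lung <- frac(function(x, y, z)
    (x^2 + y^2 <= spec$lung_radius_mm^2) &
      (abs(z) <= spec$body_length_mm / 2))

  act <- spec$background_activity * pmax(body - lung, 0)
  mu <- spec$mu_water * pmax(body - lung, 0) +
    spec$mu_water * spec$lung_density_ratio * lung
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    sph <- frac(function(x, y, z)
      ((x - s$x)^2 + (y - s$y)^2 + (z - s$z)^2 <= (s$diameter_mm / 2)^2))
    ## replace background activity by the sphere's inside the sphere
    act <- act * (1 - sph) + spec$background_activity * s$activity_ratio * sph
  }
  list(activity = voxel_volume(act, voxel_size, origin, "activity"),
       mu = voxel_volume(mu, voxel_size, origin, "mu_511"))
}

#' Crop and downsample a map for the scatter estimator
#'
#' Crops the volume axially to `axial_extent_factor` times the scanner's
#' axial field of view, centered on the isocenter, then block-mean
#' downsamples by an isotropic integer factor. If the crop window extends
#' beyond the volume, the missing slabs are zero-padded with a warning.
#' Block-mean downsampling with zero padding conserves the total quantity
#' (value times voxel volume) exactly.
#'
#' @param volume A [voxel_volume()].
#' @param scanner A [build_ring_scanner()] scanner model.
#' @param downsample_factor Integer `>= 1` isotropic block size (default 3).
#' @param axial_extent_factor Axial crop window as a multiple of the scanner
#'   axial FOV (default 1).
#' @return The prepared [voxel_volume()].
#' @export
prepare_maps <- function(volume, scanner, downsample_factor = 3L,
                         axial_extent_factor = 1) {
  f <- as.integer(downsample_factor)
  stopifnot(f >= 1)
  dz <- volume$voxel_size[3]
  half <- axial_extent_factor * scanner$axial_fov_mm / 2
  ## slab index range whose centers fall inside the window; indices may run
  ## past the array, in which case zero slabs are padded
  ilo <- as.integer(ceiling((-half - volume$origin[3]) / dz + 0.5 - 1e-9))
  ihi <- as.integer(floor((half - volume$origin[3]) / dz + 0.5 + 1e-9))
  n <- dim(volume$values)
  vals <- array(0, c(n[1], n[2], ihi - ilo + 1L))
  src <- max(ilo, 1L):min(ihi, n[3])
  if (ilo < 1L || ihi > n[3])
    warning("axial crop window exceeds the volume; zero-padding")
  if (length(src) > 0 && src[1] <= src[length(src)])
    vals[, , src - ilo + 1L] <- volume$values[, , src]
  origin <- volume$origin
  origin[3] <- origin[3] + (ilo - 1L) * dz

  if (f > 1L) {
    d <- dim(vals)
    dpad <- as.integer(ceiling(d / f) * f)
    if (any(dpad != d)) {
      tmp <- array(0, dpad)
      tmp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vals
      vals <- tmp
    }
    dd <- dim(vals) / f
    ## block mean via dimension folding
    vals <- array(vals, c(f, dd[1], f, dd[2], f, dd[3]))
    vals <- apply(vals, c(2, 4, 6), mean)
  }
  voxel_volume(vals, volume$voxel_size * f, origin, volume$quantity)
}
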