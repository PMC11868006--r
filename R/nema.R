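## NEMA NU 2 style image-quality metrics. Circular ROIs are drawn on the
## central sphere slice: per sphere one ROI at the sphere location with
## radius matching the sphere, and twelve background ROIs of the same radius
## at template positions; a lung ROI sits on the phantom axis per slice.
## ROI membership is by voxel center (deterministic); the standard deviation
## over background ROI means uses the sample (n-1) convention.

#' Build the ROI set for a NEMA-like phantom
#'
#' Deterministic ROI template: one ROI per sphere at the sphere center, and
#' twelve background ROI centers placed at angles `(k - 1/2) * 30` degrees
#' (k = 1..12) on a circle of radius `bg_radius_mm`. Placement is validated:
#' every background ROI (at the largest sphere radius) must stay inside the
#' body and clear of all spheres and the lung insert.
#'
#' @param spec A [nema_phantom_spec()].
#' @param bg_radius_mm Radius of the background ROI center circle (default:
#'   midway between the sphere circle and the body edge).
#' @param lung_roi_radius_mm Radius of the lung ROI (default: lung insert
#'   radius scaled by 0.6).
#' @return Object of class `tofsss_roi_set` with `spheres` (data frame:
#'   x, y, z, radius, kind, activity_ratio), `bg_centers`, and `lung`.
#' @export
auto_roi_set <- function(spec,
                         bg_radius_mm = NULL,
                         lung_roi_radius_mm = NULL) {
  sp <- spec$spheres
  rmax <- max(sp$diameter_mm) / 2
  if (is.null(bg_radius_mm)) {
    ring <- sqrt(sp$x[1]^2 + sp$y[1]^2)
    bg_radius_mm <- (ring + spec$body_radius_mm) / 2
  }
  if (is.null(lung_roi_radius_mm))
    lung_roi_radius_mm <- 0.6 * spec$lung_radius_mm
  ang <- (seq_len(12) - 0.5) * pi / 6
  bg <- data.frame(x = bg_radius_mm * cos(ang), y = bg_radius_mm * sin(ang))
  if (bg_radius_mm + rmax > spec$body_radius_mm)
    stop("background ROIs extend beyond the phantom body")
  for (i in seq_len(nrow(sp))) {
    dd <- sqrt((bg$x - sp$x[i])^2 + (bg$y - sp$y[i])^2)
    if (any(dd < rmax + sp$diameter_mm[i] / 2))
      stop("background ROIs overlap a sphere; supply bg_radius_mm")
  }
  if (bg_radius_mm - rmax < spec$lung_radius_mm)
    stop("background ROIs overlap the lung insert; supply bg_radius_mm")
  structure(list(
    spheres = data.frame(x = sp$x, y = sp$y, z = sp$z,
                         radius = sp$diameter_mm / 2,
                         kind = ifelse(sp$activity_ratio > 0, "hot", "cold"),
                         activity_ratio = sp$activity_ratio),
    bg_centers = bg,
    lung = list(x = 0, y = 0, radius = lung_roi_radius_mm)),
    class = "tofsss_roi_set")
}

## Mean image value in a circular ROI on the voxel slice nearest to z.
roi_mean <- function(image, cx, cy, z, radius) {
  iz <- which.min(abs(voxel_centers(image, 3) - z))
  xs <- voxel_centers(image, 1)
  ys <- voxel_centers(image, 2)
  inroi <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= radius^2)
  if (!any(inroi)) stop("ROI contains no voxel centers")
  mean(image$values[, , iz][inroi])
}

## Background ROI means for the ROI radius of sphere j, at slice z.
bg_roi_means <- function(image, roi_set, sphere_j, z = NULL) {
  r <- roi_set$spheres$radius[sphere_j]
  if (is.null(z)) z <- roi_set$spheres$z[sphere_j]
  vapply(seq_len(nrow(roi_set$bg_centers)), function(k)
    roi_mean(image, roi_set$bg_centers$x[k], roi_set$bg_centers$y[k], z, r),
    numeric(1))
}

#' Hot-sphere contrast recovery
#'
#' `Q_H = ((c_H / c_B - 1) / (a_H / a_B - 1)) * 100%`, where `c_H` is the
#' mean in the sphere ROI and `c_B` the mean of the twelve background ROI
#' means at the sphere's radius. 100% for a perfect reconstruction.
#'
#' @param image Reconstructed [voxel_volume()].
#' @param roi_set A [auto_roi_set()].
#' @param sphere_j Sphere row index.
#' @param a_H,a_B True hot-sphere and background activity concentrations
#'   (must differ).
#' @return Contrast recovery in percent.
#' @export
contrast_recovery_hot <- function(image, roi_set, sphere_j, a_H, a_B) {
  if (a_H == a_B) stop("a_H == a_B: contrast recovery undefined")
  s <- roi_set$spheres[sphere_j, ]
  cH <- roi_mean(image, s$x, s$y, s$z, s$radius)
  cB <- mean(bg_roi_means(image, roi_set, sphere_j))
  (cH / cB - 1) / (a_H / a_B - 1) * 100
}

#' Cold-sphere contrast recovery
#'
#' `Q_C = (1 - c_C / c_B) * 100%`; 100% for a perfectly cold sphere.
#'
#' @inheritParams contrast_recovery_hot
#' @return Contrast recovery in percent.
#' @export
contrast_recovery_cold <- function(image, roi_set, sphere_j) {
  s <- roi_set$spheres[sphere_j, ]
  cC <- roi_mean(image, s$x, s$y, s$z, s$radius)
  cB <- mean(bg_roi_means(image, roi_set, sphere_j))
  if (cB <= 0) stop("zero background mean: cold contrast undefined")
  (1 - cC / cB) * 100
}

#' Background variability
#'
#' `N_j = (SD_j / c_B_j) * 100%` with `SD_j` the sample standard deviation
#' (n-1) over the background ROI means at sphere j's radius.
#'
#' @inheritParams contrast_recovery_hot
#' @return Background variability in percent (>= 0).
#' @export
background_variability <- function(image, roi_set, sphere_j) {
  bmeans <- bg_roi_means(image, roi_set, sphere_j)
  if (mean(bmeans) == 0) stop("zero background mean: variability undefined")
  stats::sd(bmeans) / mean(bmeans) * 100
}

#' Lung residual error
#'
#' `Delta_lung_i = (c_lung_i / c_B_largest) * 100%` per slice: the mean in
#' the lung ROI at slice i divided by the mean of the background ROI means
#' at the largest sphere's radius. 0% for perfect attenuation and scatter
#' correction.
#'
#' @inheritParams contrast_recovery_hot
#' @param slice_z Axial position (mm) of the evaluated slice (default 0).
#' @return Residual error in percent.
#' @export
residual_error_lung <- function(image, roi_set, slice_z = 0) {
  jmax <- which.max(roi_set$spheres$radius)
  cB <- mean(bg_roi_means(image, roi_set, jmax))
  if (cB == 0) stop("zero background mean: residual error undefined")
  cl <- roi_mean(image, roi_set$lung$x, roi_set$lung$y, slice_z,
                 roi_set$lung$radius)
  cl / cB * 100
}

#' Full NEMA-style image-quality report
#'
#' Evaluates hot/cold contrast recovery and background variability for every
#' sphere and the lung residual error at the central slice.
#'
#' @inheritParams contrast_recovery_hot
#' @param a_H,a_B True hot and background activity concentrations.
#' @return Object of class `tofsss_iq_report`: data frame `spheres` (columns
#'   sphere, kind, radius_mm, contrast_recovery_pct, background_var_pct) and
#'   scalar `lung_residual_pct`.
#' @export
nema_iq_report <- function(image, roi_set, a_H, a_B) {
  ns <- nrow(roi_set$spheres)
  cr <- bv <- numeric(ns)
  for (j in seq_len(ns)) {
    cr[j] <- if (roi_set$spheres$kind[j] == "hot")
      contrast_recovery_hot(image, roi_set, j, a_H, a_B)
    else contrast_recovery_cold(image, roi_set, j)
    bv[j] <- background_variability(image, roi_set, j)
  }
  structure(list(
    spheres = data.frame(sphere = seq_len(ns),
                         kind = roi_set$spheres$kind,
                         radius_mm = roi_set$spheres$radius,
                         contrast_recovery_pct = cr,
                         background_var_pct = bv),
    lung_residual_pct = residual_error_lung(image, roi_set)),
    class = "tofsss_iq_report")
}

#' @export
print.tofsss_iq_report <- function(x, ...) {
  cat("<tofsss_iq_report>\n")
  print(x$spheres, row.names = FALSE, digits = 4)
  cat(sprintf("  lung residual error: %.2f%%\n", x$lung_residual_pct))
  invisible(x)
}
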