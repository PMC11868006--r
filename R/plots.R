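## Quick-look graphics (ggplot2, if available).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 for plotting")
}

#' Plot one plane of a TOF sinogram
#'
#' Raster of the `[angle, radial]` face of a sinogram for a given plane,
#' either one TOF bin or the TOF-summed counts.
#'
#' @param sinogram A [tof_sinogram()].
#' @param plane Plane (michelogram) index.
#' @param tof_bin TOF bin index, or `NULL` for the TOF sum.
#' @return A ggplot object.
#' @export
plot_sinogram <- function(sinogram, plane = 1, tof_bin = NULL) {
  need_ggplot()
  v <- if (is.null(tof_bin)) apply(sinogram$values[, , plane, , drop = FALSE],
                                   c(1, 2), sum)
  else sinogram$values[, , plane, tof_bin]
  df <- expand.grid(angle = seq_len(nrow(v)), radial = seq_len(ncol(v)))
  df$value <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(.data$radial, .data$angle,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "radial bin", y = "angle bin", fill = sinogram$kind)
}

#' Plot a transaxial slice of a voxel volume
#'
#' @param volume A [voxel_volume()].
#' @param z Axial position of the slice in mm (nearest voxel plane).
#' @return A ggplot object.
#' @export
plot_volume_slice <- function(volume, z = 0) {
  need_ggplot()
  iz <- which.min(abs(voxel_centers(volume, 3) - z))
  df <- expand.grid(x = voxel_centers(volume, 1),
                    y = voxel_centers(volume, 2))
  df$value <- as.vector(volume$values[, , iz])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = volume$quantity)
}

#' Plot an image-quality report
#'
#' Contrast recovery per sphere radius, colored by sphere kind.
#'
#' @param object A [nema_iq_report()].
#' @return A ggplot object.
#' @export
plot_iq_report <- function(object) {
  need_ggplot()
  ggplot2::ggplot(object$spheres,
                  ggplot2::aes(.data$radius_mm, .data$contrast_recovery_pct,
                               colour = .data$kind)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$kind)) +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = "sphere radius (mm)", y = "contrast recovery (%)",
                  colour = NULL)
}
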