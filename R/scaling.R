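## Quantitative scaling of the relative scatter estimate: image-domain tail
## fit. The model-based estimate fixes only the shape of the scatter
## distribution; multiple scatters raise its height without altering the
## shape, so a single global factor is fitted on the tails -- bins whose LOR
## and TOF window miss the object support, where the measured net trues
## contain only scattered events. Both the tails-restricted net trues and
## the tails-restricted scatter estimate are backprojected (unfiltered) onto
## an image grid and compared voxel by voxel with linear least squares.

#' Normalized net trues
#'
#' `(prompts - randoms) * norm`, clamped at zero. The number of clamped
#' (randoms > prompts) canonical bins is recorded in attribute `n_clamped`.
#'
#' @param prompts,randoms Measured [tof_sinogram()]s with matching shape.
#' @param norm Optional multiplicative normalization-factor sinogram
#'   (identity when `NULL`).
#' @return A [tof_sinogram()] of kind `"trues"`.
#' @export
net_trues <- function(prompts, randoms = NULL, norm = NULL) {
  v <- prompts$values
  if (!is.null(randoms)) {
    if (!identical(dim(v), dim(randoms$values))) stop("shape mismatch")
    v <- v - randoms$values
  }
  if (!is.null(norm)) {
    if (!identical(dim(v), dim(norm$values))) stop("shape mismatch")
    v <- v * norm$values
  }
  n_clamped <- sum(v[as.vector(prompts$index$canonical)] < 0)
  v[v < 0] <- 0
  out <- tof_sinogram(v, prompts$index, prompts$tof_bin_edges, "trues")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Build the scatter-tail mask
#'
#' Marks the sinogram bins usable for tail fitting: for each LOR, the
#' object support (`mu > mu_threshold`) is forward-projected with the same
#' TOF segment model as the estimator; bins with non-zero support weight --
#' dilated along the TOF axis by the timing-kernel truncation radius plus
#' `margin_bins` -- are excluded, the rest are masked in. A LOR missing the
#' object entirely contributes all of its TOF bins. The mask guarantees that
#' noiseless true coincidences (simulated with the same model) are exactly
#' zero on masked-in bins.
#'
#' @param mu_map Attenuation [voxel_volume()] covering the FOV.
#' @param scanner Scanner model.
#' @param index A [sinogram_index()].
#' @param mu_threshold Object-contour threshold on mu (1/mm), default 0.002.
#' @param margin_bins Extra TOF bins eroded next to the object (default 1).
#' @param projector Optional precomputed [tof_projector()] on the mu grid.
#' @return Object of class `tofsss_tail_mask`: logical 4D `values` array
#'   (mirror-symmetric), provenance fields, and the canonical-row logical
#'   vector used internally.
#' @export
build_tail_mask <- function(mu_map, scanner, index, mu_threshold = 0.002,
                            margin_bins = 1L, projector = NULL) {
  if (is.null(projector))
    projector <- tof_projector(scanner, index, mu_map)
  support <- voxel_volume((mu_map$values > mu_threshold) * 1,
                          mu_map$voxel_size, mu_map$origin, "activity")
  if (!any(support$values > 0))
    stop("no object support above mu_threshold; tail mask undefined")
  nb <- projector$n_tof_bins
  sp <- as.vector(projector$A0 %*% as.vector(support$values))
  obj <- matrix(sp > 0, ncol = nb, byrow = TRUE)   # [lor, bin]
  reach <- tof_kernel_radius(projector$scanner$specs) + as.integer(margin_bins)
  dil <- obj
  for (k in seq_len(reach)) {
    dil <- dil | cbind(obj[, -seq_len(k), drop = FALSE],
                       matrix(FALSE, nrow(obj), k)) |
      cbind(matrix(FALSE, nrow(obj), k),
            obj[, seq_len(nb - k), drop = FALSE])
  }
  mask_can <- !dil
  if (!any(mask_can)) stop("tail mask is empty: no bins clear of the object")
  dims <- c(index$n_angles, index$n_radial, nrow(index$plane_table), nb)
  v <- matrix(FALSE, prod(dims[1:3]), nb)
  v[projector$lors$bin, ] <- mask_can
  vals <- mirror_fill(array(v * 1, dims), index) > 0
  structure(list(values = vals, mu_threshold = mu_threshold,
                 margin_bins = as.integer(margin_bins),
                 kernel_radius = tof_kernel_radius(projector$scanner$specs),
                 mask_canonical = as.vector(t(mask_can)),
                 n_masked_in = sum(mask_can)),
            class = "tofsss_tail_mask")
}

#' Unfiltered TOF-weighted backprojection
#'
#' Smears each masked-in bin's value along its LOR restricted to the bin's
#' TOF window (Gaussian timing weighting, the transpose of the forward
#' model) and accumulates into the image grid. Linear in the sinogram.
#'
#' @param sinogram A [tof_sinogram()].
#' @param mask A [build_tail_mask()] (or `NULL` to backproject all bins).
#' @param scanner Scanner model.
#' @param index A [sinogram_index()].
#' @param grid A [voxel_volume()] template for the output image.
#' @param projector Optional precomputed [tof_projector()] on `grid`.
#' @return A [voxel_volume()] (quantity `"activity"`).
#' @export
backproject <- function(sinogram, mask, scanner, index, grid,
                        projector = NULL) {
  if (is.null(projector))
    projector <- tof_projector(scanner, index, grid)
  m <- canonical_values(sinogram, projector)
  if (!is.null(mask)) m <- m * mask$mask_canonical
  bp <- as.vector(Matrix::crossprod(projector$A, m))
  voxel_volume(array(bp, dim(grid$values)), grid$voxel_size, grid$origin,
               "activity")
}

#' Fit the global scatter scale factor
#'
#' Voxel-by-voxel linear least squares between the backprojected
#' tails-restricted net trues and the backprojected tails-restricted scatter
#' estimate: `factor = sum(t * s) / sum(s^2)` over voxels with `s > 0`.
#'
#' @param trues_bp,scatter_bp Backprojected [voxel_volume()]s on one grid.
#' @return Object of class `tofsss_scale_fit`: `factor`, `n_voxels_used`,
#'   `residual_norm`.
#' @export
fit_scale <- function(trues_bp, scatter_bp) {
  stopifnot(identical(dim(trues_bp$values), dim(scatter_bp$values)))
  s <- as.vector(scatter_bp$values)
  t_ <- as.vector(trues_bp$values)
  use <- s > 0
  ss <- sum(s[use]^2)
  if (!any(use) || ss == 0)
    stop("scatter backprojection is zero everywhere; cannot fit scale")
  k <- sum(t_[use] * s[use]) / ss
  structure(list(factor = k, n_voxels_used = sum(use),
                 residual_norm = sqrt(sum((t_[use] - k * s[use])^2))),
            class = "tofsss_scale_fit")
}

#' @export
print.tofsss_scale_fit <- function(x, ...) {
  cat(sprintf("<tofsss_scale_fit> factor %.6g over %d voxels (residual %.3g)\n",
              x$factor, x$n_voxels_used, x$residual_norm))
  invisible(x)
}

#' Apply a fitted scale factor to a scatter sinogram
#'
#' @param scatter A [tof_sinogram()] of kind `"scatter"`.
#' @param fit A [fit_scale()] result (or a bare positive number).
#' @return The scaled scatter [tof_sinogram()].
#' @export
scale_scatter <- function(scatter, fit) {
  k <- if (inherits(fit, "tofsss_scale_fit")) fit$factor else fit
  stopifnot(is.finite(k), k > 0)
  scatter$values <- scatter$values * k
  scatter
}
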