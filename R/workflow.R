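#' Estimator parameter set
#'
#' Parameters of the full scatter-estimation pipeline with defaults matching
#' a clinical configuration: maps downsampled by an isotropic factor of 3
#' and cropped to the scanner axial FOV, scatter points every (3, 3, 2)
#' voxels within 1.5x the axial FOV, 1/4 of the detectors and 6 rings
#' sampled, 13 TOF bins (from the scanner specs), and the image-domain tail
#' fit with mu threshold 0.002/mm and a 1-bin tail margin.
#'
#' @param downsample_factor Isotropic map downsampling factor.
#' @param point_strides Scatter-point voxel strides (x, y, z).
#' @param detector_fraction Fraction of crystals sampled per ring.
#' @param n_sampled_rings Number of sampled rings.
#' @param axial_extent_factor Scatter-point axial clip (times half FOV per
#'   side).
#' @param mu_threshold Tail-mask object contour threshold (1/mm).
#' @param margin_bins Extra TOF bins eroded next to the object.
#' @param n_outer_iterations Scatter re-estimations in the workflow loop.
#' @return Named list of parameters.
#' @export
sss_params <- function(downsample_factor = 3, point_strides = c(3, 3, 2),
                       detector_fraction = 1 / 4, n_sampled_rings = 6,
                       axial_extent_factor = 1.5, mu_threshold = 0.002,
                       margin_bins = 1L, n_outer_iterations = 2L) {
  list(downsample_factor = downsample_factor, point_strides = point_strides,
       detector_fraction = detector_fraction,
       n_sampled_rings = n_sampled_rings,
       axial_extent_factor = axial_extent_factor,
       mu_threshold = mu_threshold, margin_bins = as.integer(margin_bins),
       n_outer_iterations = as.integer(n_outer_iterations))
}

#' Run one complete scatter estimation
#'
#' The full pipeline on in-memory inputs: prepare the maps (axial crop +
#' downsample), sample scatter points, estimate the sampled scatter grid,
#' interpolate to the full TOF sinogram, build the tail mask, backproject
#' the tails-restricted normalized net trues and scatter estimate, fit the
#' global scale, and return the scaled scatter sinogram. Deterministic:
#' identical inputs give bit-identical outputs.
#'
#' @param prompts,randoms,norm Measured [tof_sinogram()]s (`randoms`/`norm`
#'   may be `NULL`).
#' @param activity Current activity estimate [voxel_volume()].
#' @param mu Attenuation map [voxel_volume()].
#' @param scanner Scanner model.
#' @param index A [sinogram_index()].
#' @param params A [sss_params()] list.
#' @param projector Optional precomputed [tof_projector()] on the prepared
#'   mu grid (rebuilt otherwise).
#' @param prepare Run [prepare_maps()] on the inputs (default); set `FALSE`
#'   when the maps are already on the prepared grid.
#' @return List: `scatter` (scaled [tof_sinogram()]), `fit`
#'   ([fit_scale()]), `mask`, `trues`, prepared maps, and a provenance
#'   `manifest` recording every parameter.
#' @export
run_scatter_estimation <- function(prompts, randoms = NULL, norm = NULL,
                                   activity, mu, scanner,
                                   index = sinogram_index(scanner),
                                   params = sss_params(),
                                   projector = NULL, prepare = TRUE) {
  if (prepare) {
    act_p <- prepare_maps(activity, scanner, params$downsample_factor,
                          params$axial_extent_factor)
    mu_p <- prepare_maps(mu, scanner, params$downsample_factor,
                         params$axial_extent_factor)
  } else {
    act_p <- activity
    mu_p <- mu
  }
  pts <- sample_scatter_points(mu_p, scanner, params$point_strides,
                               params$axial_extent_factor)
  plan <- make_sampling_plan(scanner, params$detector_fraction,
                             params$n_sampled_rings)
  sample <- estimate_sampled_scatter(scanner, plan, act_p, mu_p, pts)
  scatter_rel <- interpolate_full(sample, scanner, index)

  if (is.null(projector))
    projector <- tof_projector(scanner, index, mu_p)
  trues <- net_trues(prompts, randoms, norm)
  mask <- build_tail_mask(mu_p, scanner, index, params$mu_threshold,
                          params$margin_bins, projector = projector)
  trues_bp <- backproject(trues, mask, scanner, index, mu_p, projector)
  scatter_bp <- backproject(scatter_rel, mask, scanner, index, mu_p,
                            projector)
  fit <- fit_scale(trues_bp, scatter_bp)
  scatter <- scale_scatter(scatter_rel, fit)
  manifest <- list(
    package = "tofsss", version = "0.1.0",
    params = params,
    scanner = list(crystals_per_ring = scanner$crystals_per_ring,
                   n_rings = scanner$n_rings,
                   ring_radius_mm = scanner$ring_radius_mm,
                   specs = scanner$specs),
    n_scatter_points = nrow(pts$positions),
    sampled_grid = as.list(plan$grid_shape),
    n_tail_bins = mask$n_masked_in,
    scale_factor = fit$factor)
  list(scatter = scatter, fit = fit, mask = mask, trues = trues,
       activity_prepared = act_p, mu_prepared = mu_p, manifest = manifest)
}

#' Iterative reconstruction loop with scatter correction
#'
#' The estimate-and-reconstruct loop: iteration 0 reconstructs without
#' scatter correction; each outer iteration then estimates and scales a new
#' scatter sinogram from the current activity image and reconstructs again
#' with the additive scatter term.
#'
#' @inheritParams run_scatter_estimation
#' @param reconstructor Function `(prompts, scatter_or_NULL) -> voxel_volume`;
#'   defaults to the built-in [mlem_reconstruct()] on the prepared mu grid.
#' @param n_iter,n_subsets Settings of the default reconstructor.
#' @return List: `images` (one [voxel_volume()] per outer iteration,
#'   uncorrected first), `scatters` (one scaled sinogram per estimation),
#'   `fits`, and a `manifest` listing one scatter entry per outer iteration.
#' @export
run_workflow_loop <- function(prompts, randoms = NULL, norm = NULL, mu,
                              scanner, index = sinogram_index(scanner),
                              params = sss_params(),
                              reconstructor = NULL,
                              n_iter = 3, n_subsets = 4) {
  mu_p <- prepare_maps(mu, scanner, params$downsample_factor, 1.5)
  projector <- tof_projector(scanner, index, mu_p)
  if (is.null(reconstructor)) {
    reconstructor <- function(prompts, scatter) {
      mlem_reconstruct(prompts, scatter, mu_p, scanner, index, grid = mu_p,
                       n_iter = n_iter, n_subsets = n_subsets,
                       projector = projector)
    }
  }
  images <- list(reconstructor(prompts, NULL))
  scatters <- list()
  fits <- list()
  for (i in seq_len(params$n_outer_iterations)) {
    ## the current image lives on the prepared grid already; skip re-prepare
    est <- tryCatch(
      run_scatter_estimation(prompts, randoms, norm,
                             activity = images[[length(images)]],
                             mu = mu_p, scanner = scanner, index = index,
                             params = params, projector = projector,
                             prepare = FALSE),
      error = function(e) stop("scatter estimation failed at outer iteration ",
                               i, ": ", conditionMessage(e)))
    scatters[[i]] <- est$scatter
    fits[[i]] <- est$fit
    images[[i + 1L]] <- tryCatch(
      reconstructor(prompts, est$scatter),
      error = function(e) stop("reconstruction failed at outer iteration ",
                               i, ": ", conditionMessage(e)))
  }
  list(images = images, scatters = scatters, fits = fits,
       manifest = list(n_outer_iterations = params$n_outer_iterations,
                       scatter_estimates = lapply(fits, function(f)
                         list(scale_factor = f$factor,
                              n_voxels_used = f$n_voxels_used))))
}
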