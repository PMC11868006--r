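## Desk-scale synthetic TOF-PET data: attenuated TOF forward projection of
## trues, single-scatter injection from the package's own estimator run at
## dense settings, Poisson noise, and a minimal TOF-OSEM reconstructor.
## Because the simulated scatter ground truth comes from the same physics
## model (at dense sampling), scale-recovery and workflow properties can be
## verified exactly; Monte-Carlo-level realism is out of scope.

#' Attenuated TOF forward projection of true coincidences
#'
#' Per canonical LOR: `exp(-integral of mu) *` per-TOF-bin activity line
#' integrals, with the same TOF segment model and Gaussian timing smearing
#' as the scatter estimator. Deterministic.
#'
#' @param activity,mu [voxel_volume()]s on a common grid.
#' @param scanner Scanner model.
#' @param index A [sinogram_index()].
#' @param projector Optional precomputed [tof_projector()] on the activity
#'   grid.
#' @return A [tof_sinogram()] of kind `"trues"`.
#' @export
forward_trues <- function(activity, mu, scanner, index, projector = NULL) {
  if (is.null(projector))
    projector <- tof_projector(scanner, index, activity)
  nb <- projector$n_tof_bins
  att <- lor_attenuation(scanner, projector$lors, mu)
  q <- as.vector(projector$A %*% as.vector(activity$values)) *
    rep(att, each = nb)
  sinogram_from_canonical(q, projector, "trues")
}

#' Simulate a synthetic TOF-PET dataset
#'
#' Builds a complete dataset on a toy scanner: noiseless trues by attenuated
#' TOF forward projection, a single-scatter shape from
#' [estimate_sampled_scatter()] at dense settings interpolated to the full
#' sinogram, both scaled so the total prompts and the scatter fraction hit
#' their targets, then optional Poisson noise (drawn on canonical bins and
#' mirrored, one draw per physical LOR bin). Randoms default to zero; a
#' uniform randoms level can be added to exercise [net_trues()].
#'
#' @param scanner Scanner model.
#' @param activity,mu Phantom maps (used for both simulation and the scatter
#'   shape).
#' @param n_counts Target total prompt counts over canonical bins.
#' @param scatter_fraction Target scatter / (trues + scatter) fraction.
#' @param seed Integer seed governing all stochastic draws.
#' @param noise Draw Poisson noise (default TRUE).
#' @param randoms_level Uniform randoms counts per canonical bin (default 0).
#' @param scatter_strides Scatter-point strides of the dense estimation run.
#' @param index,projector Optional precomputed index/projector.
#' @return List: `prompts`, `randoms`, `norm`, and `truth` (a list with
#'   `trues`, `scatter_shape` (unscaled), `scatter` (scaled),
#'   `true_scale` -- the factor on `scatter_shape` -- plus the maps and the
#'   realized scatter fraction).
#' @export
simulate_dataset <- function(scanner, activity, mu, n_counts = 1e6,
                             scatter_fraction = 0.3, seed = 1,
                             noise = TRUE, randoms_level = 0,
                             scatter_strides = c(1, 1, 1),
                             index = sinogram_index(scanner),
                             projector = NULL) {
  stopifnot(n_counts > 0, scatter_fraction >= 0, scatter_fraction < 1)
  if (is.null(projector))
    projector <- tof_projector(scanner, index, activity)
  trues <- forward_trues(activity, mu, scanner, index, projector)
  tt <- sinogram_total(trues)
  if (tt <= 0) stop("activity map produces no true coincidences")
  trues$values <- trues$values * (n_counts * (1 - scatter_fraction) / tt)

  plan <- make_sampling_plan(scanner, 1, scanner$n_rings)
  pts <- sample_scatter_points(mu, scanner, strides = scatter_strides,
                               axial_extent_factor = 1.5)
  shape <- interpolate_full(estimate_sampled_scatter(scanner, plan, activity,
                                                     mu, pts),
                            scanner, index)
  st <- sinogram_total(shape)
  if (st <= 0) stop("scatter shape is zero everywhere; unreachable fraction")
  true_scale <- n_counts * scatter_fraction / st
  scatter <- shape
  scatter$values <- shape$values * true_scale

  prompts_v <- trues$values + scatter$values
  randoms_v <- array(randoms_level, dim(prompts_v))
  prompts_v <- prompts_v + randoms_v
  if (noise) {
    set.seed(as.integer(seed))
    nb <- dim(prompts_v)[4]
    canon <- as.vector(index$canonical)
    pv <- matrix(prompts_v, ncol = nb)
    pv[canon, ] <- matrix(stats::rpois(sum(canon) * nb, pv[canon, ]),
                          ncol = nb)
    prompts_v <- mirror_fill(array(pv, dim(prompts_v)), index)
  }
  prompts <- tof_sinogram(prompts_v, index, trues$tof_bin_edges, "prompts")
  randoms <- tof_sinogram(randoms_v, index, trues$tof_bin_edges, "randoms")
  norm <- tof_sinogram(array(1, dim(prompts_v)), index, trues$tof_bin_edges,
                       "norm")
  list(prompts = prompts, randoms = randoms, norm = norm,
       truth = list(trues = trues, scatter_shape = shape, scatter = scatter,
                    true_scale = true_scale, activity = activity, mu = mu,
                    scatter_fraction = sinogram_total(scatter) /
                      (sinogram_total(scatter) + sinogram_total(trues))))
}

#' TOF-MLEM/OSEM reconstruction with an additive scatter term
#'
#' Ordered-subset EM with the scatter estimate added in the forward
#' projection: expected counts `q = att * (A x) + s`. The multiplicative
#' update preserves non-negativity; voxels with zero sensitivity are
#' excluded. Subsets partition the canonical LORs by angle index.
#'
#' @param prompts Measured [tof_sinogram()].
#' @param scatter_correction Scatter [tof_sinogram()] on the same grid, or
#'   `NULL` for no correction.
#' @param mu Attenuation map.
#' @param scanner Scanner model.
#' @param index A [sinogram_index()].
#' @param grid Image grid template [voxel_volume()] (defaults to `mu`).
#' @param n_iter,n_subsets Iterations and ordered subsets (updates =
#'   `n_iter * n_subsets`). `n_subsets` is capped at the angle count.
#' @param projector Optional precomputed [tof_projector()] on `grid`.
#' @return Reconstructed activity [voxel_volume()].
#' @export
mlem_reconstruct <- function(prompts, scatter_correction, mu, scanner, index,
                             grid = mu, n_iter = 3, n_subsets = 4,
                             projector = NULL) {
  if (is.null(projector))
    projector <- tof_projector(scanner, index, grid)
  nb <- projector$n_tof_bins
  nl <- nrow(projector$lors)
  att_bin <- rep(lor_attenuation(scanner, projector$lors, mu), each = nb)
  m <- canonical_values(prompts, projector)
  s <- if (is.null(scatter_correction)) numeric(nl * nb) else
    canonical_values(scatter_correction, projector)

  n_subsets <- max(1L, min(as.integer(n_subsets), index$n_angles))
  sub_of_lor <- (projector$lors$angle_idx - 1L) %% n_subsets
  rows_of <- lapply(0:(n_subsets - 1L), function(k) {
    lr <- which(sub_of_lor == k)
    as.vector(outer(seq_len(nb), (lr - 1L) * nb, "+"))
  })
  Asub <- lapply(rows_of, function(r) projector$A[r, , drop = FALSE])
  sens <- lapply(seq_len(n_subsets), function(k)
    as.vector(Matrix::crossprod(Asub[[k]], att_bin[rows_of[[k]]])))

  x <- rep(1, ncol(projector$A))
  alive <- Reduce(`+`, sens) > 0
  x[!alive] <- 0
  for (it in seq_len(n_iter)) {
    for (k in seq_len(n_subsets)) {
      r <- rows_of[[k]]
      q <- att_bin[r] * as.vector(Asub[[k]] %*% x) + s[r]
      ratio <- ifelse(q > 0, m[r] / q, 0)
      upd <- as.vector(Matrix::crossprod(Asub[[k]], att_bin[r] * ratio))
      ok <- alive & sens[[k]] > 0
      x[ok] <- x[ok] * upd[ok] / sens[[k]][ok]
    }
  }
  voxel_volume(array(x, dim(grid$values)), grid$voxel_size, grid$origin,
               "activity")
}
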