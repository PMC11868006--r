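# Synthetic TOF-PET data: forward projection of trues, dataset assembly,
# and the MLEM/OSEM reconstructor.

test_that("forward trues: zero activity, point source geometry, conservation", {
  sc <- toy_scanner(16, 2, radius = 60, pitch = 16, n_tof_bins = 5,
                    tof_range = 2000, tof_res = 150)
  idx <- sinogram_index(sc)
  n <- 15; voxel <- 6
  zero <- voxel_volume(array(0, rep(n, 3)), voxel)
  nomu <- voxel_volume(array(0, rep(n, 3)), voxel, quantity = "mu_511")
  proj <- tof_projector(sc, idx, zero)
  t0 <- forward_trues(zero, nomu, sc, idx, proj)
  expect_true(all(t0$values == 0))
  ## point-like source at the isocenter, no attenuation: counts appear only
  ## in the central TOF bin of LORs whose tube passes the center
  pt <- zero
  pt$values[8, 8, 8] <- 100   # voxel centered on the isocenter
  tp <- forward_trues(pt, nomu, sc, idx, proj)
  nz <- which(tp$values > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  ## central TOF bins only: bin 3 of 5 plus the timing-kernel spread
  kr <- tofsss:::tof_kernel_radius(sc$specs)
  expect_true(all(abs(nz[, 4] - 3) <= kr))
  ## and the central bin holds most of the mass
  expect_gt(sum(tp$values[, , , 3]), 0.6 * sum(tp$values))
  ## every hit LOR passes within a voxel diagonal of the center
  for (i in seq_len(nrow(nz))) {
    pair <- crystal_pair_of_bin(sc, idx, nz[i, 1], nz[i, 2], nz[i, 3])
    pA <- sc$crystal_xyz[pair$idA, ]; pB <- sc$crystal_xyz[pair$idB, ]
    u <- (pB - pA) / sqrt(sum((pB - pA)^2))
    perp <- -pA - sum(-pA * u) * u
    expect_lt(sqrt(sum(perp^2)), sqrt(3) * voxel)
  }
  ## TOF-summed equals the non-TOF forward projection (wide range)
  m <- toy_maps(n = 15, voxel = 6, act_kind = "blob")
  tr <- forward_trues(m$activity, m$mu, sc, idx, proj)
  tof_sum <- apply(tr$values, 1:3, sum)
  lors <- tofsss:::canonical_lors(sc, idx)
  att <- tofsss:::lor_attenuation(sc, lors, m$mu)
  for (r in sample(nrow(lors), 25)) {
    direct <- att[r] * line_integral(m$activity,
                                     sc$crystal_xyz[lors$idA[r], ],
                                     sc$crystal_xyz[lors$idB[r], ])
    expect_equal(tof_sum[lors$angle_idx[r], lors$radial_idx[r],
                         lors$plane[r]],
                 direct, tolerance = 1e-6)
  }
})

test_that("simulated datasets are reproducible with exact bookkeeping", {
  sc <- toy_scanner(16, 2, radius = 60, pitch = 16, n_tof_bins = 5,
                    tof_range = 900, tof_res = 200)
  idx <- sinogram_index(sc)
  m <- toy_maps(n = 12, voxel = 6, body_radius = 30, body_halflen = 34,
                act_kind = "blob")
  proj <- tof_projector(sc, idx, m$activity)
  ## noiseless: prompts are exactly trues + scaled scatter, fraction exact
  s0 <- simulate_dataset(sc, m$activity, m$mu, n_counts = 1e5,
                         scatter_fraction = 0.25, noise = FALSE,
                         scatter_strides = c(2, 2, 2), index = idx,
                         projector = proj)
  expect_equal(s0$prompts$values,
               s0$truth$trues$values + s0$truth$scatter$values)
  expect_equal(s0$truth$scatter_fraction, 0.25, tolerance = 1e-12)
  expect_equal(tofsss:::sinogram_total(s0$prompts), 1e5, tolerance = 1e-9)
  ## fixed seed: bit-identical reruns
  s1 <- simulate_dataset(sc, m$activity, m$mu, n_counts = 1e5,
                         scatter_fraction = 0.25, seed = 7, noise = TRUE,
                         scatter_strides = c(2, 2, 2), index = idx,
                         projector = proj)
  s2 <- simulate_dataset(sc, m$activity, m$mu, n_counts = 1e5,
                         scatter_fraction = 0.25, seed = 7, noise = TRUE,
                         scatter_strides = c(2, 2, 2), index = idx,
                         projector = proj)
  expect_identical(s1$prompts$values, s2$prompts$values)
  ## noise is drawn once per physical bin: mirror symmetry survives
  v <- s1$prompts$values
  expect_equal(v, tofsss:::mirror_fill(v, idx))
})

test_that("MLEM reconstructs a uniform cylinder and stays non-negative", {
  sc <- toy_scanner(16, 2, radius = 60, pitch = 16, n_tof_bins = 5,
                    tof_range = 900, tof_res = 200)
  idx <- sinogram_index(sc)
  m <- toy_maps(n = 12, voxel = 6, body_radius = 26, body_halflen = 30,
                act_kind = "cylinder")
  proj <- tof_projector(sc, idx, m$activity)
  trues <- forward_trues(m$activity, m$mu, sc, idx, proj)
  prompts <- tof_sinogram(trues$values, idx, trues$tof_bin_edges, "prompts")
  rec <- mlem_reconstruct(prompts, NULL, m$mu, sc, idx, grid = m$activity,
                          n_iter = 13, n_subsets = 4, projector = proj)
  expect_true(all(rec$values >= 0))
  ## mean inside the cylinder core, well within the transaxial and axial
  ## FOV (the cylinder extends past the 32 mm axial FOV, where the scanner
  ## has no sensitivity), within 5% of truth after ~50 updates
  core <- which(m$activity$values == 1000, arr.ind = TRUE)
  xs <- voxel_centers(m$activity, 1)
  keep <- xs[core[, 1]]^2 + xs[core[, 2]]^2 < 20^2 &
    abs(xs[core[, 3]]) < 12
  expect_equal(mean(rec$values[core[keep, , drop = FALSE]]), 1000,
               tolerance = 0.05)
  ## Poisson log-likelihood increases over iterations (smoke)
  loglik <- function(img) {
    q <- as.vector(proj$A %*% as.vector(img$values)) *
      rep(tofsss:::lor_attenuation(sc, proj$lors, m$mu),
          each = proj$n_tof_bins)
    mm <- tofsss:::canonical_values(prompts, proj)
    sum(mm[q > 0] * log(q[q > 0]) - q[q > 0])
  }
  rec1 <- mlem_reconstruct(prompts, NULL, m$mu, sc, idx, grid = m$activity,
                           n_iter = 1, n_subsets = 1, projector = proj)
  rec5 <- mlem_reconstruct(prompts, NULL, m$mu, sc, idx, grid = m$activity,
                           n_iter = 5, n_subsets = 1, projector = proj)
  expect_gt(loglik(rec5), loglik(rec1))
})

test_that("additive scatter term is honoured by the forward model", {
  ## with the true scatter supplied, reconstruction of noiseless prompts
  ## with scatter converges to the same image as trues-only reconstruction
  sc <- toy_scanner(16, 2, radius = 60, pitch = 16, n_tof_bins = 5,
                    tof_range = 900, tof_res = 200)
  idx <- sinogram_index(sc)
  m <- toy_maps(n = 12, voxel = 6, body_radius = 26, body_halflen = 30,
                act_kind = "blob")
  proj <- tof_projector(sc, idx, m$activity)
  sim <- simulate_dataset(sc, m$activity, m$mu, n_counts = 1e6,
                          scatter_fraction = 0.35, noise = FALSE,
                          scatter_strides = c(2, 2, 2), index = idx,
                          projector = proj)
  rec_corr <- mlem_reconstruct(sim$prompts, sim$truth$scatter, m$mu, sc, idx,
                               grid = m$activity, n_iter = 30, n_subsets = 1,
                               projector = proj)
  trues_only <- tof_sinogram(sim$truth$trues$values, idx,
                             sim$prompts$tof_bin_edges, "prompts")
  rec_clean <- mlem_reconstruct(trues_only, NULL, m$mu, sc, idx,
                                grid = m$activity, n_iter = 30, n_subsets = 1,
                                projector = proj)
  ## compare where the scanner has sensitivity (inside the axial FOV);
  ## voxel-wise agreement in normalized mean absolute difference
  zc <- voxel_centers(m$mu, 3)
  inside <- m$mu$values > 0 &
    abs(array(rep(zc, each = 144), dim(m$mu$values))) < 12
  nmad <- mean(abs(rec_corr$values[inside] - rec_clean$values[inside])) /
    mean(rec_clean$values[inside])
  expect_lt(nmad, 0.03)
})
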