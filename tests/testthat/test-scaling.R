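# Image-domain tail-fit scaling: net trues, tail mask, backprojection,
# least-squares scale factor, and end-to-end scale recovery.

scale_fixture <- function(n_counts = 2e6, scatter_fraction = 0.3,
                          noise = FALSE, seed = 1) {
  sc <- toy_scanner(16, 2, radius = 60, pitch = 16, n_tof_bins = 5,
                    tof_range = 900, tof_res = 200)
  idx <- sinogram_index(sc)
  m <- toy_maps(n = 16, voxel = 5, body_radius = 32, body_halflen = 36,
                act_kind = "blob", blob_sigma = 25)
  proj <- tof_projector(sc, idx, m$mu)
  sim <- simulate_dataset(sc, m$activity, m$mu, n_counts = n_counts,
                          scatter_fraction = scatter_fraction, seed = seed,
                          noise = noise, scatter_strides = c(2, 2, 2),
                          index = idx, projector = proj)
  list(sc = sc, idx = idx, m = m, proj = proj, sim = sim)
}

test_that("net trues subtracts randoms, normalizes, and clamps", {
  f <- scale_fixture(noise = FALSE)
  prompts <- f$sim$prompts
  ## identity when randoms = 0, norm = 1
  nt <- net_trues(prompts, f$sim$randoms, f$sim$norm)
  expect_equal(nt$values, prompts$values)
  expect_equal(nt$kind, "trues")
  ## prompts == randoms -> zero
  nt0 <- net_trues(prompts, prompts)
  expect_true(all(nt0$values == 0))
  ## clamp counts bins where randoms exceed prompts
  r <- prompts
  r$values <- prompts$values + 1
  ntc <- net_trues(prompts, r)
  expect_true(all(ntc$values == 0))
  expect_gt(attr(ntc, "n_clamped"), 0)
  ## shape mismatch errors
  small <- tof_sinogram(prompts$values[, , , 1, drop = FALSE] * 0, f$idx,
                        prompts$tof_bin_edges[1:2], "randoms")
  expect_error(net_trues(prompts, small), "mismatch")
})

test_that("tail mask excludes the object and every bin the trues can reach", {
  f <- scale_fixture()
  mask <- build_tail_mask(f$m$mu, f$sc, f$idx, mu_threshold = 0.002,
                          margin_bins = 1, projector = f$proj)
  expect_gt(mask$n_masked_in, 0)
  ## noiseless simulated trues vanish exactly on masked-in bins
  expect_true(all(f$sim$truth$trues$values[mask$values] == 0))
  ## a LOR that misses the phantom entirely keeps all its TOF bins:
  ## radial offset 1 passes at |r| = 60 cos(pi/16) = 58.8 mm > body radius
  expect_true(all(mask$values[1, 1, 1, ]))
  ## scatter estimate is positive on enough tail bins to fit
  expect_gt(sum(f$sim$truth$scatter$values[mask$values] > 0), 50)
  ## no support above threshold -> error
  zero <- voxel_volume(array(0, dim(f$m$mu$values)), f$m$mu$voxel_size,
                       f$m$mu$origin, "mu_511")
  expect_error(build_tail_mask(zero, f$sc, f$idx, projector = f$proj),
               "support")
})

test_that("backprojection is linear and confined to the LOR TOF window", {
  f <- scale_fixture()
  dims <- dim(f$sim$prompts$values)
  zero <- tof_sinogram(array(0, dims), f$idx, f$sim$prompts$tof_bin_edges,
                       "scatter")
  bp0 <- backproject(zero, NULL, f$sc, f$idx, f$m$mu, f$proj)
  expect_true(all(bp0$values == 0))
  ## linearity
  a <- zero; a$values[5, 8, 1, 3] <- 2
  b <- zero; b$values[3, 6, 2, 2] <- 1.5
  ab <- zero; ab$values <- a$values + b$values
  bpa <- backproject(a, NULL, f$sc, f$idx, f$m$mu, f$proj)
  bpb <- backproject(b, NULL, f$sc, f$idx, f$m$mu, f$proj)
  bpab <- backproject(ab, NULL, f$sc, f$idx, f$m$mu, f$proj)
  expect_equal(bpab$values, bpa$values + bpb$values, tolerance = 1e-10)
  ## geometric containment: a single bin backprojects only into voxels
  ## within its LOR's TOF window (+- 4 sigma of the timing kernel)
  lor <- f$proj$lors[f$proj$lors$angle_idx == 5 & f$proj$lors$radial_idx == 8 &
                       f$proj$lors$plane == 1, ]
  pA <- f$sc$crystal_xyz[lor$idA, ]; pB <- f$sc$crystal_xyz[lor$idB, ]
  hit <- which(bpa$values > 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  u <- (pB - pA) / sqrt(sum((pB - pA)^2))
  edges <- f$sim$prompts$tof_bin_edges
  sigma_l <- f$sc$specs$tof_resolution_ps / 2.3548 * 0.299792458 / 2
  L <- sqrt(sum((pB - pA)^2))
  for (i in seq_len(nrow(hit))) {
    p <- c(voxel_centers(f$m$mu, 1)[hit[i, 1]],
           voxel_centers(f$m$mu, 2)[hit[i, 2]],
           voxel_centers(f$m$mu, 3)[hit[i, 3]])
    ## perpendicular distance to the LOR is at most half a voxel diagonal
    w <- p - pA
    perp <- sqrt(sum((w - sum(w * u) * u)^2))
    expect_lt(perp, sqrt(sum(f$m$mu$voxel_size^2)) / 2 + 1e-9)
    ## arc position within the TOF-bin 3 window +- 4 sigma + voxel diagonal
    l <- sum(w * u)
    lwin <- (L + 0.299792458 * edges[3:4]) / 2
    expect_gt(l, lwin[1] - 4 * sigma_l - sqrt(sum(f$m$mu$voxel_size^2)))
    expect_lt(l, lwin[2] + 4 * sigma_l + sqrt(sum(f$m$mu$voxel_size^2)))
  }
})

test_that("fit_scale is the closed-form least squares and scale-equivariant", {
  g <- voxel_volume(array(stats::runif(27, 0, 2), c(3, 3, 3)), 10)
  t2 <- voxel_volume(2 * g$values, 10)
  expect_equal(fit_scale(t2, g)$factor, 2)
  ## with noise: equals direct-summation closed form
  set.seed(9)
  tn <- voxel_volume(2 * g$values + stats::rnorm(27, 0, 0.1), 10)
  fit <- fit_scale(tn, g)
  use <- g$values > 0
  expect_equal(fit$factor,
               sum(tn$values[use] * g$values[use]) / sum(g$values[use]^2),
               tolerance = 1e-12)
  expect_equal(fit$n_voxels_used, sum(use))
  ## scale equivariance: scaling the scatter by c scales the factor by 1/c
  gc <- voxel_volume(4 * g$values, 10)
  expect_equal(fit_scale(tn, gc)$factor, fit$factor / 4, tolerance = 1e-12)
  ## all-zero scatter errors
  z <- voxel_volume(array(0, c(3, 3, 3)), 10)
  expect_error(fit_scale(tn, z), "zero")
})

test_that("scale_scatter multiplies every bin and conserves shape", {
  f <- scale_fixture()
  s <- f$sim$truth$scatter_shape
  s1 <- scale_scatter(s, structure(list(factor = 1),
                                   class = "tofsss_scale_fit"))
  expect_equal(s1$values, s$values)
  s2 <- scale_scatter(s, 2)
  expect_equal(s2$values, 2 * s$values)
  expect_equal(sum(s2$values), 2 * sum(s$values))
})

test_that("noiseless pipeline recovers the injected scatter scale to 1e-6", {
  f <- scale_fixture(noise = FALSE)
  nt <- net_trues(f$sim$prompts, f$sim$randoms, f$sim$norm)
  mask <- build_tail_mask(f$m$mu, f$sc, f$idx, projector = f$proj)
  tb <- backproject(nt, mask, f$sc, f$idx, f$m$mu, f$proj)
  sb <- backproject(f$sim$truth$scatter_shape, mask, f$sc, f$idx, f$m$mu,
                    f$proj)
  fit <- fit_scale(tb, sb)
  expect_equal(fit$factor, f$sim$truth$true_scale, tolerance = 1e-6)
})

test_that("Poisson noise: scale recovered within 5% across 20 seeds", {
  f0 <- scale_fixture(n_counts = 1e7, noise = FALSE)
  mask <- build_tail_mask(f0$m$mu, f0$sc, f0$idx, projector = f0$proj)
  ## at least 1e5 expected counts on the tail bins
  canon4 <- array(f0$idx$canonical, dim(f0$sim$prompts$values))
  tail_counts <- sum(f0$sim$prompts$values[mask$values & canon4])
  expect_gt(tail_counts, 1e5)
  sb <- backproject(f0$sim$truth$scatter_shape, mask, f0$sc, f0$idx, f0$m$mu,
                    f0$proj)
  canon <- as.vector(f0$idx$canonical)
  nb <- dim(f0$sim$prompts$values)[4]
  for (seed in 1:20) {
    set.seed(seed)
    noisy <- f0$sim$prompts
    pv <- matrix(noisy$values, ncol = nb)
    pv[canon, ] <- matrix(stats::rpois(sum(canon) * nb, pv[canon, ]),
                          ncol = nb)
    noisy$values <- tofsss:::mirror_fill(array(pv, dim(noisy$values)),
                                         f0$idx)
    nt <- net_trues(noisy)
    tb <- backproject(nt, mask, f0$sc, f0$idx, f0$m$mu, f0$proj)
    fit <- fit_scale(tb, sb)
    expect_equal(fit$factor, f0$sim$truth$true_scale, tolerance = 0.05,
                 label = sprintf("seed %d factor", seed))
  }
})
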