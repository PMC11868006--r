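# TOF single-scatter estimator: scatter-point sampling, the single-LOR
# reference kernel, and bin-for-bin equivalence of the vectorised estimator
# with a literal nested loop over LORs and scatter points.

test_that("scatter points form the strided lattice inside the support", {
  m <- toy_maps(n = 12, voxel = 6)
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24)
  pts <- sample_scatter_points(m$mu, sc, strides = c(3, 3, 2),
                               axial_extent_factor = 1.5)
  ## brute-force membership count over the same lattice
  ix <- seq(2, 12, by = 3); iz <- seq(1, 12, by = 2)
  zc <- voxel_centers(m$mu, 3)[iz]
  iz <- iz[abs(zc) <= 1.5 * sc$axial_fov_mm / 2]
  cnt <- 0
  for (i in ix) for (j in ix) for (k in iz)
    if (m$mu$values[i, j, k] > 0) cnt <- cnt + 1
  expect_equal(nrow(pts$positions), cnt)
  expect_true(all(pts$mu_values > 0))
  expect_true(all(abs(pts$positions[, 3]) <= 1.5 * sc$axial_fov_mm / 2))
  expect_equal(pts$cell_volume_mm3, 3 * 3 * 2 * 6^3)
  ## all-zero mu map errors
  zero <- voxel_volume(array(0, c(4, 4, 4)), 6, quantity = "mu_511")
  expect_error(sample_scatter_points(zero, sc), "no scatter points")
})

test_that("single-LOR kernel: zero activity, symmetry, forward-scatter cutoff", {
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24)
  m <- toy_maps(n = 10, voxel = 8)
  zero_act <- voxel_volume(array(0, dim(m$activity$values)),
                           m$activity$voxel_size, m$activity$origin)
  v <- single_scatter_lor(sc, 1, 5, c(10, 15, 0), 0.0096, zero_act, m$mu)
  expect_equal(v, numeric(sc$specs$n_tof_bins))
  ## S on the perpendicular bisector plane of a symmetric LOR, symmetric
  ## phantom: TOF spectrum symmetric under bin reversal
  ## crystals 1 and 5 are at +x and -x in ring 1; bisector plane is x = 0
  v2 <- single_scatter_lor(sc, 1, 5, c(0, 20, -5), 0.0096,
                           m$activity, m$mu)
  expect_gt(sum(v2), 0)
  expect_equal(v2, rev(v2), tolerance = 1e-9)
  ## scatter point on the LOR axis (ring 1 sits at z = -12):
  ## deflection ~ 0, dropped by min_theta
  v3 <- single_scatter_lor(sc, 1, 5, c(5, 0, -12), 0.0096, m$activity, m$mu)
  expect_equal(v3, numeric(sc$specs$n_tof_bins))
})

test_that("vectorised estimator equals the nested-loop reference bin-for-bin", {
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24)
  m <- toy_maps(n = 10, voxel = 8, act_kind = "blob")
  plan <- make_sampling_plan(sc, 1, sc$n_rings)
  pts <- sample_scatter_points(m$mu, sc, strides = c(3, 3, 2),
                               axial_extent_factor = 1.5)
  expect_gte(nrow(pts$positions), 20)
  est <- estimate_sampled_scatter(sc, plan, m$activity, m$mu, pts)

  ## literal nested loops over grid cells and scatter points
  N <- sc$crystals_per_ring
  nb <- sc$specs$n_tof_bins
  K <- length(plan$angle_vals)
  ref <- array(0, dim(est$values))
  for (ia in seq_along(plan$angle_vals)) {
    for (id in seq_along(plan$radial_vals)) {
      for (r1 in seq_along(plan$ring_ids)) for (r2 in seq_along(plan$ring_ids)) {
        a <- plan$angle_vals[ia]; d <- plan$radial_vals[id]
        idA <- (plan$ring_ids[r1] - 1) * N + a + 1
        idB <- (plan$ring_ids[r2] - 1) * N + ((a + d) %% N) + 1
        acc <- numeric(nb)
        for (p in seq_len(nrow(pts$positions))) {
          acc <- acc + single_scatter_lor(sc, idA, idB, pts$positions[p, ],
                                          pts$mu_values[p], m$activity, m$mu)
        }
        ref[ia, id, r1, r2, ] <- acc * pts$cell_volume_mm3
      }
    }
  }
  expect_equal(est$values, ref, tolerance = 1e-10)
  expect_true(all(est$values >= 0))
  expect_true(all(is.finite(est$values)))
})

test_that("estimator is linear in activity and additive over scatter points", {
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24)
  m <- toy_maps(n = 10, voxel = 8, act_kind = "blob")
  plan <- make_sampling_plan(sc, 1 / 2, 2)
  pts <- sample_scatter_points(m$mu, sc, strides = c(5, 5, 5))
  est1 <- estimate_sampled_scatter(sc, plan, m$activity, m$mu, pts)
  act2 <- voxel_volume(2 * m$activity$values, m$activity$voxel_size,
                       m$activity$origin)
  est2 <- estimate_sampled_scatter(sc, plan, act2, m$mu, pts)
  expect_equal(est2$values, 2 * est1$values, tolerance = 1e-12)
  ## additivity over scatter points
  split_pts <- function(p, sel) {
    structure(list(positions = p$positions[sel, , drop = FALSE],
                   mu_values = p$mu_values[sel], strides = p$strides,
                   cell_volume_mm3 = p$cell_volume_mm3),
              class = "tofsss_scatter_points")
  }
  n <- nrow(pts$positions)
  half <- seq_len(n) <= n / 2
  est_a <- estimate_sampled_scatter(sc, plan, m$activity, m$mu,
                                    split_pts(pts, half))
  est_b <- estimate_sampled_scatter(sc, plan, m$activity, m$mu,
                                    split_pts(pts, !half))
  expect_equal(est_a$values + est_b$values, est1$values, tolerance = 1e-12)
})

test_that("TOF-summed estimate equals a single all-covering TOF bin", {
  ## wide TOF range so the truncated timing kernel loses no mass
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24,
                    n_tof_bins = 7, tof_range = 2800, tof_res = 150)
  m <- toy_maps(n = 10, voxel = 8, act_kind = "blob")
  plan <- make_sampling_plan(sc, 1 / 2, 2)
  pts <- sample_scatter_points(m$mu, sc, strides = c(4, 4, 4))
  est <- estimate_sampled_scatter(sc, plan, m$activity, m$mu, pts)
  sc1 <- sc
  sc1$specs$n_tof_bins <- 1L
  est1 <- estimate_sampled_scatter(sc1, plan, m$activity, m$mu, pts,
                                   specs = sc1$specs)
  tof_sum <- apply(est$values, 1:4, sum)
  expect_equal(tof_sum, est1$values[, , , , 1], tolerance = 1e-6)
})

test_that("raising attenuation never increases transmission factors", {
  sc <- toy_scanner(8, 2, radius = 60, pitch = 24)
  m <- toy_maps(n = 10, voxel = 8, act_kind = "blob")
  plan <- make_sampling_plan(sc, 1 / 2, 2)
  pts <- sample_scatter_points(m$mu, sc, strides = c(5, 5, 4))
  mu_hi <- voxel_volume(1.1 * m$mu$values, m$mu$voxel_size, m$mu$origin,
                        "mu_511")
  ## hold the mu(S) scatter-point weight constant: only the e^{-...}
  ## factors change
  est_lo <- estimate_sampled_scatter(sc, plan, m$activity, m$mu, pts)
  est_hi <- estimate_sampled_scatter(sc, plan, m$activity, mu_hi, pts)
  expect_true(all(est_hi$values <= est_lo$values + 1e-12))
})
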