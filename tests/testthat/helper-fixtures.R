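# Shared fixtures: tiny scanners, phantoms and volumes built in code.

## 8-crystal x 2-ring toy scanner for exhaustive / brute-force checks
toy_scanner <- function(n_crystals = 8, n_rings = 2, radius = 60,
                        pitch = 10, n_tof_bins = 5, tof_range = 700,
                        tof_res = 150, ...) {
  build_ring_scanner(n_crystals, n_rings, radius, pitch,
                     scanner_specs(tof_resolution_ps = tof_res,
                                   tof_range_ps = tof_range,
                                   n_tof_bins = n_tof_bins, ...))
}

## small uniform water cylinder (mu) + activity blob volumes on one grid
toy_maps <- function(n = 10, voxel = 8, body_radius = 32, body_halflen = 38,
                     act_kind = c("cylinder", "blob", "smooth"),
                     blob_sigma = body_radius / 2) {
  act_kind <- match.arg(act_kind)
  dims <- rep(n, 3)
  origin <- -dims * voxel / 2
  cx <- (seq_len(n) - 0.5) * voxel + origin[1]
  X <- array(rep(cx, times = n * n), dims)
  Y <- array(rep(rep(cx, each = n), times = n), dims)
  Z <- array(rep(cx, each = n * n), dims)
  inside <- (X^2 + Y^2 <= body_radius^2) & (abs(Z) <= body_halflen)
  if (act_kind == "smooth") {
    ## edgeless variant: super-Gaussian attenuation body and Gaussian
    ## activity blob, for tests that need a smooth scatter distribution
    mu_vals <- 0.0096 * exp(-((X^2 + Y^2) / body_radius^2)^3) *
      exp(-(Z / body_halflen)^6)
    act_vals <- 1000 * exp(-(X^2 + Y^2 + Z^2) / (2 * blob_sigma^2))
    return(list(activity = voxel_volume(act_vals, voxel, origin, "activity"),
                mu = voxel_volume(mu_vals, voxel, origin, "mu_511")))
  }
  mu <- voxel_volume(inside * 0.0096, voxel, origin, "mu_511")
  act_vals <- if (act_kind == "cylinder") inside * 1000 else
    1000 * exp(-(X^2 + Y^2 + Z^2) / (2 * blob_sigma^2)) * inside
  act <- voxel_volume(act_vals, voxel, origin, "activity")
  list(activity = act, mu = mu)
}

## small NEMA-like phantom scaled to a toy scanner bore; dimensioned so the
## 12-background-ROI template fits between the spheres and the body edge
toy_phantom_spec <- function(body_radius = 40, body_length = 96) {
  nema_phantom_spec(body_radius_mm = body_radius,
                    body_length_mm = body_length,
                    sphere_diameters_mm = c(8, 10),
                    sphere_ring_radius_mm = 18,
                    hot_activity_ratio = 4,
                    n_cold = 1,
                    lung_radius_mm = 7,
                    background_activity = 1000)
}

## deterministic random volume for ray-tracer oracles: smoothed noise, so
## that the midpoint-rule oracle (which mis-assigns up to half a step at
## each voxel boundary) converges fast
random_volume <- function(seed, n = c(7, 9, 8), voxel = c(3, 2.5, 4),
                          smooth = 3) {
  set.seed(seed)
  a <- array(stats::runif(prod(n)), n)
  sm1 <- function(x) (c(x[1], x[-length(x)]) + 2 * x +
                        c(x[-1], x[length(x)])) / 4
  for (k in seq_len(smooth)) {
    a <- aperm(apply(a, c(2, 3), sm1), c(1, 2, 3))
    a <- aperm(apply(a, c(1, 3), sm1), c(2, 1, 3))
    a <- aperm(apply(a, c(1, 2), sm1), c(2, 3, 1))
  }
  voxel_volume(1 + 0.05 * a, voxel, -n * voxel / 2 + stats::runif(3, -1, 1),
               "activity")
}

## dense midpoint-rule oracle for line integrals (independent of the exact
## traversal): samples the volume at small steps along the segment
midpoint_line_integral <- function(volume, p0, p1, step_frac = 0.01) {
  L <- sqrt(sum((p1 - p0)^2))
  h <- min(volume$voxel_size) * step_frac
  m <- ceiling(L / h)
  tt <- (seq_len(m) - 0.5) / m * L
  u <- (p1 - p0) / L
  n <- dim(volume$values)
  val <- 0
  idx <- floor(sweep(outer(tt, u), 2, p0 - volume$origin, `+`) /
               rep(volume$voxel_size, each = m)) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= n[1] & idx[, 2] >= 1 & idx[, 2] <= n[2] &
    idx[, 3] >= 1 & idx[, 3] <= n[3]
  sum(volume$values[idx[ok, , drop = FALSE]]) * L / m
}
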