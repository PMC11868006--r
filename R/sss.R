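## TOF single-scatter estimation.
##
## For detectors A, B and scatter point S, the single-scatter contribution is
## the Watson decomposition into (i) photons reaching S, (ii) the
## Klein-Nishina probability of scattering by the deflection angle theta of
## the path A-S-B, and (iii) transmission and detection of both photons:
##
##   value[bin] = [mu(S)/sigma_KN(511)] / (R_AS^2 R_BS^2) * dsigma/dOmega(theta)
##                * eff(511) * eff(E') *
##                { exp(-[I_mu(SA) + k(E') I_mu(SB)]) * tofbin(activity on SA)
##                + exp(-[I_mu(SB) + k(E') I_mu(SA)]) * tofbin(activity on SB) }
##
## with E' = scattered_energy(511, theta), k(E') = sigma_KN(E')/sigma_KN(511)
## (Compton-dominated energy scaling of the mu map), and theta the deflection
## from the straight-through direction (zero when S lies on the segment AB).
## Emission on the S-A leg sends the unscattered photon to A and the
## scattered one to B; TOF assignment uses t = t_A - t_B, so an emission
## point at arc l from S on the S-A leg has t = (L_SA - L_SB - 2l)/c.
## Absolute constants (r_e^2, crystal face area) are dropped: the tail fit
## supplies the global scale.

#' Sample scatter points from an attenuation map
#'
#' Takes a strided lattice of voxel centers of the (prepared) mu map,
#' keeping voxels with attenuation above `mu_epsilon` and within
#' `axial_extent_factor` times the half axial FOV of the isocenter on each
#' side. Each point carries the local mu and the lattice cell volume used as
#' the scatter-volume weight.
#'
#' @param mu_map Prepared attenuation [voxel_volume()].
#' @param scanner Scanner model (axial FOV for the axial clip).
#' @param strides Integer voxel strides (sx, sy, sz), default (3, 3, 2).
#' @param axial_extent_factor Axial clip: points with
#'   `|z| <= axial_extent_factor * axial_fov / 2` are kept (default 1.5).
#' @param mu_epsilon Minimum mu for a voxel to scatter (default 0: any
#'   non-zero attenuation).
#' @return Object of class `tofsss_scatter_points` with `positions` (n x 3
#'   mm), `mu_values`, `strides`, `cell_volume_mm3`.
#' @export
sample_scatter_points <- function(mu_map, scanner, strides = c(3, 3, 2),
                                  axial_extent_factor = 1.5,
                                  mu_epsilon = 0) {
  strides <- rep_len(as.integer(strides), 3)
  stopifnot(all(strides >= 1))
  n <- dim(mu_map$values)
  ix <- seq((strides[1] + 1L) %/% 2L, n[1], by = strides[1])
  iy <- seq((strides[2] + 1L) %/% 2L, n[2], by = strides[2])
  iz <- seq((strides[3] + 1L) %/% 2L, n[3], by = strides[3])
  zc <- voxel_centers(mu_map, 3)[iz]
  iz <- iz[abs(zc) <= axial_extent_factor * scanner$axial_fov_mm / 2]
  idx <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  mu <- mu_map$values[idx]
  keep <- mu > mu_epsilon
  if (!any(keep)) stop("no scatter points: attenuation map has no support")
  idx <- idx[keep, , drop = FALSE]
  pos <- cbind(voxel_centers(mu_map, 1)[idx[, 1]],
               voxel_centers(mu_map, 2)[idx[, 2]],
               voxel_centers(mu_map, 3)[idx[, 3]])
  structure(list(positions = pos, mu_values = mu[keep],
                 strides = strides,
                 cell_volume_mm3 = prod(strides * mu_map$voxel_size)),
            class = "tofsss_scatter_points")
}

#' Single-scatter TOF contribution of one LOR and one scatter point
#'
#' Reference implementation of the scatter kernel (see the file header for
#' the model): computes the per-TOF-bin single-scatter probability density
#' for the LOR between crystals `idA` and `idB` and a single scatter point,
#' by direct line integrals. Used both as the user-facing single-LOR probe
#' and as the independent reference against which the vectorised estimator
#' is tested. The scatter-volume weight (lattice cell volume) is NOT
#' included; [estimate_sampled_scatter()] applies it.
#'
#' @param scanner Scanner model.
#' @param idA,idB Crystal ids of the LOR (order defines the TOF sign:
#'   `t = t_A - t_B`).
#' @param s_pos Scatter point position (mm).
#' @param s_mu Attenuation at the scatter point (1/mm).
#' @param activity,mu Activity and attenuation [voxel_volume()]s.
#' @param specs Scanner specs (defaults to the scanner's).
#' @param min_theta Deflection-angle cutoff in radians (default 1e-3);
#'   smaller deflections contribute zero (forward-scatter degeneracy).
#' @param min_distance Minimum scatter-point-to-crystal distance in mm
#'   (default: one voxel diagonal of the mu map); closer points contribute
#'   zero (1/R^2 singularity).
#' @param incidence_cosines Include crystal-face incidence cosine factors
#'   (point-detector model off by default).
#' @return Numeric vector of per-TOF-bin contributions (smeared).
#' @export
single_scatter_lor <- function(scanner, idA, idB, s_pos, s_mu, activity, mu,
                               specs = scanner$specs,
                               min_theta = 1e-3,
                               min_distance = NULL,
                               incidence_cosines = FALSE) {
  edges <- tof_bin_edges(specs)
  nb <- length(edges) - 1L
  if (is.null(min_distance)) min_distance <- max(mu$voxel_size)
  pA <- scanner$crystal_xyz[idA, ]
  pB <- scanner$crystal_xyz[idB, ]
  vA <- pA - s_pos; vB <- pB - s_pos
  RA <- sqrt(sum(vA^2)); RB <- sqrt(sum(vB^2))
  if (RA < min_distance || RB < min_distance) return(numeric(nb))
  ## deflection angle: angle between the incoming direction (A -> S) and the
  ## outgoing direction (S -> B); zero when S is on the segment A-B
  cth <- -sum(vA * vB) / (RA * RB)
  theta <- acos(pmin(pmax(cth, -1), 1))
  if (theta < min_theta) return(numeric(nb))
  Ep <- scattered_energy(.mec2_kev, theta)
  sigE <- energy_fwhm_kev(Ep, specs$energy_resolution_fwhm) * .fwhm_to_sigma
  if (Ep < specs$energy_lld_kev - 4 * sigE) return(numeric(nb))
  eff <- detection_efficiency(.mec2_kev, specs) * detection_efficiency(Ep, specs)
  kE <- total_kn_cross_section(Ep) / total_kn_cross_section(.mec2_kev)
  ImuA <- line_integral(mu, s_pos, pA)
  ImuB <- line_integral(mu, s_pos, pB)
  geom <- s_mu / total_kn_cross_section(.mec2_kev) / (RA^2 * RB^2) *
    klein_nishina_dcs(.mec2_kev, theta) * eff
  if (incidence_cosines) {
    nrmA <- -c(pA[1], pA[2], 0) / sqrt(pA[1]^2 + pA[2]^2)
    nrmB <- -c(pB[1], pB[2], 0) / sqrt(pB[1]^2 + pB[2]^2)
    geom <- geom * abs(sum(vA / RA * nrmA)) * abs(sum(vB / RB * nrmB))
  }
  c_t <- RA - RB

  ## emission on S-A leg: t = (c_t - 2 l)/c, l = arc from S towards A
  lA <- (c_t - .c_mm_per_ps * edges) / 2
  mA <- -diff(eval_cum_integral(cum_integral_knots(activity,
                                                   ray_trace(activity, s_pos, pA)),
                                lA))
  ## emission on S-B leg: t = (c_t + 2 l)/c
  lB <- (.c_mm_per_ps * edges - c_t) / 2
  mB <- diff(eval_cum_integral(cum_integral_knots(activity,
                                                  ray_trace(activity, s_pos, pB)),
                               lB))
  unsmeared <- geom * (exp(-(ImuA + kE * ImuB)) * mA +
                       exp(-(ImuB + kE * ImuA)) * mB)
  as.vector(tof_kernel_matrix(specs, edges) %*% unsmeared)
}

#' Estimate the sampled scatter grid
#'
#' Vectorised TOF-SSS estimator: for every sampled LOR (the complete
#' rectilinear fan-coordinate grid of a [make_sampling_plan()]) and every
#' scatter point, accumulates the single-scatter TOF contributions into the
#' 5D sampled grid `[angle, radial, ring1, ring2, tof_bin]`. Work is
#' organised per scatter point (ray traces to each sampled detector are
#' shared across all LORs through that point); results are order-independent
#' sums, deterministic given inputs. Each point's contribution carries the
#' lattice cell volume of the point set as scatter-volume weight.
#'
#' @param scanner Scanner model.
#' @param plan A [make_sampling_plan()].
#' @param activity,mu Prepared activity and attenuation [voxel_volume()]s.
#' @param points A [sample_scatter_points()] set.
#' @param specs Scanner specs (defaults to the scanner's).
#' @inheritParams single_scatter_lor
#' @return Object of class `tofsss_scatter_sample`: `values` (5D array),
#'   `plan`, `tof_bin_edges`.
#' @export
estimate_sampled_scatter <- function(scanner, plan, activity, mu, points,
                                     specs = scanner$specs,
                                     min_theta = 1e-3,
                                     min_distance = NULL,
                                     incidence_cosines = FALSE) {
  edges <- tof_bin_edges(specs)
  nb <- length(edges) - 1L
  if (is.null(min_distance)) min_distance <- max(mu$voxel_size)
  N <- scanner$crystals_per_ring
  txs <- plan$crystal_tx
  rings <- plan$ring_ids
  M <- length(txs); nr <- length(rings)
  det_ids <- as.vector(outer(txs, rings,
                             function(t, r) crystal_id(scanner, r, t)))
  nD <- length(det_ids)
  det_xyz <- scanner$crystal_xyz[det_ids, , drop = FALSE]
  det_tx_rank <- rep(seq_len(M), times = nr)
  det_ring_rank <- rep(seq_len(nr), each = M)
  same_grid <- identical(dim(activity$values), dim(mu$values)) &&
    isTRUE(all.equal(activity$voxel_size, mu$voxel_size)) &&
    isTRUE(all.equal(activity$origin, mu$origin))

  ## ordered-pair leg values V[dA, dB, bin]: emission on the S-dA leg of the
  ## LOR (dA, dB), including all per-pair factors; the full LOR value is
  ## V[A, B, ] + rev(V[B, A, ]) (symmetric bin edges)
  sigma511 <- total_kn_cross_section(.mec2_kev)
  eff511 <- detection_efficiency(.mec2_kev, specs)
  out <- array(0, c(M, M - 1L, nr, nr, nb))
  ## map ordered detector pairs -> grid cells: cell (ia, id, ir1, ir2) has
  ## A = (rank ia, ring ir1), B = (tx (a + d) mod N, ring ir2)
  tx_rank_of <- integer(N); tx_rank_of[txs + 1L] <- seq_len(M)
  for (p in seq_len(nrow(points$positions))) {
    S <- points$positions[p, ]
    muS <- points$mu_values[p]
    vecs <- sweep(det_xyz, 2, S)
    Rd <- sqrt(rowSums(vecs^2))
    U <- vecs / Rd
    Imu_d <- numeric(nD)
    kn_act <- vector("list", nD)
    for (d in seq_len(nD)) {
      trm <- ray_trace(mu, S, det_xyz[d, ])
      Imu_d[d] <- sum(trace_values(mu, trm) * trm$len)
      tra <- if (same_grid) trm else ray_trace(activity, S, det_xyz[d, ])
      kn_act[[d]] <- cum_integral_knots(activity, tra)
    }
    cth <- -tcrossprod(U)            # cos(deflection) for ordered pairs
    theta <- acos(pmin(pmax(cth, -1), 1))
    Ep <- scattered_energy(.mec2_kev, theta)
    sigE <- energy_fwhm_kev(Ep, specs$energy_resolution_fwhm) * .fwhm_to_sigma
    ok <- theta >= min_theta & Ep >= specs$energy_lld_kev - 4 * sigE &
      outer(Rd >= min_distance, Rd >= min_distance, "&")
    kE <- total_kn_cross_section(Ep) / sigma511
    eff <- eff511 * detection_efficiency(Ep, specs)
    base <- muS / sigma511 / outer(Rd^2, Rd^2) *
      klein_nishina_dcs(.mec2_kev, theta) * eff
    if (incidence_cosines) {
      nrm <- -cbind(det_xyz[, 1], det_xyz[, 2], 0) /
        sqrt(det_xyz[, 1]^2 + det_xyz[, 2]^2)
      cosf <- abs(rowSums(U * nrm))
      base <- base * outer(cosf, cosf)
    }
    ## att[A, B] = exp(-(Imu[A] + kE[A,B] * Imu[B]))
    att <- exp(-(matrix(Imu_d, nD, nD) + kE * matrix(Imu_d, nD, nD, byrow = TRUE)))
    w <- base * att * ok
    ## leg masses: for each emission-side detector dA, evaluate its
    ## cumulative activity at the bin-edge arc positions of every partner
    V <- array(0, c(nD, nD, nb))
    for (dA in seq_len(nD)) {
      if (all(w[dA, ] == 0)) next
      ## l at edges: t = (R_A - R_B - 2 l)/c  ->  l = (R_A - R_B - c t)/2
      ct <- Rd[dA] - Rd
      Ledge <- (matrix(ct, nD, nb + 1L) -
                matrix(.c_mm_per_ps * edges, nD, nb + 1L, byrow = TRUE)) / 2
      Fv <- matrix(eval_cum_integral(kn_act[[dA]], Ledge), nD, nb + 1L)
      V[dA, , ] <- -t(diff(t(Fv))) * w[dA, ]
    }
    ## combine legs into LOR values and accumulate into the sampled grid
    contrib <- V
    contrib <- contrib + aperm(V, c(2, 1, 3))[, , nb:1, drop = FALSE]
    ## index into 5D grid: loops are cheap relative to the work above
    for (ir1 in seq_len(nr)) for (ir2 in seq_len(nr)) {
      dA_ids <- (ir1 - 1L) * M + seq_len(M)
      for (idd in seq_len(M - 1L)) {
        dval <- plan$radial_vals[idd]
        txB <- (txs + dval) %% N
        dB_ids <- (ir2 - 1L) * M + tx_rank_of[txB + 1L]
        out[, idd, ir1, ir2, ] <- out[, idd, ir1, ir2, ] +
          contrib[cbind(rep(dA_ids, nb), rep(dB_ids, nb),
                        rep(seq_len(nb), each = M))]
      }
    }
  }
  ## smear with the timing kernel and apply the scatter-volume weight
  K <- tof_kernel_matrix(specs, edges)
  flat <- matrix(out, ncol = nb)
  out <- array(flat %*% t(K), dim(out)) * points$cell_volume_mm3
  structure(list(values = out, plan = plan, tof_bin_edges = edges,
                 specs = specs),
            class = "tofsss_scatter_sample")
}
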