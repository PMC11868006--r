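#' Default scanner specification list
#'
#' Energy and timing specifications used throughout the estimator: fractional
#' energy resolution (FWHM at 511 keV), lower/upper energy discriminators
#' (keV), TOF resolution (FWHM, ps), TOF range (ps, bins span
#' `[-range/2, +range/2]`), number of TOF bins (odd), and the maximum ring
#' difference of accepted coincidences. Defaults follow a modern clinical
#' TOF scanner: 10.8% energy resolution, 435 keV threshold, 264 ps TOF
#' resolution, 1000 ps TOF range.
#'
#' @param energy_resolution_fwhm Fractional FWHM of the energy response at
#'   511 keV.
#' @param energy_lld_kev Lower energy discriminator, keV.
#' @param energy_uld_kev Upper energy discriminator, keV (`Inf` for none).
#' @param tof_resolution_ps Coincidence timing resolution FWHM, ps.
#' @param tof_range_ps Width of the TOF acceptance window, ps.
#' @param n_tof_bins Odd number of TOF bins.
#' @param max_ring_difference Maximum |ring1 - ring2| of accepted LORs.
#' @return A named list of specifications.
#' @export
scanner_specs <- function(energy_resolution_fwhm = 0.108,
                          energy_lld_kev = 435,
                          energy_uld_kev = Inf,
                          tof_resolution_ps = 264,
                          tof_range_ps = 1000,
                          n_tof_bins = 13,
                          max_ring_difference = NULL) {
  stopifnot(energy_resolution_fwhm > 0, tof_resolution_ps > 0,
            tof_range_ps > 0, n_tof_bins >= 1, n_tof_bins %% 2 == 1,
            energy_lld_kev < 511,
            !is.finite(energy_uld_kev) || energy_uld_kev > 511)
  list(energy_resolution_fwhm = energy_resolution_fwhm,
       energy_lld_kev = energy_lld_kev,
       energy_uld_kev = energy_uld_kev,
       tof_resolution_ps = tof_resolution_ps,
       tof_range_ps = tof_range_ps,
       n_tof_bins = as.integer(n_tof_bins),
       max_ring_difference = max_ring_difference)
}

#' Build a cylindrical ring scanner model
#'
#' Places `n_crystals_per_ring` crystals uniformly on circles of radius
#' `ring_radius_mm`, on `n_rings` rings uniformly spaced by `axial_pitch_mm`
#' and centered axially on the isocenter. Crystal ids are 1-based:
#' `id = (ring - 1) * n_crystals_per_ring + transaxial_index + 1`, with the
#' transaxial index running 0..N-1 counter-clockwise from the +x axis.
#'
#' @param n_crystals_per_ring Even integer `>= 8`.
#' @param n_rings Positive integer.
#' @param ring_radius_mm Distance of every crystal from the scanner axis.
#' @param axial_pitch_mm Axial spacing between adjacent rings.
#' @param specs A [scanner_specs()] list.
#' @return Object of class `tofsss_scanner` with crystal coordinates, ring
#'   structure, axial FOV (`n_rings * axial_pitch_mm`) and specifications.
#' @export
build_ring_scanner <- function(n_crystals_per_ring, n_rings, ring_radius_mm,
                               axial_pitch_mm = 4, specs = scanner_specs()) {
  N <- as.integer(n_crystals_per_ring)
  R <- as.integer(n_rings)
  if (N < 8 || N %% 2 != 0)
    stop("n_crystals_per_ring must be an even integer >= 8")
  stopifnot(R >= 1, ring_radius_mm > 0, axial_pitch_mm > 0)
  if (is.null(specs$max_ring_difference))
    specs$max_ring_difference <- R - 1L
  stopifnot(specs$max_ring_difference < R)
  ring_z <- (seq_len(R) - (R + 1) / 2) * axial_pitch_mm
  phi <- 2 * pi * (0:(N - 1)) / N
  xyz <- cbind(x = rep(ring_radius_mm * cos(phi), R),
               y = rep(ring_radius_mm * sin(phi), R),
               z = rep(ring_z, each = N))
  structure(list(crystal_xyz = xyz,
                 crystals_per_ring = N,
                 n_rings = R,
                 ring_z = ring_z,
                 ring_radius_mm = ring_radius_mm,
                 axial_pitch_mm = axial_pitch_mm,
                 axial_fov_mm = R * axial_pitch_mm,
                 specs = specs),
            class = "tofsss_scanner")
}

#' @export
print.tofsss_scanner <- function(x, ...) {
  cat(sprintf(paste0("<tofsss_scanner> %d crystals/ring x %d rings, ",
                     "radius %.1f mm, axial FOV %.1f mm\n"),
              x$crystals_per_ring, x$n_rings, x$ring_radius_mm,
              x$axial_fov_mm))
  cat(sprintf("  %.1f%% energy res, LLD %g keV, TOF %g ps FWHM, %d bins over %g ps\n",
              100 * x$specs$energy_resolution_fwhm, x$specs$energy_lld_kev,
              x$specs$tof_resolution_ps, x$specs$n_tof_bins,
              x$specs$tof_range_ps))
  invisible(x)
}

crystal_ring <- function(scanner, id) {
  (as.integer(id) - 1L) %/% scanner$crystals_per_ring + 1L
}
crystal_tx <- function(scanner, id) {
  (as.integer(id) - 1L) %% scanner$crystals_per_ring
}
crystal_id <- function(scanner, ring, tx) {
  (as.integer(ring) - 1L) * scanner$crystals_per_ring + as.integer(tx) + 1L
}

#' Sinogram index for a ring scanner
#'
#' Defines the sinogram coordinate system used throughout the package: the
#' crystal-difference "fan" convention, chosen because uniformly strided
#' crystal subsets then form complete rectilinear grids (as required by the
#' unit-grid interpolation). For a LOR between transaxial indices
#' `(tA, tB)` (crystal A in `ring1`, B in `ring2`):
#' `angle index = tA + 1` (periodic axis, N values) and
#' `radial index = (tB - tA) mod N`, in 1..N-1; same-transaxial pairs are
#' excluded. Planes enumerate the michelogram: all ordered ring pairs with
#' `|ring1 - ring2| <= max_ring_difference`. Each physical LOR owns one
#' canonical bin (`ring1 < ring2`, or `tA < tB` within a ring) plus a mirror
#' alias bin with crystals swapped; sinogram arrays are kept mirror-symmetric.
#'
#' @param scanner A [build_ring_scanner()] model.
#' @return Object of class `tofsss_sino_index` with `n_angles`, `n_radial`,
#'   `plane_table` (data frame ring1, ring2), `plane_of` (lookup matrix) and
#'   `canonical` (logical `[angle, radial, plane]` array marking canonical
#'   bins).
#' @export
sinogram_index <- function(scanner) {
  N <- scanner$crystals_per_ring
  R <- scanner$n_rings
  mrd <- scanner$specs$max_ring_difference
  pt <- expand.grid(ring1 = seq_len(R), ring2 = seq_len(R))
  pt <- pt[abs(pt$ring1 - pt$ring2) <= mrd, , drop = FALSE]
  pt <- pt[order(pt$ring1, pt$ring2), ]
  rownames(pt) <- NULL
  plane_of <- matrix(NA_integer_, R, R)
  plane_of[cbind(pt$ring1, pt$ring2)] <- seq_len(nrow(pt))
  ## canonical: ring1 < ring2 always; within a ring, tA < tB, i.e.
  ## (angle-1) + radial <= N - 1
  canon <- array(TRUE, c(N, N - 1L, nrow(pt)))
  same <- which(pt$ring1 == pt$ring2)
  tA <- matrix(0:(N - 1), N, N - 1L)
  dd <- matrix(seq_len(N - 1L), N, N - 1L, byrow = TRUE)
  canon_same <- (tA + dd) <= (N - 1L)
  for (p in same) canon[, , p] <- canon_same
  canon[, , pt$ring1 > pt$ring2] <- FALSE
  structure(list(n_angles = N, n_radial = N - 1L,
                 plane_table = pt, plane_of = plane_of,
                 canonical = canon,
                 crystals_per_ring = N, n_rings = R,
                 max_ring_difference = mrd),
            class = "tofsss_sino_index")
}

#' Sinogram coordinates of a crystal pair
#'
#' Maps a valid crystal pair to its canonical sinogram bin
#' `(angle_idx, radial_idx, ring1, ring2)` under the fan convention of
#' [sinogram_index()]. The result is independent of the order in which the
#' two crystals are given. Vectorised over pairs.
#'
#' @param scanner A scanner model.
#' @param idA,idB Crystal ids (1-based); must differ in transaxial position
#'   and respect the maximum ring difference.
#' @return Data frame with columns angle_idx, radial_idx, ring1, ring2.
#' @export
sinogram_coords <- function(scanner, idA, idB) {
  N <- scanner$crystals_per_ring
  rA <- crystal_ring(scanner, idA); tA <- crystal_tx(scanner, idA)
  rB <- crystal_ring(scanner, idB); tB <- crystal_tx(scanner, idB)
  if (any(tA == tB))
    stop("crystals must be in different transaxial positions")
  if (any(abs(rA - rB) > scanner$specs$max_ring_difference))
    stop("ring difference exceeds max_ring_difference")
  swap <- (rA > rB) | (rA == rB & tA > tB)
  t1 <- ifelse(swap, tB, tA); t2 <- ifelse(swap, tA, tB)
  r1 <- ifelse(swap, rB, rA); r2 <- ifelse(swap, rA, rB)
  data.frame(angle_idx = t1 + 1L,
             radial_idx = ((t2 - t1) %% N),
             ring1 = r1, ring2 = r2)
}

#' Crystal pair of a sinogram bin
#'
#' Inverse of [sinogram_coords()]: returns the two crystal ids of the bin
#' `(angle_idx, radial_idx, plane)` (alias bins are valid input and return
#' the same physical pair with roles swapped). Vectorised.
#'
#' @param scanner A scanner model.
#' @param index A [sinogram_index()].
#' @param angle_idx,radial_idx,plane 1-based bin coordinates.
#' @return Data frame with columns idA, idB.
#' @export
crystal_pair_of_bin <- function(scanner, index, angle_idx, radial_idx, plane) {
  N <- scanner$crystals_per_ring
  pt <- index$plane_table
  tA <- angle_idx - 1L
  tB <- (tA + radial_idx) %% N
  data.frame(idA = crystal_id(scanner, pt$ring1[plane], tA),
             idB = crystal_id(scanner, pt$ring2[plane], tB))
}

#' Uniform LOR sampling plan
#'
#' Selects every `1/detector_fraction`-th crystal per ring (the stride must
#' divide the crystal count) and `n_sampled_rings` rings spread uniformly and
#' always including the first and last ring. The sampled LORs are all pairs
#' of sampled crystals across all sampled ring pairs, which form a complete
#' rectilinear grid in the fan sinogram coordinates: angle values =
#' sampled transaxial indices, radial values = multiples of the stride,
#' ring axes = sampled ring ids (the full michelogram square, so that
#' interpolation cells near the ring-difference limit always have corners).
#'
#' @param scanner A scanner model.
#' @param detector_fraction Fraction of crystals sampled per ring (e.g. 1/4);
#'   `1/detector_fraction` must be an integer dividing the crystal count.
#' @param n_sampled_rings Number of sampled rings (default 6, capped at the
#'   ring count).
#' @return Object of class `tofsss_sampling_plan` with `stride`,
#'   `crystal_tx` (0-based sampled transaxial indices), `ring_ids`,
#'   `angle_vals`, `radial_vals`, and `grid_shape`.
#' @export
make_sampling_plan <- function(scanner, detector_fraction = 1 / 4,
                               n_sampled_rings = 6) {
  N <- scanner$crystals_per_ring
  stride <- 1 / detector_fraction
  if (abs(stride - round(stride)) > 1e-9 || N %% round(stride) != 0)
    stop("1/detector_fraction must be an integer dividing the crystal count")
  stride <- as.integer(round(stride))
  R <- scanner$n_rings
  ns <- min(as.integer(n_sampled_rings), R)
  stopifnot(ns >= 1)
  ring_ids <- if (ns == 1) 1L else
    as.integer(round(seq(1, R, length.out = ns)))
  if (anyDuplicated(ring_ids)) stop("n_sampled_rings too large for ring count")
  M <- N %/% stride
  structure(list(stride = stride,
                 detector_fraction = detector_fraction,
                 crystal_tx = as.integer(seq(0, N - 1, by = stride)),
                 ring_ids = ring_ids,
                 angle_vals = as.integer(seq(0, N - 1, by = stride)),
                 radial_vals = as.integer(stride * seq_len(M - 1)),
                 grid_shape = c(angle = M, radial = M - 1L,
                                ring1 = ns, ring2 = ns)),
            class = "tofsss_sampling_plan")
}
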