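## Expansion of the sampled scatter grid to the full TOF sinogram.
##
## Interpolation is performed directly in the 4D sinogram space (angle,
## radial, ring1, ring2) on unit-grid coordinates: consecutive sampled grid
## points are at distance one along every axis, whatever their physical
## spacing. Multilinear (degree-1) interpolation per TOF bin; the TOF axis is
## a set of independent channels. The angle axis is periodic (the crystal
## ring wraps); the radial axis is clamped to the outermost sampled
## coordinate; ring axes always contain the first and last ring, so no ring
## extrapolation occurs.

## fractional unit-grid coordinate of value `x` within sorted sampled values
## `vals` (clamped); returns floor index i0 (1-based, < length(vals)) and
## fraction f in [0, 1].
unit_coord <- function(x, vals) {
  nv <- length(vals)
  i0 <- findInterval(x, vals, rightmost.closed = TRUE)
  i0 <- pmin(pmax(i0, 1L), nv - 1L)
  f <- (x - vals[i0]) / (vals[i0 + 1L] - vals[i0])
  list(i0 = i0, f = pmin(pmax(f, 0), 1))
}

#' Interpolate the sampled scatter grid to the full TOF sinogram
#'
#' Fills every bin of the full sinogram (all angles, radial offsets and
#' allowed ring-difference planes) by 4D multilinear interpolation of the
#' sampled scatter grid on unit-grid coordinates, per TOF bin. Exact at
#' sampled grid points; reproduces constant and (grid-)linear fields; output
#' clamped at zero. Canonical bins are interpolated and alias bins
#' mirror-filled, so the output is exactly mirror-symmetric.
#'
#' @param sample A [estimate_sampled_scatter()] result.
#' @param scanner Scanner model.
#' @param index A [sinogram_index()] of the scanner.
#' @return A [tof_sinogram()] of kind `"scatter"`.
#' @export
interpolate_full <- function(sample, scanner, index) {
  plan <- sample$plan
  gs <- plan$grid_shape
  if (!identical(dim(sample$values)[1:4], unname(gs)))
    stop("sample grid incomplete: values do not match the sampling plan grid")
  nb <- dim(sample$values)[5]
  N <- index$n_angles
  M <- gs[1]
  stride <- plan$stride
  nplanes <- nrow(index$plane_table)
  dims <- c(N, index$n_radial, nplanes, nb)

  w <- which(index$canonical)
  a <- ((w - 1L) %% N)                                  # transaxial index tA
  d <- (((w - 1L) %/% N) %% index$n_radial) + 1L         # radial offset
  p <- ((w - 1L) %/% (N * index$n_radial)) + 1L
  r1 <- index$plane_table$ring1[p]
  r2 <- index$plane_table$ring2[p]

  ## unit coordinates per axis
  xa_i0 <- (a %/% stride)
  xa_f <- (a %% stride) / stride              # periodic: neighbor (i0+1) %% M
  rc <- unit_coord(d, plan$radial_vals)       # clamped radial
  u1 <- unit_coord(r1, plan$ring_ids)
  u2 <- unit_coord(r2, plan$ring_ids)

  smat <- matrix(sample$values, ncol = nb)
  gm <- c(M, gs[2], gs[3], gs[4])
  out_can <- matrix(0, length(w), nb)
  for (ca in 0:1) for (cd in 0:1) for (c1 in 0:1) for (c2 in 0:1) {
    wt <- (if (ca) xa_f else 1 - xa_f) *
      (if (cd) rc$f else 1 - rc$f) *
      (if (c1) u1$f else 1 - u1$f) *
      (if (c2) u2$f else 1 - u2$f)
    nzw <- wt > 0
    if (!any(nzw)) next
    ia <- ((xa_i0 + ca) %% M) + 1L
    id <- rc$i0 + cd
    i1 <- u1$i0 + c1
    i2 <- u2$i0 + c2
    lin <- ia + (id - 1L) * gm[1] + (i1 - 1L) * gm[1] * gm[2] +
      (i2 - 1L) * gm[1] * gm[2] * gm[3]
    out_can[nzw, ] <- out_can[nzw, ] +
      wt[nzw] * smat[lin[nzw], , drop = FALSE]
  }
  out_can[out_can < 0] <- 0
  vals <- matrix(0, prod(dims[1:3]), nb)
  vals[w, ] <- out_can
  vals <- mirror_fill(array(vals, dims), index)
  tof_sinogram(vals, index, sample$tof_bin_edges, "scatter")
}

#' Interpolation error report against exact full-grid estimation
#'
#' On a scanner small enough for exhaustive computation, estimates the
#' scatter on the full LOR grid exactly (sampling plan with every detector
#' and ring) and compares it with the interpolation of a reduced sampling
#' plan, using the same scatter points. Reports the maximum and mean
#' relative error over bins whose exact value exceeds
#' `rel_floor * max(exact)` (relative errors on near-empty bins are not
#' informative).
#'
#' @param scanner Scanner model.
#' @param activity,mu Prepared maps.
#' @param plan Reduced [make_sampling_plan()] to evaluate.
#' @param points Scatter point set (shared by both computations).
#' @param index Optional precomputed [sinogram_index()].
#' @param exact Optional precomputed exact full [tof_sinogram()] (from a
#'   previous call, to compare several plans against one reference).
#' @param rel_floor Fraction of the maximum exact value below which bins are
#'   excluded from relative-error statistics (default 0.01).
#' @param radial_span Radial offsets defining the interpolation domain
#'   (default: the evaluated plan's sampled span). Bins outside it are
#'   clamped extrapolation, not interpolation, and are summarised
#'   separately.
#' @return List with `max_rel_error`, `mean_rel_error`, `n_bins_compared`
#'   (interpolation domain), `edge_mean_rel_error` (clamped radial-edge
#'   bins, `NA` when the span covers everything), and the `exact` and
#'   `interpolated` sinograms.
#' @export
interp_error_report <- function(scanner, activity, mu, plan, points,
                                index = sinogram_index(scanner),
                                exact = NULL, rel_floor = 0.01,
                                radial_span = range(plan$radial_vals)) {
  if (is.null(exact)) {
    full_plan <- make_sampling_plan(scanner, 1, scanner$n_rings)
    full_sample <- estimate_sampled_scatter(scanner, full_plan, activity, mu,
                                            points)
    exact <- interpolate_full(full_sample, scanner, index)
  }
  sample <- estimate_sampled_scatter(scanner, plan, activity, mu, points)
  interp <- interpolate_full(sample, scanner, index)
  nb <- dim(exact$values)[4]
  canon <- index$canonical
  dvals <- slice.index(exact$values, 2)
  in_span <- dvals >= radial_span[1] & dvals <= radial_span[2]
  can4 <- array(canon, dim(exact$values))  # recycled over the TOF axis
  sel <- can4 & exact$values > rel_floor * max(exact$values)
  rel <- abs(interp$values - exact$values) / exact$values
  edge <- sel & !in_span
  sel <- sel & in_span
  list(max_rel_error = if (any(sel)) max(rel[sel]) else NA_real_,
       mean_rel_error = if (any(sel)) mean(rel[sel]) else NA_real_,
       edge_mean_rel_error = if (any(edge)) mean(rel[edge]) else NA_real_,
       n_bins_compared = sum(sel), exact = exact, interpolated = interp)
}
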