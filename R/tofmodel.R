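## TOF binning and the shared forward/backprojection model.
##
## TOF sign convention (fixed repo-wide): the TOF coordinate of a coincidence
## is t = t_A - t_B (arrival-time difference, ps) where A is the first
## crystal of the canonical bin; emission points nearer A give negative t.
## Bin 1 starts at the most negative edge. Bins span
## [-tof_range/2, +tof_range/2].

#' TOF bin edges of a scanner specification
#'
#' @param specs A [scanner_specs()] list.
#' @return Numeric vector of `n_tof_bins + 1` edges in ps, symmetric about 0.
#' @export
tof_bin_edges <- function(specs) {
  seq(-specs$tof_range_ps / 2, specs$tof_range_ps / 2,
      length.out = specs$n_tof_bins + 1L)
}

## Number of bins at which the discretised Gaussian timing kernel is
## truncated (4 sigma in bin widths).
tof_kernel_radius <- function(specs) {
  sigma <- specs$tof_resolution_ps * .fwhm_to_sigma
  width <- specs$tof_range_ps / specs$n_tof_bins
  as.integer(ceiling(4 * sigma / width))
}

## Discretised Gaussian timing kernel: K[b, b0] is the probability that mass
## assigned to bin b0 (represented at its center) is measured in bin b, i.e.
## the Gaussian (sigma from the TOF resolution FWHM) integrated over bin b's
## window. Truncated at 4 sigma and NOT renormalised: mass smeared beyond the
## TOF range is lost, as it is in measured data.
tof_kernel_matrix <- function(specs, edges = tof_bin_edges(specs)) {
  nb <- length(edges) - 1L
  sigma <- specs$tof_resolution_ps * .fwhm_to_sigma
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  K <- stats::pnorm(outer(edges[-1], centers, "-") / sigma) -
    stats::pnorm(outer(edges[-(nb + 1)], centers, "-") / sigma)
  kr <- tof_kernel_radius(specs)
  off <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  K[off > kr] <- 0
  K
}

#' TOF sinogram container
#'
#' A 4D array `[angle, radial, plane, tof_bin]` with its [sinogram_index()]
#' and TOF bin edges. `kind` records the payload (prompts, randoms, norm,
#' scatter, trues). Count-like kinds must be non-negative. Arrays are kept
#' mirror-symmetric over alias bins (see [sinogram_index()]).
#'
#' @param values 4D numeric array.
#' @param index A [sinogram_index()].
#' @param tof_bin_edges Bin edges in ps.
#' @param kind One of prompts, randoms, norm, scatter, trues.
#' @return Object of class `tofsss_sinogram`.
#' @export
tof_sinogram <- function(values, index, tof_bin_edges,
                         kind = c("prompts", "randoms", "norm", "scatter",
                                  "trues")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 4,
            dim(values)[1] == index$n_angles,
            dim(values)[2] == index$n_radial,
            dim(values)[3] == nrow(index$plane_table),
            dim(values)[4] == length(tof_bin_edges) - 1L)
  if (kind != "scatter" && any(values < 0))
    stop("count-like sinograms must be non-negative")
  structure(list(values = values, index = index,
                 tof_bin_edges = tof_bin_edges, kind = kind),
            class = "tofsss_sinogram")
}

#' @export
print.tofsss_sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tofsss_sinogram> kind=%s, %d angles x %d radial x %d planes x %d TOF bins\n",
              x$kind, d[1], d[2], d[3], d[4]))
  cat(sprintf("  total (canonical bins): %.6g\n", sinogram_total(x)))
  invisible(x)
}

## Sum over canonical (physical) bins only.
sinogram_total <- function(sino) {
  nb <- dim(sino$values)[4]
  canon <- as.vector(sino$index$canonical)
  v <- matrix(sino$values, ncol = nb)
  sum(v[canon, ])
}

## Canonical LOR list of an index: data frame with bin coordinates and
## crystal ids, in column-major bin order. Cached per index via an attribute.
canonical_lors <- function(scanner, index) {
  dims <- dim(index$canonical)
  w <- which(index$canonical)
  a <- ((w - 1L) %% dims[1]) + 1L
  d <- (((w - 1L) %/% dims[1]) %% dims[2]) + 1L
  p <- ((w - 1L) %/% (dims[1] * dims[2])) + 1L
  pair <- crystal_pair_of_bin(scanner, index, a, d, p)
  data.frame(angle_idx = a, radial_idx = d, plane = p,
             idA = pair$idA, idB = pair$idB, bin = w)
}

## Mirror alias of canonical bins: bin (a, d, plane(r1, r2)) -> bin
## (a', N - d, plane(r2, r1)) with a' = (a - 1 + d) mod N + 1.
mirror_bins <- function(index, a, d, p) {
  N <- index$n_angles
  pt <- index$plane_table
  pm <- index$plane_of[cbind(pt$ring2[p], pt$ring1[p])]
  cbind(((a - 1L + d) %% N) + 1L, N - d, pm)
}

## Fill alias bins of a 4D sinogram array from its canonical bins. The alias
## swaps the crystal roles, so its TOF axis (t = t_A - t_B) is reversed;
## the bin edges are symmetric about zero, so reversal is a flip of the TOF
## index.
mirror_fill <- function(values, index) {
  dims <- dim(values)
  w <- which(index$canonical)
  a <- ((w - 1L) %% dims[1]) + 1L
  d <- (((w - 1L) %/% dims[1]) %% dims[2]) + 1L
  p <- ((w - 1L) %/% (dims[1] * dims[2])) + 1L
  mb <- mirror_bins(index, a, d, p)
  nlor <- dims[1] * dims[2] * dims[3]
  v <- matrix(values, nrow = nlor)
  mlin <- mb[, 1] + (mb[, 2] - 1L) * dims[1] + (mb[, 3] - 1L) * dims[1] * dims[2]
  v[mlin, ] <- v[w, rev(seq_len(dims[4])), drop = FALSE]
  array(v, dims)
}

#' TOF projector: sparse system matrix over an image grid
#'
#' Builds the TOF-resolved forward model shared by the trues simulator, the
#' MLEM reconstructor, and the tail-fit backprojection: for every canonical
#' LOR, the exact Siddon voxel chord lengths are distributed over TOF bins by
#' the arc position of each chord (arrival-time difference `t = (2l - L)/c`
#' for emission at arc `l` from crystal A) and smeared with the discretised
#' Gaussian timing kernel. The result is a sparse matrix `A` with rows
#' indexed by (LOR, TOF bin) and columns by voxels, so that `A %*% x` is the
#' per-bin line integral of image `x`.
#'
#' @param scanner A scanner model.
#' @param index A [sinogram_index()].
#' @param grid A [voxel_volume()] supplying the image geometry (values
#'   ignored).
#' @param specs Scanner specs (defaults to the scanner's).
#' @return Object of class `tofsss_projector` with the smeared matrix `A`,
#'   the unsmeared matrix `A0`, the canonical LOR table, bin edges and grid
#'   geometry.
#' @export
tof_projector <- function(scanner, index, grid, specs = scanner$specs) {
  edges <- tof_bin_edges(specs)
  nb <- length(edges) - 1L
  K <- tof_kernel_matrix(specs, edges)
  lors <- canonical_lors(scanner, index)
  nl <- nrow(lors)
  si <- sj <- sx <- vector("list", nl)  # smeared triplets
  ui <- uj <- ux <- vector("list", nl)  # unsmeared triplets
  nvox <- prod(dim(grid$values))
  gd <- dim(grid$values)
  for (r in seq_len(nl)) {
    pA <- scanner$crystal_xyz[lors$idA[r], ]
    pB <- scanner$crystal_xyz[lors$idB[r], ]
    tr <- ray_trace(grid, pA, pB)
    if (length(tr$len) == 0) next
    L <- tr$length
    ## arc-length window of TOF bin b: l in [(L + c*e_b)/2, (L + c*e_{b+1})/2]
    ledges <- (L + .c_mm_per_ps * edges) / 2
    ## overlap of chord [t0, t1] with each bin window
    W0 <- pmax(outer(tr$t1, ledges[-1], pmin) -
               outer(tr$t0, ledges[-(nb + 1)], pmax), 0)
    Ws <- W0 %*% t(K)
    nzs <- which(Ws > 0, arr.ind = TRUE)
    nz0 <- which(W0 > 0, arr.ind = TRUE)
    jlin <- as.integer(tr$idx[, 1] + (tr$idx[, 2] - 1L) * gd[1] +
                       (tr$idx[, 3] - 1L) * gd[1] * gd[2])
    base <- (r - 1L) * nb
    si[[r]] <- base + nzs[, 2]; sj[[r]] <- jlin[nzs[, 1]]; sx[[r]] <- Ws[nzs]
    ui[[r]] <- base + nz0[, 2]; uj[[r]] <- jlin[nz0[, 1]]; ux[[r]] <- W0[nz0]
  }
  A <- Matrix::sparseMatrix(i = unlist(si), j = unlist(sj), x = unlist(sx),
                            dims = c(nl * nb, nvox))
  A0 <- Matrix::sparseMatrix(i = unlist(ui), j = unlist(uj), x = unlist(ux),
                             dims = c(nl * nb, nvox))
  structure(list(A = A, A0 = A0, lors = lors, n_tof_bins = nb,
                 tof_bin_edges = edges, index = index, grid = grid,
                 scanner = scanner),
            class = "tofsss_projector")
}

## Attenuation survival factor exp(-integral of mu) per canonical LOR.
lor_attenuation <- function(scanner, lors, mu) {
  att <- numeric(nrow(lors))
  for (r in seq_len(nrow(lors))) {
    att[r] <- exp(-line_integral(mu, scanner$crystal_xyz[lors$idA[r], ],
                                 scanner$crystal_xyz[lors$idB[r], ]))
  }
  att
}

## Extract canonical-bin values of a sinogram as an [nl * nb] vector in
## projector row order, and scatter a row vector back into a full
## mirror-symmetric 4D array.
canonical_values <- function(sino, proj) {
  nb <- proj$n_tof_bins
  dims <- dim(sino$values)
  v <- matrix(sino$values, nrow = dims[1] * dims[2] * dims[3])
  as.vector(t(v[proj$lors$bin, , drop = FALSE]))
}

sinogram_from_canonical <- function(vec, proj, kind) {
  nb <- proj$n_tof_bins
  index <- proj$index
  dims <- c(index$n_angles, index$n_radial, nrow(index$plane_table), nb)
  v <- matrix(0, dims[1] * dims[2] * dims[3], nb)
  v[proj$lors$bin, ] <- matrix(vec, ncol = nb, byrow = TRUE)
  vals <- mirror_fill(array(v, dims), index)
  tof_sinogram(vals, index, proj$tof_bin_edges, kind)
}
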