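## Exact line integrals through voxel grids.
##
## Geometry convention (fixed repo-wide): all coordinates are scanner
## coordinates in mm with the isocenter at the origin; a volume's `origin` is
## the position of the low corner of voxel (1,1,1); voxel (i,j,k) occupies the
## half-open box [origin + (i-1)*h, origin + i*h) per axis. Traversal is exact
## (Siddon-style parametric plane crossings), not sampled.

## Core traversal: returns the voxel crossings of the segment p0 -> p1 as
## parallel vectors of interval start/end arc lengths (mm from p0), interval
## lengths, and 1-based voxel indices. Crossings are contiguous and ordered.
ray_trace <- function(volume, p0, p1) {
  h <- volume$voxel_size
  o <- volume$origin
  n <- dim(volume$values)
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  if (L <= 0) stop("degenerate zero-length segment")
  u <- d / L

  tmin <- 0
  tmax <- L
  for (k in 1:3) {
    lo <- o[k]
    hi <- o[k] + n[k] * h[k]
    if (u[k] == 0) {
      if (p0[k] < lo || p0[k] >= hi) return(empty_trace(L))
    } else {
      t1 <- (lo - p0[k]) / u[k]
      t2 <- (hi - p0[k]) / u[k]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax <= tmin) return(empty_trace(L))

  ts <- c(tmin, tmax)
  for (k in 1:3) {
    if (u[k] != 0) {
      jlo <- ceiling(min((tmin * u[k] + p0[k] - o[k]) / h[k],
                         (tmax * u[k] + p0[k] - o[k]) / h[k]))
      jhi <- floor(max((tmin * u[k] + p0[k] - o[k]) / h[k],
                       (tmax * u[k] + p0[k] - o[k]) / h[k]))
      if (jhi >= jlo) {
        tk <- (o[k] + (jlo:jhi) * h[k] - p0[k]) / u[k]
        ts <- c(ts, tk[tk > tmin & tk < tmax])
      }
    }
  }
  ts <- sort(ts)
  keep <- c(TRUE, diff(ts) > 1e-12 * max(L, 1))
  ts <- ts[keep]
  m <- length(ts) - 1
  if (m < 1) return(empty_trace(L))
  tm <- (ts[-1] + ts[-(m + 1)]) / 2
  ix <- floor((p0[1] + tm * u[1] - o[1]) / h[1]) + 1L
  iy <- floor((p0[2] + tm * u[2] - o[2]) / h[2]) + 1L
  iz <- floor((p0[3] + tm * u[3] - o[3]) / h[3]) + 1L
  ok <- ix >= 1L & ix <= n[1] & iy >= 1L & iy <= n[2] & iz >= 1L & iz <= n[3]
  list(t0 = ts[-(m + 1)][ok], t1 = ts[-1][ok],
       len = (ts[-1] - ts[-(m + 1)])[ok],
       idx = cbind(ix, iy, iz)[ok, , drop = FALSE],
       length = L)
}

empty_trace <- function(L) {
  list(t0 = numeric(0), t1 = numeric(0), len = numeric(0),
       idx = matrix(integer(0), 0, 3), length = L)
}

trace_values <- function(volume, tr) {
  if (nrow(tr$idx) == 0) numeric(0) else volume$values[tr$idx]
}

#' Exact line integral of a voxel volume along a segment
#'
#' Sums voxel value times exact chord length over every voxel the segment
#' `p0 -> p1` crosses (Siddon traversal). The volume contributes zero outside
#' its support. Result units: volume units times mm.
#'
#' @param volume A [voxel_volume()].
#' @param p0,p1 Segment endpoints, length-3 numeric vectors (mm, scanner
#'   coordinates).
#' @return Scalar line integral.
#' @examples
#' v <- voxel_volume(array(2, c(4, 4, 4)), c(1, 1, 1), c(-2, -2, -2))
#' line_integral(v, c(-10, 0.5, 0.5), c(10, 0.5, 0.5))  # 2 * 4
#' @export
line_integral <- function(volume, p0, p1) {
  tr <- ray_trace(volume, p0, p1)
  sum(trace_values(volume, tr) * tr$len)
}

## Piecewise-linear cumulative integral F(l) = integral from arc length 0 to l
## along the traced segment. Returns knots (x, y) suitable for interpolation;
## F is 0 before entry and constant after exit.
cum_integral_knots <- function(volume, tr) {
  v <- trace_values(volume, tr)
  if (length(v) == 0) {
    return(list(x = c(0, tr$length), y = c(0, 0)))
  }
  x <- c(0, tr$t0[1], tr$t1, tr$length)
  y <- c(0, 0, cumsum(v * tr$len))
  y <- c(y, y[length(y)])
  keep <- c(TRUE, diff(x) > 0)
  list(x = x[keep], y = y[keep])
}

eval_cum_integral <- function(knots, l) {
  stats::approx(knots$x, knots$y, xout = pmin(pmax(l, knots$x[1]),
                                              knots$x[length(knots$x)]),
                rule = 2, ties = "ordered")$y
}

#' Per-interval line integrals along a segment
#'
#' Splits the segment `p0 -> p1` at the given sorted arc-length positions and
#' returns the exact line integral of each resulting interval. The intervals
#' are `[0, b1], [b1, b2], ..., [bk, L]`; with no breakpoints the single
#' interval equals [line_integral()]. Interval values sum exactly to the full
#' integral (telescoping cumulative sums).
#'
#' @inheritParams line_integral
#' @param breakpoints Sorted numeric vector of arc-length positions in
#'   `[0, |p1 - p0|]` (mm from `p0`).
#' @return Numeric vector of length `length(breakpoints) + 1`.
#' @export
partial_integrals <- function(volume, p0, p1, breakpoints = numeric(0)) {
  tr <- ray_trace(volume, p0, p1)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints)) stop("breakpoints must be sorted")
    if (min(breakpoints) < 0 || max(breakpoints) > tr$length + 1e-9)
      stop("breakpoints must lie within [0, segment length]")
  }
  kn <- cum_integral_knots(volume, tr)
  diff(eval_cum_integral(kn, c(0, breakpoints, tr$length)))
}
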