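#' Geometric size grid for the breakage population balance
#'
#' Discrete particle-size grid with strictly decreasing bin edges: index 1 is
#' the coarsest interval, matching the population balance convention in which
#' interval i receives fragments from all coarser intervals j < i. The
#' representative size of a bin is the geometric mean of its edges.
#'
#' @param x_min,x_max Smallest and largest edge, m. Defaults span
#'   0.05-5 micrometres, covering a nanomilling run that reduces a 1.5 um
#'   feed by roughly one order of magnitude.
#' @param n_bins Number of size intervals (>= 3).
#' @param edges Optional explicit edges (strictly decreasing, length
#'   `n_bins + 1`); overrides `x_min`/`x_max`.
#' @return An object of class `size_grid` with fields `edges` (descending,
#'   length n+1), `x` (representative sizes, m) and `n`.
#' @examples
#' g <- size_grid()
#' g$n
#' @export
size_grid <- function(x_min = 0.05e-6, x_max = 5e-6, n_bins = 20, edges = NULL) {
  if (is.null(edges)) {
    stopifnot(x_min > 0, x_max > x_min)
    edges <- exp(seq(log(x_max), log(x_min), length.out = n_bins + 1))
  }
  if (length(edges) < 4) stop("a size grid needs at least 3 bins")
  if (any(diff(edges) >= 0)) stop("edges must be strictly decreasing")
  n <- length(edges) - 1L
  structure(list(edges = edges, x = sqrt(edges[-1] * edges[-(n + 1)]), n = n),
            class = "size_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat("size_grid:", x$n, "geometric bins,",
      format(x$edges[x$n + 1] * 1e6), "-", format(x$edges[1] * 1e6), "um\n")
  invisible(x)
}

#' Particle size distribution on a size grid
#'
#' Mass fractions per size interval; the state vector of the batch grinding
#' balance. Fractions must be non-negative and sum to one.
#'
#' @param grid A [size_grid].
#' @param w Mass fractions, length `grid$n`, non-negative, summing to 1
#'   within 1e-10.
#' @return An object of class `psd`.
#' @export
psd <- function(grid, w) {
  stopifnot(inherits(grid, "size_grid"))
  if (length(w) != grid$n) stop("w must have one entry per bin")
  if (any(w < 0)) stop("mass fractions must be non-negative")
  if (abs(sum(w) - 1) > 1e-10) stop("mass fractions must sum to 1 (within 1e-10)")
  structure(list(grid = grid, w = as.numeric(w)), class = "psd")
}

#' Lognormal particle size distribution
#'
#' Discretizes a lognormal mass distribution onto a size grid by edge
#' differences of its cumulative law, then renormalizes the (small) mass
#' falling outside the grid span back onto the grid.
#'
#' @param grid A [size_grid].
#' @param median Mass-median size, m.
#' @param gsd Geometric standard deviation (> 1).
#' @return A [psd].
#' @export
psd_lognormal <- function(grid, median = 1.5e-6, gsd = 1.5) {
  stopifnot(median > 0, gsd > 1)
  cdf <- stats::plnorm(grid$edges, meanlog = log(median), sdlog = log(gsd))
  w <- cdf[-(grid$n + 1)] - cdf[-1]   # edges descending: undersize differences
  psd(grid, w / sum(w))
}

#' @export
print.psd <- function(x, ...) {
  cat("psd on", x$grid$n, "bins; D50 =", format(d50(x)), "um\n")
  invisible(x)
}

#' Median particle size D50
#'
#' Size at which the cumulative mass-undersize distribution equals 0.5,
#' obtained by linear interpolation in log-size on the cumulative-undersize
#' curve evaluated at the bin edges. All mass in a single bin therefore
#' yields that bin's representative (geometric-mean) size.
#'
#' @param x A [psd] or an object with one (e.g. a row of a trajectory).
#' @param ... Unused.
#' @return Median size in micrometres.
#' @export
d50 <- function(x, ...) UseMethod("d50")

#' @export
d50.psd <- function(x, ...) d50_from_w(x$w, x$grid)

# undersize at edge k = mass of bins k..n (bins k..n are all finer than edge k)
d50_from_w <- function(w, grid) {
  if (length(w) == 0 || sum(w) <= 0) stop("empty particle size distribution")
  n <- grid$n
  und <- c(rev(cumsum(rev(w))), 0) / sum(w)
  k <- which(und < 0.5)[1]
  if (is.na(k)) return(grid$edges[n + 1] * 1e6)
  if (k == 1L) return(grid$edges[1] * 1e6)
  u1 <- und[k - 1]; u2 <- und[k]
  lx <- log(grid$edges[k - 1]) +
    (0.5 - u1) / (u2 - u1) * (log(grid$edges[k]) - log(grid$edges[k - 1]))
  exp(lx) * 1e6
}
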