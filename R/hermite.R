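## Cubic Hermite splines with analytic integration.
##
## This is the numerical core of the linkage method: titration curves are
## interpolated by piecewise cubics that pass through the sampled mean
## protonations AND carry the thermodynamic slopes -ln10*var(n) (or
## -ln10*cov(n_i,n)) at the knots, so the interpolant honours both the
## observed means and the exact local derivatives. The integral of each
## piece is closed-form, so linkage free energies require no quadrature.

#' Build a cubic Hermite spline
#'
#' Piecewise cubic interpolant matching prescribed values and first
#' derivatives at strictly increasing knots; C1-continuous by construction.
#' No monotonicity filtering is applied: the supplied slopes are physical
#' and any overshoot between knots is reported as-is.
#'
#' @param knots Strictly increasing numeric vector (>= 2 knots), e.g. the
#'   sampled pH values.
#' @param values Function values at the knots.
#' @param slopes First derivatives at the knots.
#' @return Object of class \code{hermite_spline}.
#' @export
hermite_spline <- function(knots, values, slopes) {
  knots <- as.numeric(knots); values <- as.numeric(values)
  slopes <- as.numeric(slopes)
  if (length(knots) < 2) stop("at least 2 knots required")
  if (length(values) != length(knots) || length(slopes) != length(knots))
    stop("knots, values and slopes must have equal length")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = knots, values = values, slopes = slopes),
            class = "hermite_spline")
}

#' @export
print.hermite_spline <- function(x, ...) {
  cat(sprintf("hermite_spline: %d knots on [%g, %g]\n",
              length(x$knots), x$knots[1], x$knots[length(x$knots)]))
  invisible(x)
}

## Locate the interval index for each x (clamped to the knot range).
interval_index <- function(s, x) {
  pmin(pmax(findInterval(x, s$knots, rightmost.closed = TRUE), 1L),
       length(s$knots) - 1L)
}

#' Evaluate a Hermite spline
#'
#' @param s A \code{hermite_spline}.
#' @param x Points inside the knot range (extrapolation refused).
#' @return Spline values at \code{x}.
#' @export
eval_spline <- function(s, x) {
  rng <- range(s$knots)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9))
    stop("evaluation outside the knot range [", rng[1], ", ", rng[2], "]")
  k <- interval_index(s, x)
  h <- s$knots[k + 1L] - s$knots[k]
  t <- (x - s$knots[k]) / h
  t2 <- t * t; t3 <- t2 * t
  h00 <- 2 * t3 - 3 * t2 + 1
  h10 <- t3 - 2 * t2 + t
  h01 <- -2 * t3 + 3 * t2
  h11 <- t3 - t2
  h00 * s$values[k] + h10 * h * s$slopes[k] +
    h01 * s$values[k + 1L] + h11 * h * s$slopes[k + 1L]
}

#' Evaluate the derivative of a Hermite spline
#'
#' @param s A \code{hermite_spline}.
#' @param x Points inside the knot range.
#' @return First-derivative values at \code{x}.
#' @export
eval_spline_deriv <- function(s, x) {
  rng <- range(s$knots)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9))
    stop("evaluation outside the knot range")
  k <- interval_index(s, x)
  h <- s$knots[k + 1L] - s$knots[k]
  t <- (x - s$knots[k]) / h
  t2 <- t * t
  d00 <- (6 * t2 - 6 * t) / h
  d10 <- 3 * t2 - 4 * t + 1
  d01 <- (-6 * t2 + 6 * t) / h
  d11 <- 3 * t2 - 2 * t
  d00 * s$values[k] + d10 * s$slopes[k] +
    d01 * s$values[k + 1L] + d11 * s$slopes[k + 1L]
}

## Antiderivatives of the Hermite basis on [0, t] (unit interval):
##   H00 = t^4/2 - t^3 + t        H10 = t^4/4 - 2 t^3/3 + t^2/2
##   H01 = -t^4/2 + t^3           H11 = t^4/4 - t^3/3
## so that \int_0^1 h00 = 1/2, h10 = 1/12, h01 = 1/2, h11 = -1/12.
hermite_partial_integral <- function(s, k, t) {
  h <- s$knots[k + 1L] - s$knots[k]
  t2 <- t * t; t3 <- t2 * t; t4 <- t3 * t
  H00 <- t4 / 2 - t3 + t
  H10 <- t4 / 4 - 2 * t3 / 3 + t2 / 2
  H01 <- -t4 / 2 + t3
  H11 <- t4 / 4 - t3 / 3
  h * (H00 * s$values[k] + H10 * h * s$slopes[k] +
         H01 * s$values[k + 1L] + H11 * h * s$slopes[k + 1L])
}

#' Analytic integral of a Hermite spline
#'
#' Closed-form piecewise-polynomial integral \eqn{\int_a^b s(x)\,dx}; exact
#' up to floating round-off and additive over subintervals. Limits must lie
#' inside the knot range (no extrapolation).
#'
#' @param s A \code{hermite_spline}.
#' @param a,b Integration limits (either order; \code{a > b} negates).
#' @return The integral value.
#' @export
integrate_spline <- function(s, a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (a > b) return(-integrate_spline(s, b, a))
  rng <- range(s$knots)
  if (a < rng[1] - 1e-9 || b > rng[2] + 1e-9)
    stop("integration limits outside the knot range")
  a <- max(a, rng[1]); b <- min(b, rng[2])
  ia <- interval_index(s, a); ib <- interval_index(s, b)
  cum <- function(x) {           # integral from knots[1] to x
    k <- interval_index(s, x)
    full <- if (k > 1L)
      sum(vapply(seq_len(k - 1L), function(j)
        hermite_partial_integral(s, j, 1), numeric(1))) else 0
    t <- (x - s$knots[k]) / (s$knots[k + 1L] - s$knots[k])
    full + hermite_partial_integral(s, k, t)
  }
  cum(b) - cum(a)
}

#' Cumulative integral of a Hermite spline on a grid
#'
#' \eqn{F(x) = \int_{x_0}^{x} s\,dx'} evaluated at every grid point, with
#' the same closed-form per-piece antiderivative as
#' \code{\link{integrate_spline}} (vectorized for dense output grids).
#'
#' @param s A \code{hermite_spline}.
#' @param grid Increasing numeric vector inside the knot range.
#' @param x0 Lower reference limit (default first grid point).
#' @return Numeric vector of cumulative integrals at \code{grid}.
#' @export
cumulative_spline_integral <- function(s, grid, x0 = grid[1]) {
  rng <- range(s$knots)
  if (any(grid < rng[1] - 1e-9 | grid > rng[2] + 1e-9) ||
      x0 < rng[1] - 1e-9 || x0 > rng[2] + 1e-9)
    stop("grid outside the knot range")
  nseg <- length(s$knots) - 1L
  seg_full <- vapply(seq_len(nseg), function(j)
    hermite_partial_integral(s, j, 1), numeric(1))
  cum_knot <- c(0, cumsum(seg_full))       # integral from knot 1 to knot k
  k <- interval_index(s, grid)
  t <- (grid - s$knots[k]) / (s$knots[k + 1L] - s$knots[k])
  t2 <- t * t; t3 <- t2 * t; t4 <- t3 * t
  h <- s$knots[k + 1L] - s$knots[k]
  part <- h * ((t4 / 2 - t3 + t) * s$values[k] +
                 (t4 / 4 - 2 * t3 / 3 + t2 / 2) * h * s$slopes[k] +
                 (-t4 / 2 + t3) * s$values[k + 1L] +
                 (t4 / 4 - t3 / 3) * h * s$slopes[k + 1L])
  Fg <- cum_knot[k] + part
  k0 <- interval_index(s, x0)
  t0 <- (x0 - s$knots[k0]) / (s$knots[k0 + 1L] - s$knots[k0])
  F0 <- cum_knot[k0] + hermite_partial_integral(s, k0, t0)
  Fg - F0
}
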