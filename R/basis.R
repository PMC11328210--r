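#' Finite-difference weights on an arbitrary grid (Fornberg)
#'
#' Weights of the interpolating-polynomial approximation to the m-th
#' derivative at `x0` from samples at `x`.  Exact for polynomials up to
#' degree length(x) - 1, hence 4th-order accurate for the 5-point
#' centered stencils used by [derivative_basis()] on uniform grids, and
#' valid for non-uniform monotone grids.
#'
#' @param x0 evaluation point.
#' @param x stencil nodes (distinct).
#' @param m derivative order (0 <= m < length(x)).
#' @return Numeric weight vector w such that sum(w * f(x)) ~ f^(m)(x0).
#' @keywords internal
fd_weights <- function(x0, x, m) {
  n <- length(x)
  if (m >= n) stop("stencil too short for requested derivative order")
  # B. Fornberg's recursion, Math. Comp. 51 (1988)
  c1 <- 1
  c4 <- x[1] - x0
  C <- matrix(0, n, m + 1)
  C[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        if (mn >= 1) for (k in mn:1)
          C[i, k + 1] <- c1 * (k * C[i - 1, k] - c5 * C[i - 1, k + 1]) / c2
        C[i, 1] <- -c1 * c5 * C[i - 1, 1] / c2
      }
      if (mn >= 1) for (k in mn:1)
        C[j, k + 1] <- (c4 * C[j, k + 1] - k * C[j, k]) / c3
      C[j, 1] <- c4 * C[j, 1] / c3
    }
    c1 <- c2
  }
  C[, m + 1]
}

grid_derivative <- function(x, y, order, stencil = 5L) {
  n <- length(x)
  if (n < stencil) stop("grid too short for derivative estimation")
  out <- numeric(n)
  half <- (stencil - 1L) %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - stencil + 1L))
    idx <- lo:(lo + stencil - 1L)
    out[i] <- sum(fd_weights(x[i], x[idx], order) * y[idx])
  }
  out
}

#' Liptay derivative basis of an absorption spectrum
#'
#' Computes the three line-shape components onto which a field-induced
#' difference spectrum is decomposed in the Stark analysis of an
#' isotropic immobilized sample:
#' \deqn{b_0 = A(\nu), \quad
#'       b_1 = \nu \frac{d}{d\nu}\left[\frac{A(\nu)}{\nu}\right], \quad
#'       b_2 = \nu \frac{d^2}{d\nu^2}\left[\frac{A(\nu)}{\nu}\right].}
#' The zeroth component carries transition-moment (hyper)polarizability
#' effects, the first component polarizability changes, and the second
#' component the dominant dipole-moment-change (broadening) contribution.
#'
#' Derivatives are estimated on the native grid with 5-point
#' finite-difference stencils (centered in the interior, shifted at the
#' edges), which avoids resampling artifacts and converges at 4th order
#' on uniform grids.
#'
#' @param s a `stark_spectrum` with at least 5 points.
#' @return An object of class `derivative_basis`: list with `grid`,
#'   `b0` (a.u.), `b1` (a.u. cm), `b2` (a.u. cm^2).
#' @examples
#' s <- synth_band(band_model(1731, 24), seq(1650, 1810, by = 0.5))
#' db <- derivative_basis(s)
#' db$b2[s$wavenumber == 1731] < 0  # negative curvature at the maximum
#' @export
derivative_basis <- function(s) {
  nu <- s$wavenumber
  if (length(nu) < 5)
    stop("grid too short for second-derivative estimation (need >= 5 points)")
  red <- s$absorbance / nu
  structure(
    list(grid = nu,
         b0 = s$absorbance,
         b1 = nu * grid_derivative(nu, red, 1L),
         b2 = nu * grid_derivative(nu, red, 2L)),
    class = "derivative_basis")
}

# Numerical rank test of the basis after nondimensionalizing b1, b2
# with powers of the grid step (putting all columns in b0's units); a
# reference linear in nu, for instance, yields b1 = b2 = 0 up to
# round-off and must be rejected before least squares.
basis_degenerate <- function(db, tol = 1e-8) {
  h <- median(diff(db$grid))
  Xs <- cbind(db$b0, db$b1 * h, db$b2 * h^2)
  dsv <- svd(Xs, nu = 0, nv = 0)$d
  !all(is.finite(dsv)) || dsv[3] < tol * dsv[1]
}

#' @export
print.derivative_basis <- function(x, ...) {
  cat(sprintf("<derivative_basis> %d points, %.1f-%.1f cm-1\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}
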