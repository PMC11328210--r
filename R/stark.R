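#' Parallel-plate estimate of the static field in the nanogap
#'
#' For a flat tip wider than the film thickness the tip-substrate gap is
#' well approximated by a parallel-plate capacitor, so the nominal
#' static field is simply bias over thickness.
#'
#' @param bias applied voltage, V.
#' @param thickness film (gap) thickness, nm.
#' @return Field in V/nm (1 V/nm = 10 MV/cm).
#' @examples
#' parallel_plate_field(16.5, 55)  # 0.3 V/nm
#' parallel_plate_field(3, 10)     # 0.3 V/nm
#' @export
parallel_plate_field <- function(bias, thickness) {
  if (any(thickness <= 0)) stop("thickness must be > 0")
  bias / thickness
}

#' Static-field model for one bias point
#'
#' Couples the applied bias to the film thickness via the parallel-plate
#' model and carries the local field correction factor f, the
#' dimensionless multiplier relating the nominal field V/d to the actual
#' field in the probed volume.  Flat tips give f between 1 and 2; sharp
#' tips concentrate the field and can exceed that range, which is
#' allowed with a warning.
#'
#' @param bias applied voltage, V.
#' @param thickness nm (> 0).
#' @param f local field correction factor (>= 1 nominally).
#' @return An object of class `field_model` with fields `bias`,
#'   `thickness`, `f`, `F_stat` (V/nm).
#' @export
field_model <- function(bias, thickness, f = 1) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (f < 1 || f > 2)
    warning("local field factor outside the nominal [1, 2] flat-tip range",
            " (sharp-tip regime)")
  structure(list(bias = bias, thickness = thickness, f = f,
                 F_stat = parallel_plate_field(bias, thickness)),
            class = "field_model")
}

# Geometric factor of the isotropic-immobilized Liptay second-derivative
# coefficient; chi is the angle between the static and IR fields, zeta
# the angle between the dipole-moment change and the transition moment.
liptay_g <- function(chi, zeta) {
  if (chi < 0 || chi > 90 || zeta < 0 || zeta > 90)
    stop("angles must lie in [0, 90] degrees")
  cc <- cos(chi * pi / 180)^2
  cz <- cos(zeta * pi / 180)^2
  5 + (3 * cz - 1) * (3 * cc - 1)
}

# Stark shift scale dmu * F_eff / (h c) in cm^-1, evaluated in either
# unit system.  dmu in Debye, field in V/nm (before the local-field
# factor f).  The SI and cgs routes are algebraically identical because
# the Debye constant is defined through the esu system in both.
stark_shift_scale <- function(delta_mu, F_vnm, f = 1,
                              units = c("si", "cgs")) {
  units <- match.arg(units)
  k <- stark_constants
  if (units == "si") {
    (delta_mu * k$debye_si) * (f * F_vnm * 1e9) / (k$h_si * k$c_si) / 100
  } else {
    F_statvolt_cm <- f * F_vnm * 1e9 / k$statvolt_si / 100
    (delta_mu * k$debye_cgs) * F_statvolt_cm / (k$h_cgs * k$c_cgs)
  }
}

# Second-derivative coefficient c2 (cm^-2 units, multiplies b2) expected
# for dmu (Debye) at field F_vnm with local-field factor f.
vse_c2 <- function(delta_mu, F_vnm, f = 1, chi = 0, zeta = 0,
                   units = "si") {
  liptay_g(chi, zeta) / 30 * stark_shift_scale(delta_mu, F_vnm, f, units)^2
}

#' Forward vibrational-Stark difference spectrum (Liptay model)
#'
#' Evaluates the field-induced absorbance change of an isotropic
#' immobilized sample in the Liptay derivative basis of the zero-field
#' band A(nu):
#' \deqn{\Delta A(\nu) = (f F_{stat})^2 \left[ a\, b_0 + b\, b_1 +
#'   C_\chi\, b_2 \right], \qquad
#'   C_\chi = \frac{\Delta\mu^2}{30\,h^2 c^2}
#'   \left[5 + (3\cos^2\zeta - 1)(3\cos^2\chi - 1)\right],}
#' with \eqn{b_0 = A}, \eqn{b_1 = \nu\, d(A/\nu)/d\nu},
#' \eqn{b_2 = \nu\, d^2(A/\nu)/d\nu^2}.  The zeroth term carries
#' transition-moment effects, the first polarizability changes (both
#' typically negligible here and zero by default), and the second the
#' dominant dipole-moment-change broadening, quadratic in both the field
#' and the dipole change.
#'
#' Unit bookkeeping: with `delta_mu` in Debye and the field in V/nm, the
#' quantity \eqn{\Delta\mu\, f F_{stat} / (hc)} is a wavenumber (cm^-1),
#' so \eqn{C_\chi (f F_{stat})^2} is in cm^-2 and multiplies `b2`
#' (a.u. cm^2) to give an absorbance.  The same expression can be
#' evaluated in SI or cgs-esu units (`units`); the two routes agree to
#' machine precision and serve as a cross-check of the constant handling.
#'
#' @param A zero-field `stark_spectrum`.
#' @param field a [field_model()].
#' @param delta_mu dipole-moment change, Debye (>= 0).
#' @param chi angle between the static and IR fields, degrees in
#'   [0, 90].
#' @param zeta angle between the dipole-moment change and the transition
#'   moment, degrees in [0, 90].
#' @param a_term,b_term coefficients of the zeroth/first derivative
#'   components, in a.u. (V/nm)^-2 and a.u. cm (V/nm)^-2 respectively;
#'   default 0.
#' @param units evaluation unit system, `"si"` (default) or `"cgs"`.
#' @return A `difference_spectrum` at the field's bias.
#' @examples
#' A <- synth_band(band_model(1731, 24), seq(1650, 1810, by = 0.5))
#' fm <- field_model(16.5, 55)
#' dA <- vse_forward(A, fm, delta_mu = 0.065)
#' max(abs(dA$delta))  # a few percent of the unit peak
#' @export
vse_forward <- function(A, field, delta_mu, chi = 0, zeta = 0,
                        a_term = 0, b_term = 0, units = c("si", "cgs")) {
  units <- match.arg(units)
  if (delta_mu < 0) stop("delta_mu must be >= 0")
  db <- derivative_basis(A)
  F2 <- (field$f * field$F_stat)^2
  c2 <- vse_c2(delta_mu, field$F_stat, field$f, chi, zeta, units)
  delta <- F2 * (a_term * db$b0 + b_term * db$b1) + c2 * db$b2
  difference_spectrum(db$grid, delta, bias = field$bias)
}

#' Fit a difference spectrum in the derivative basis
#'
#' Weighted linear least squares of the averaged difference onto the
#' three Liptay components \{b0, b1, b2\} of the zero-bias reference.
#' Weights default to 1/sem^2 where the per-point standard errors are
#' available and positive, and to 1 otherwise.  The coefficient
#' covariance follows the usual linear-model convention
#' (residual-variance scaled), so it stays calibrated even if the
#' supplied sem is off by a common factor.
#'
#' The reference enters through its second derivative, which amplifies
#' measurement noise as 1/step^2, attenuating the fitted coefficients
#' (errors in variables).  Pass the reference through
#' [smooth_spectrum()] with GCV before fitting whenever it carries
#' noise; [run_pipeline()] does this by default.
#'
#' @param dA a `difference_spectrum`.
#' @param A_ref the averaged zero-bias `stark_spectrum` on the same
#'   grid.
#' @param weights optional per-point weights overriding the default.
#' @return An object of class `vse_fit`: list with `bias`, `coeffs`
#'   (c0, c1, c2 multiplying b0, b1, b2), `covariance` (3x3),
#'   `residual_rms`, `fitted`, `basis`.
#' @export
fit_vse <- function(dA, A_ref, weights = NULL) {
  if (length(dA$grid) != length(A_ref$wavenumber) ||
      max(abs(dA$grid - A_ref$wavenumber)) > 1e-9 * max(dA$grid))
    stop("difference and reference must share one grid")
  db <- derivative_basis(A_ref)
  X <- cbind(b0 = db$b0, b1 = db$b1, b2 = db$b2)
  if (basis_degenerate(db))
    stop("rank-deficient derivative basis (degenerate reference spectrum)")
  if (is.null(weights)) {
    weights <- if (any(dA$sem > 0)) {
      w <- 1 / pmax(dA$sem, max(dA$sem) * 1e-6)^2
      w / mean(w)
    } else rep(1, length(dA$delta))
  }
  sw <- sqrt(weights)
  qr_w <- qr(sw * X)
  beta <- qr.coef(qr_w, sw * dA$delta)
  res <- dA$delta - drop(X %*% beta)
  n <- length(dA$delta)
  s2 <- sum(weights * res^2) / (n - 3L)
  XtWX_inv <- chol2inv(qr.R(qr_w))
  V <- s2 * XtWX_inv
  beta <- unname(beta)
  structure(
    list(bias = dA$bias, coeffs = setNames(beta, c("c0", "c1", "c2")),
         covariance = V, residual_rms = sqrt(mean(res^2)),
         fitted = drop(X %*% beta), basis = db),
    class = "vse_fit")
}

#' @export
print.vse_fit <- function(x, ...) {
  cat(sprintf(
    "<vse_fit> bias %g V: c0 = %.3g, c1 = %.3g, c2 = %.3g (rms %.2g)\n",
    x$bias, x$coeffs[1], x$coeffs[2], x$coeffs[3], x$residual_rms))
  invisible(x)
}

# slope of c2 vs F_stat^2 expected for a unit local-field factor
slope_expected <- function(delta_mu, chi = 0, zeta = 0, units = "si") {
  vse_c2(delta_mu, F_vnm = 1, f = 1, chi = chi, zeta = zeta, units = units)
}

#' Extract the dipole-moment change from per-bias fits
#'
#' First-order perturbation theory makes the dipole-moment change field
#' independent, so the second-derivative coefficient
#' \eqn{c_2 = C_\chi (f F_{stat})^2} must be linear in
#' \eqn{F_{stat}^2}.  This routine regresses c2 against F^2 through the
#' origin (the difference must vanish at zero field by construction),
#' converts the slope to \eqn{\Delta\mu} in Debye for the assumed f,
#' chi, zeta, and propagates a first-order (delta-method) confidence
#' interval from the per-fit coefficient variances.  A free-intercept
#' regression is reported alongside as a linearity diagnostic.
#'
#' A negative fitted slope (possible under noise) maps to
#' `delta_mu = 0` with `degenerate = TRUE` rather than an error.
#'
#' @param fits list of [fit_vse()] results, one per bias level.
#' @param fields list of [field_model()]s aligned with `fits`.
#' @param chi,zeta assumed angles, degrees (defaults 0: tip-axis fields,
#'   dipole change parallel to the transition moment, g = 9).
#' @param level confidence level for the interval.
#' @return An object of class `stark_result`: `delta_mu` (Debye),
#'   `delta_mu_ci`, `slope` (c2 per (V/nm)^2), `slope_se`,
#'   `linearity_r2`, `intercept_diag`, `assumed_f`, `chi`, `zeta`,
#'   `degenerate`, `table` (per-bias data frame), `debye_si`.
#' @export
extract_delta_mu <- function(fits, fields, chi = 0, zeta = 0,
                             level = 0.95) {
  if (length(fits) != length(fields))
    stop("fits and fields must be aligned")
  F2 <- vapply(fields, function(f) f$F_stat^2, numeric(1))
  if (length(unique(round(F2, 12))) < 2)
    stop("need at least two distinct bias levels")
  fvals <- vapply(fields, function(f) f$f, numeric(1))
  if (length(unique(fvals)) != 1)
    stop("all field models must share one local-field factor")
  f_assumed <- fvals[1]
  c2 <- vapply(fits, function(x) x$coeffs[["c2"]], numeric(1))
  v2 <- vapply(fits, function(x) x$covariance[3, 3], numeric(1))
  w <- if (all(v2 > 0)) 1 / v2 else rep(1, length(c2))
  # through-origin weighted regression of c2 on F^2
  slope <- sum(w * F2 * c2) / sum(w * F2^2)
  res <- c2 - slope * F2
  n <- length(c2)
  s2 <- if (n > 1) sum(w * res^2) / (n - 1) else 0
  slope_se <- sqrt(s2 / sum(w * F2^2))
  ss_tot <- sum(w * c2^2)       # uncentered: through-origin convention
  r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else NA_real_
  # free-intercept diagnostic
  fit_free <- lm(c2 ~ F2, weights = w)
  unit <- slope_expected(1, chi, zeta) * f_assumed^2  # slope for dmu = 1 D
  degenerate <- slope <= 0
  delta_mu <- if (degenerate) 0 else sqrt(slope / unit)
  z <- qnorm(1 - (1 - level) / 2)
  dmu_se <- if (degenerate || slope == 0) NA_real_ else
    delta_mu * slope_se / (2 * slope)
  ci <- if (is.na(dmu_se)) c(NA_real_, NA_real_) else
    c(max(0, delta_mu - z * dmu_se), delta_mu + z * dmu_se)
  structure(
    list(delta_mu = delta_mu, delta_mu_ci = ci, delta_mu_se = dmu_se,
         slope = slope, slope_se = slope_se, linearity_r2 = r2,
         intercept_diag = unname(coef(fit_free)),
         assumed_f = f_assumed, chi = chi, zeta = zeta,
         degenerate = degenerate,
         table = data.frame(
           bias = vapply(fields, `[[`, numeric(1), "bias"),
           F_stat = sqrt(F2), F2 = F2, c2 = c2, c2_se = sqrt(pmax(v2, 0))),
         debye_si = stark_constants$debye_si),
    class = "stark_result")
}

#' @export
print.stark_result <- function(x, ...) {
  cat(sprintf(
    "<stark_result> delta_mu = %.4g D [%.4g, %.4g] (f = %g, chi = %g, zeta = %g)\n  slope = %.4g per (V/nm)^2, linearity r^2 = %.4f%s\n",
    x$delta_mu, x$delta_mu_ci[1], x$delta_mu_ci[2],
    x$assumed_f, x$chi, x$zeta, x$slope, x$linearity_r2,
    if (x$degenerate) " [degenerate: nonpositive slope]" else ""))
  invisible(x)
}

#' Local-field factor from a calibration slope
#'
#' Once the dipole-moment change of a calibration sample is known, an
#' observed c2-vs-F^2 slope measures the actual field in the probed
#' volume: `f = sqrt(observed / expected at f = 1)`.  Sharp tips
#' concentrate the field and give f > 1.
#'
#' @param observed_slope fitted slope of c2 against F_stat^2 (>= 0).
#' @param reference_delta_mu known dipole-moment change, Debye (> 0).
#' @param chi,zeta assumed angles, degrees.
#' @return Estimated local-field factor (dimensionless).
#' @export
estimate_local_field_factor <- function(observed_slope, reference_delta_mu,
                                        chi = 0, zeta = 0) {
  if (reference_delta_mu <= 0) stop("reference delta_mu must be > 0")
  if (observed_slope < 0) stop("observed slope must be >= 0")
  sqrt(observed_slope / slope_expected(reference_delta_mu, chi, zeta))
}
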