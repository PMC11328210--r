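#' Construct a single absorption spectrum
#'
#' A `stark_spectrum` holds one absorption spectrum A(nu) on a strictly
#' increasing, strictly positive wavenumber grid, together with the
#' acquisition metadata used by the difference-spectroscopy protocol: the
#' applied bias (0 V marks the reference acquisitions) and the repeat
#' index within the interleaved schedule.
#'
#' Positivity of the wavenumber grid is enforced because the Liptay
#' derivative basis divides by nu.
#'
#' @param wavenumber numeric, strictly increasing wavenumbers in cm^-1,
#'   all > 0, length >= 8.
#' @param absorbance numeric, same length, finite; arbitrary units.
#' @param bias applied voltage in V (0 for the zero-bias reference).
#' @param repeat_index integer repeat-cycle index (>= 1).
#' @param label free-text label.
#' @return An object of class `stark_spectrum`.
#' @examples
#' s <- spectrum_new(seq(1500, 1800), dnorm(seq(1500, 1800), 1665, 17))
#' print(s)
#' @export
spectrum_new <- function(wavenumber, absorbance, bias = 0,
                         repeat_index = 1L, label = "") {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have equal length")
  if (length(wavenumber) < 8)
    stop("spectrum needs at least 8 points")
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance)))
    stop("spectrum values must all be finite")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing")
  if (wavenumber[1] <= 0)
    stop("wavenumber grid must be strictly positive")
  if (!is.numeric(bias) || length(bias) != 1 || !is.finite(bias))
    stop("bias must be a single finite number")
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         bias = as.numeric(bias), repeat_index = as.integer(repeat_index),
         label = as.character(label)),
    class = "stark_spectrum")
}

#' @export
print.stark_spectrum <- function(x, ...) {
  cat(sprintf(
    "<stark_spectrum> %d points, %.1f-%.1f cm-1, bias %g V, repeat %d%s\n",
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
    x$bias, x$repeat_index,
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.stark_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, absorbance = x$absorbance)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavenumber) == length(b$wavenumber) &&
    max(abs(a$wavenumber - b$wavenumber)) <= tol * max(abs(a$wavenumber))
}

#' Parameterize an infrared band
#'
#' Describes a single vibrational band by center, full width at half
#' maximum, peak amplitude and line shape.  Gaussian and Lorentzian
#' shapes are standard; the pseudo-Voigt (linear Gaussian/Lorentzian mix)
#' is included because measured photothermal bands are often
#' intermediate.
#'
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param amplitude peak height, arbitrary units (>= 0).
#' @param shape one of "gaussian", "lorentzian", "pseudo_voigt".
#' @param eta pseudo-Voigt Lorentzian fraction in [0, 1] (ignored for the
#'   pure shapes).
#' @return An object of class `band_model`.
#' @export
band_model <- function(center, fwhm, amplitude = 1,
                       shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                       eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (eta < 0 || eta > 1) stop("pseudo-Voigt mixing fraction must be in [0, 1]")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape, eta = eta),
            class = "band_model")
}

band_profile <- function(model, nu) {
  g <- exp(-4 * log(2) * ((nu - model$center) / model$fwhm)^2)
  l <- 1 / (1 + (2 * (nu - model$center) / model$fwhm)^2)
  switch(model$shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = (1 - model$eta) * g + model$eta * l)
}

#' Evaluate a band model on a wavenumber grid
#'
#' The returned spectrum peaks at `amplitude` when the band center lies
#' on the grid.
#'
#' @param model a [band_model()].
#' @param grid strictly increasing, positive wavenumbers (cm^-1).
#' @inheritParams spectrum_new
#' @return A `stark_spectrum`.
#' @examples
#' b <- band_model(1731, 24)
#' s <- synth_band(b, seq(1650, 1810, by = 0.5))
#' max(s$absorbance)  # 1 at 1731
#' @export
synth_band <- function(model, grid, bias = 0, repeat_index = 1L,
                       label = model$shape) {
  if (length(grid) == 0) stop("empty grid")
  if (any(grid <= 0)) stop("grid must be strictly positive")
  spectrum_new(grid, model$amplitude * band_profile(model, grid),
               bias = bias, repeat_index = repeat_index, label = label)
}

#' Shift a spectrum along the wavenumber axis
#'
#' Returns the spectrum displaced by `shift` cm^-1 on its own grid,
#' i.e. A(nu - shift), using linear interpolation with flat
#' extrapolation at the ends.  Used by the reorientation generator and
#' by the matched-centroid shift estimator.
#'
#' @param s a `stark_spectrum`.
#' @param shift displacement in cm^-1 (positive moves the band up).
#' @return A `stark_spectrum` on the same grid.
#' @export
shift_spectrum <- function(s, shift) {
  y <- approx(s$wavenumber + shift, s$absorbance, xout = s$wavenumber,
              rule = 2)$y
  spectrum_new(s$wavenumber, y, bias = s$bias,
               repeat_index = s$repeat_index, label = s$label)
}
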