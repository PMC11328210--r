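#' Smoothing-spline denoising of a spectrum
#'
#' Cubic smoothing spline evaluated back on the native grid, as is
#' routinely applied to photothermal difference spectra before display
#' and fitting.  `smoothing = 0` returns the input unchanged;
#' `smoothing = "auto"` selects the penalty by generalized
#' cross-validation (GCV); a positive number is passed through as the
#' `lambda` penalty of [stats::smooth.spline()] (larger = smoother).
#'
#' @param s a `stark_spectrum`.
#' @param smoothing nonnegative penalty, or `"auto"` for GCV.
#' @return A smoothed `stark_spectrum` on the same grid.
#' @examples
#' set.seed(1)
#' s <- synth_band(band_model(1731, 24), seq(1650, 1810, by = 0.5))
#' noisy <- spectrum_new(s$wavenumber, s$absorbance + rnorm(321, 0, 0.01))
#' sm <- smooth_spectrum(noisy, "auto")
#' @export
smooth_spectrum <- function(s, smoothing = "auto") {
  if (identical(smoothing, "auto")) {
    fit <- smooth.spline(s$wavenumber, s$absorbance, cv = FALSE)
  } else {
    if (!is.numeric(smoothing) || length(smoothing) != 1 || smoothing < 0)
      stop("smoothing must be a nonnegative number or \"auto\"")
    if (smoothing == 0) return(s)
    fit <- smooth.spline(s$wavenumber, s$absorbance, lambda = smoothing)
  }
  y <- predict(fit, s$wavenumber)$y
  spectrum_new(s$wavenumber, y, bias = s$bias,
               repeat_index = s$repeat_index, label = s$label)
}

#' Smooth the averaged difference of a series
#'
#' Applies [smooth_spectrum()] to the delta trace of a
#' `difference_spectrum`, leaving the per-point standard errors
#' untouched (they describe the raw average).
#'
#' @param d a `difference_spectrum`.
#' @inheritParams smooth_spectrum
#' @return A `difference_spectrum`.
#' @export
smooth_difference <- function(d, smoothing = "auto") {
  s <- spectrum_new(d$grid, d$delta, bias = d$bias)
  sm <- smooth_spectrum(s, smoothing)
  difference_spectrum(d$grid, sm$absorbance, d$bias,
                      n_repeats = d$n_repeats, sem = d$sem)
}
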