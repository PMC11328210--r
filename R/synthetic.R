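# Run expr with a private RNG stream; the caller's .Random.seed is
# untouched, so generators are pure functions of (preset, n_repeats, seed).
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configure the effects injected by the synthetic-data generators
#'
#' Bundles the physical effects the generators can imprint on an
#' acquisition series, each parameterized as in the analysis it is meant
#' to exercise:
#' \describe{
#'   \item{vse}{`delta_mu` (Debye), `f` (local-field factor), `chi`,
#'     `zeta` (degrees) -- quadratic-in-field Stark broadening.}
#'   \item{reorientation}{`shift_per_bias` (cm^-1/V) -- rigid band shift
#'     linear in bias, producing a first-derivative difference shape.}
#'   \item{orientation}{`theta0` (deg, angle between the net transition
#'     dipole and the IR field) and `dtheta_per_bias` (deg/V) -- cos^2
#'     selection-rule amplitude response of the amide-I band.}
#'   \item{protonation}{`marker_center`, `marker_fwhm` (cm^-1),
#'     `amplitude_per_bias` (a.u./V), `active_polarity` (+1 or -1) --
#'     carboxyl protonation marker added at one polarity only.}
#'   \item{noise}{`sigma` (a.u. white noise per point),
#'     `drift_amplitude` (a.u. bound on a smooth quadratic baseline
#'     wander per acquisition), `seed`.}
#' }
#'
#' @param vse,reorientation,orientation,protonation,noise named lists
#'   overriding the defaults above (all effects default to zero
#'   amplitude; noise defaults to sigma 0.005, drift 0.002, seed 1).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(vse = list(), reorientation = list(),
                          orientation = list(), protonation = list(),
                          noise = list()) {
  cfg <- list(
    vse = modifyList(list(delta_mu = 0, f = 1, chi = 0, zeta = 0), vse),
    reorientation = modifyList(list(shift_per_bias = 0), reorientation),
    orientation = modifyList(list(theta0 = 0, dtheta_per_bias = 0,
                                  mechanism_polarity = 1), orientation),
    protonation = modifyList(list(marker_center = 1760, marker_fwhm = 12,
                                  amplitude_per_bias = 0,
                                  active_polarity = -1), protonation),
    noise = modifyList(list(sigma = 0.005, drift_amplitude = 0.002,
                            seed = 1L), noise))
  stopifnot(cfg$vse$delta_mu >= 0, cfg$vse$f >= 1,
            cfg$orientation$theta0 >= 0, cfg$orientation$theta0 <= 90,
            cfg$noise$sigma >= 0, cfg$noise$drift_amplitude >= 0)
  if ((cfg$noise$sigma > 0 || cfg$noise$drift_amplitude > 0) &&
      is.null(cfg$noise$seed))
    stop("a seed is required whenever noise or drift is nonzero")
  structure(cfg, class = "effect_config")
}

#' Sample presets shipped with the package
#'
#' Three ready-made synthetic samples emulating the study conditions of
#' the field-modulated nanospectroscopy experiments:
#' \describe{
#'   \item{pmma55}{55 nm PMMA film, C=O stretching band (Gaussian,
#'     center 1731 cm^-1, fwhm 24 cm^-1 -- conventional values for the
#'     PMMA carbonyl, configurable), bias ladder 6/9/12/16.5 V, pure VSE
#'     response with delta_mu = 6.5e-2 D, f = 1.}
#'   \item{pmma23}{23 nm PMMA film, same band, reorientation response
#'     (0.06 cm^-1/V band shift) instead of VSE: thin films with chain
#'     end-to-end distance comparable to the thickness gain orientational
#'     freedom and respond by shifting, not broadening.}
#'   \item{br10}{10 nm stack of two purple membranes, bacteriorhodopsin
#'     amide-I band (Gaussian, center 1665 cm^-1, fwhm 45 cm^-1),
#'     bias +/-3 V, with polarity-asymmetric effects: cos^2 orientation
#'     amplitude response at positive bias (theta0 = 38 deg, +1 deg per
#'     3 V), apparent band shift at negative bias (9 cm^-1 at -3 V), and
#'     a 1760 cm^-1 protonation marker at the negative polarity.}
#' }
#'
#' @param name one of `"pmma55"`, `"pmma23"`, `"br10"`.
#' @param ... fields overriding the preset (`band`, `grid`, `thickness`,
#'   `bias_levels`, `effects`).
#' @return An object of class `sample_preset` with fields `name`,
#'   `band` ([band_model()]), `grid`, `thickness` (nm), `bias_levels`
#'   (V), `effects` ([effect_config()]).
#' @examples
#' p <- sample_preset("pmma55")
#' p$effects$vse$delta_mu
#' @export
sample_preset <- function(name = c("pmma55", "pmma23", "br10"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    pmma55 = list(
      name = "pmma55",
      band = band_model(1731, 24, 1, "gaussian"),
      grid = seq(1650, 1810, by = 0.5),
      thickness = 55,
      bias_levels = c(6, 9, 12, 16.5),
      effects = effect_config(vse = list(delta_mu = 0.065))),
    pmma23 = list(
      name = "pmma23",
      band = band_model(1731, 24, 1, "gaussian"),
      grid = seq(1650, 1810, by = 0.5),
      thickness = 23,
      bias_levels = c(6, 9, 12, 16.5),
      effects = effect_config(reorientation = list(shift_per_bias = 0.06))),
    br10 = list(
      name = "br10",
      band = band_model(1665, 45, 1, "gaussian"),
      grid = seq(1450, 1850, by = 1),
      thickness = 10,
      bias_levels = 3,
      effects = effect_config(
        orientation = list(theta0 = 38, dtheta_per_bias = 1 / 3,
                           mechanism_polarity = 1),
        reorientation = list(shift_per_bias = -3),
        protonation = list(amplitude_per_bias = 0.01,
                           active_polarity = -1))))
  out <- modifyList(base, list(...))
  if (out$thickness <= 0) stop("thickness must be > 0")
  structure(out, class = "sample_preset")
}

#' @export
print.sample_preset <- function(x, ...) {
  cat(sprintf(
    "<sample_preset> %s: %s band at %g cm-1 (fwhm %g), d = %g nm, bias %s V\n",
    x$name, x$band$shape, x$band$center, x$band$fwhm, x$thickness,
    paste(x$bias_levels, collapse = "/")))
  invisible(x)
}

# white noise plus a bounded smooth quadratic baseline wander
noise_trace <- function(grid, sigma, drift_amplitude) {
  t <- if (length(grid) > 1)
    2 * (grid - min(grid)) / diff(range(grid)) - 1 else 0
  coefs <- runif(3, -1, 1)
  drift <- drift_amplitude * (coefs[1] + coefs[2] * t + coefs[3] * t^2) / 3
  rnorm(length(grid), 0, sigma) + drift
}

fill_series <- function(preset, n_repeats, seed, at_bias_fun) {
  sk <- build_schedule(preset$bias_levels, n_repeats)
  nz <- preset$effects$noise
  A0 <- synth_band(preset$band, preset$grid, label = preset$name)
  with_private_seed(seed, {
    entries <- vector("list", nrow(sk$schedule))
    for (i in seq_len(nrow(sk$schedule))) {
      v <- sk$schedule$bias[i]
      clean <- if (v == 0) A0 else at_bias_fun(A0, v)
      entries[[i]] <- spectrum_new(
        preset$grid,
        clean$absorbance + noise_trace(preset$grid, nz$sigma,
                                       nz$drift_amplitude),
        bias = v, repeat_index = sk$schedule$repeat_index[i],
        label = preset$name)
    }
    acquisition_series(entries, sk$schedule)
  })
}

#' Synthetic PMMA acquisition series with a pure VSE response
#'
#' Zero-bias entries are the preset band plus noise; at-bias entries
#' additionally carry the forward Liptay difference evaluated at the
#' parallel-plate field `V/thickness` with the preset's delta_mu, f,
#' chi, zeta, so the noiseless at-bias minus zero-bias difference equals
#' [vse_forward()] output exactly.
#'
#' @param preset a [sample_preset()] with an active vse effect.
#' @param n_repeats repeats per bias level.
#' @param seed RNG seed (defaults to the preset's noise seed).
#' @return A filled `acquisition_series`.
#' @examples
#' s <- make_pmma_series(sample_preset("pmma55"), n_repeats = 3, seed = 7)
#' @export
make_pmma_series <- function(preset, n_repeats = 10L,
                             seed = preset$effects$noise$seed) {
  e <- preset$effects$vse
  if (e$delta_mu <= 0)
    stop("preset has no active VSE effect (delta_mu = 0)")
  fill_series(preset, n_repeats, seed, function(A0, v) {
    fm <- suppressWarnings(field_model(v, preset$thickness, e$f))
    dA <- vse_forward(A0, fm, e$delta_mu, e$chi, e$zeta)
    spectrum_new(A0$wavenumber, A0$absorbance + dA$delta, bias = v)
  })
}

#' Synthetic thin-film series with a reorientation (band-shift) response
#'
#' At-bias entries re-evaluate the band displaced by
#' `shift_per_bias * V`, so for small shifts the difference approximates
#' the first-derivative line shape `-s dA/dnu` that distinguishes
#' molecular reorientation from Stark broadening.
#'
#' @inheritParams make_pmma_series
#' @export
make_reorientation_series <- function(preset, n_repeats = 10L,
                                      seed = preset$effects$noise$seed) {
  s_per_v <- preset$effects$reorientation$shift_per_bias
  fill_series(preset, n_repeats, seed, function(A0, v) {
    b <- preset$band
    shifted <- band_model(b$center + s_per_v * v, b$fwhm, b$amplitude,
                          b$shape, b$eta)
    synth_band(shifted, preset$grid, bias = v)
  })
}

#' Synthetic bacteriorhodopsin series with polarity-asymmetric effects
#'
#' The generator imprints the phenomenology used to interpret amide-I
#' difference spectra of oriented membrane stacks, with the
#' polarity-to-mechanism mapping taken from the preset configuration
#' rather than hard-coded:
#' \itemize{
#'   \item at the amplitude-dominated polarity
#'     (`orientation$mechanism_polarity`), the amide-I amplitude is
#'     scaled by the cos^2 selection-rule response at
#'     `theta0 + dtheta_per_bias * |V|`;
#'   \item at the opposite polarity the band center is displaced by
#'     `reorientation$shift_per_bias * V`;
#'   \item the protonation marker band is added at the configured active
#'     polarity with amplitude `amplitude_per_bias * |V|`.
#' }
#' Polarity asymmetry of the difference spectra is therefore guaranteed
#' by construction whenever any effect is active.
#'
#' @inheritParams make_pmma_series
#' @param polarity +1 or -1; the sign applied to the preset's bias
#'   magnitudes.
#' @export
make_br_series <- function(preset, n_repeats = 10L, polarity = 1,
                           seed = preset$effects$noise$seed) {
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  eff <- preset$effects
  th0 <- eff$orientation$theta0
  dth <- eff$orientation$dtheta_per_bias
  if (th0 >= 90 && dth > 0)
    stop("theta0 >= 90 deg with positive dtheta is undefined")
  signed <- preset
  signed$bias_levels <- polarity * abs(preset$bias_levels)
  fill_series(signed, n_repeats, seed, function(A0, v) {
    b <- preset$band
    if (sign(v) == sign(eff$orientation$mechanism_polarity) && dth != 0) {
      theta1 <- th0 + dth * abs(v)
      scale <- cos(theta1 * pi / 180)^2 / cos(th0 * pi / 180)^2
      y <- A0$absorbance * scale
    } else {
      shifted <- band_model(b$center +
                              eff$reorientation$shift_per_bias * v,
                            b$fwhm, b$amplitude, b$shape, b$eta)
      y <- synth_band(shifted, preset$grid)$absorbance
    }
    if (sign(v) == sign(eff$protonation$active_polarity) &&
        eff$protonation$amplitude_per_bias != 0) {
      marker <- band_model(eff$protonation$marker_center,
                           eff$protonation$marker_fwhm,
                           eff$protonation$amplitude_per_bias * abs(v))
      y <- y + synth_band(marker, preset$grid)$absorbance
    }
    spectrum_new(preset$grid, y, bias = v)
  })
}

#' Add seeded noise and baseline drift to a series
#'
#' White noise of standard deviation `sigma` plus an independent smooth
#' quadratic baseline wander bounded by `drift_amplitude`, per spectrum.
#' With both amplitudes zero the series is returned unchanged.
#'
#' @param series an `acquisition_series`.
#' @param sigma white-noise standard deviation, a.u.
#' @param drift_amplitude bound on the baseline wander, a.u.
#' @param seed RNG seed.
#' @return An `acquisition_series`.
#' @export
add_noise <- function(series, sigma, drift_amplitude = 0, seed = 1L) {
  if (sigma < 0 || drift_amplitude < 0)
    stop("sigma and drift_amplitude must be >= 0")
  if (sigma == 0 && drift_amplitude == 0) return(series)
  with_private_seed(seed, {
    entries <- lapply(series$entries, function(s) {
      spectrum_new(s$wavenumber,
                   s$absorbance + noise_trace(s$wavenumber, sigma,
                                              drift_amplitude),
                   bias = s$bias, repeat_index = s$repeat_index,
                   label = s$label)
    })
    acquisition_series(entries, series$schedule)
  })
}
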