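# Shared fixtures built in code.

quiet_preset <- function(name, ...) {
  p <- sample_preset(name, ...)
  p$effects$noise$sigma <- 0
  p$effects$noise$drift_amplitude <- 0
  p
}

# standard PMMA test band and grid
pmma_band <- function() band_model(1731, 24, 1, "gaussian")
pmma_grid <- function(step = 0.5) seq(1650, 1810, by = step)

# noiseless single-repeat differences + reference for a preset series
noiseless_analysis <- function(series) {
  out <- series_differences(series)
  list(diffs = out$differences, ref = out$reference)
}

# closed-form Gaussian area for a band_model
gaussian_area <- function(model) {
  model$amplitude * model$fwhm * sqrt(pi / (4 * log(2)))
}
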