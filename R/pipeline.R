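#' Assemble a pipeline run configuration
#'
#' Either a shipped preset name (synthetic run; `seed` mandatory) or an
#' input directory with a `manifest.csv` (measured run), never both.
#' Every field mirrors a key of the YAML config file accepted by
#' [run_pipeline()]; values given here win over the preset defaults.
#'
#' @param preset preset name (`"pmma55"`, `"pmma23"`, `"br10"`) or
#'   `NULL`.
#' @param input_dir directory with spectra plus `manifest.csv`, or
#'   `NULL`.
#' @param thickness film thickness, nm (defaults to the preset's).
#' @param f,chi,zeta assumed local-field factor and angles for the
#'   Stark analysis.
#' @param n_repeats repeats per bias level for synthetic runs.
#' @param seed RNG seed (required for synthetic runs).
#' @param polarity +1 or -1, used by the bacteriorhodopsin generator.
#' @param smoothing smoothing penalty for the averaged differences: 0
#'   (off, the default -- fitting happens on the raw averages),
#'   positive, or `"auto"` for GCV.
#' @param ref_smoothing smoothing applied to the averaged zero-bias
#'   reference before the derivative basis is computed; defaults to
#'   `"auto"` (GCV) because the second-derivative component amplifies
#'   reference noise as 1/step^2 and would otherwise attenuate the
#'   fitted coefficients.  Set 0 for noise-free input.
#' @param windows named window list for the feature stage.
#' @param output_dir where tables, summaries and the run manifest are
#'   written.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input_dir = NULL, thickness = NULL,
                       f = 1, chi = 0, zeta = 0, n_repeats = 10L,
                       seed = NULL, polarity = 1, smoothing = 0,
                       ref_smoothing = "auto",
                       windows = default_windows(),
                       output_dir = tempfile("starkir_run_")) {
  if (is.null(preset) == is.null(input_dir))
    stop("configure exactly one of 'preset' or 'input_dir'")
  if (!is.null(preset) && is.null(seed))
    stop("synthetic runs require a seed")
  structure(list(preset = preset, input_dir = input_dir,
                 thickness = thickness, f = f, chi = chi, zeta = zeta,
                 n_repeats = as.integer(n_repeats), seed = seed,
                 polarity = polarity, smoothing = smoothing,
                 ref_smoothing = ref_smoothing,
                 windows = windows, output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (`windows` as a mapping of name to [lo, hi]).
#' @param ... overrides applied after reading (e.g. command-line flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$windows))
    y$windows <- lapply(y$windows, as.numeric)
  y <- modifyList(y, list(...))
  do.call(run_config, y)
}

generate_series <- function(preset_name, cfg) {
  preset <- sample_preset(preset_name)
  if (!is.null(cfg$thickness)) preset$thickness <- cfg$thickness
  eff <- preset$effects
  if (eff$vse$delta_mu > 0) {
    make_pmma_series(preset, cfg$n_repeats, seed = cfg$seed)
  } else if (eff$orientation$dtheta_per_bias != 0 ||
             eff$protonation$amplitude_per_bias != 0) {
    make_br_series(preset, cfg$n_repeats, polarity = cfg$polarity,
                   seed = cfg$seed)
  } else {
    make_reorientation_series(preset, cfg$n_repeats, seed = cfg$seed)
  }
}

#' Run the full analysis pipeline
#'
#' Executes generate-or-load, difference/average, optional smoothing,
#' derivative-basis fitting, dipole-moment-change extraction (when at
#' least two bias levels are present), line-shape classification, and
#' windowed feature analysis.  Writes `coefficients.csv` (one row per
#' bias level), `features.csv`, `summary.json` and a `run_manifest.json`
#' recording the configuration, package version and md5 checksums of
#' every output, then returns the results.
#'
#' @param config a [run_config()] (or YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with `differences`, `reference`, `fits`,
#'   `stark` (a `stark_result` or NULL), `shapes`, `features`,
#'   `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(preset = "pmma55", seed = 1,
#'                                n_repeats = 3,
#'                                output_dir = tempfile()))
#' res$stark$delta_mu
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  series <- if (!is.null(cfg$preset)) generate_series(cfg$preset, cfg)
            else read_series(cfg$input_dir)
  thickness <- if (!is.null(cfg$thickness)) cfg$thickness
               else if (!is.null(cfg$preset)) sample_preset(cfg$preset)$thickness
               else stop("thickness must be configured for measured runs")

  sd_out <- series_differences(series)
  diffs <- sd_out$differences
  if (!identical(cfg$smoothing, 0))
    diffs <- lapply(diffs, smooth_difference, smoothing = cfg$smoothing)
  reference <- sd_out$reference
  if (!identical(cfg$ref_smoothing, 0))
    reference <- smooth_spectrum(reference, cfg$ref_smoothing)

  fits <- lapply(diffs, fit_vse, A_ref = reference)
  fields <- lapply(diffs, function(d)
    suppressWarnings(field_model(d$bias, thickness, cfg$f)))
  stark <- if (length(unique(vapply(fields, function(x) x$F_stat^2,
                                    numeric(1)))) >= 2)
    extract_delta_mu(fits, fields, chi = cfg$chi, zeta = cfg$zeta)
  else NULL

  shapes <- lapply(seq_along(diffs), function(i)
    decompose_shape(diffs[[i]], reference))
  grid_range <- range(reference$wavenumber)
  usable <- Filter(function(w) w[1] >= grid_range[1] &&
                     w[2] <= grid_range[2], cfg$windows)
  feats <- if (length(usable))
    lapply(diffs, window_features, windows = usable) else NULL

  coef_tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; s <- shapes[[i]]
    data.frame(bias = f$bias, F_stat = fields[[i]]$F_stat,
               c0 = f$coeffs[1], c1 = f$coeffs[2], c2 = f$coeffs[3],
               c2_se = sqrt(max(f$covariance[3, 3], 0)),
               residual_rms = f$residual_rms,
               f0 = s$fractions[1], f1 = s$fractions[2],
               f2 = s$fractions[3], label = s$label)
  }))
  rownames(coef_tab) <- NULL
  write.csv(coef_tab, file.path(cfg$output_dir, "coefficients.csv"),
            row.names = FALSE)

  paths <- c(file.path(cfg$output_dir, "coefficients.csv"))
  if (!is.null(feats)) {
    feat_tab <- do.call(rbind, lapply(seq_along(feats), function(i)
      cbind(bias = diffs[[i]]$bias, as.data.frame(feats[[i]]))))
    write.csv(feat_tab, file.path(cfg$output_dir, "features.csv"),
              row.names = FALSE)
    paths <- c(paths, file.path(cfg$output_dir, "features.csv"))
  }

  summary <- list(
    preset = cfg$preset, thickness = thickness,
    f = cfg$f, chi = cfg$chi, zeta = cfg$zeta,
    n_bias_levels = length(diffs),
    labels = vapply(shapes, `[[`, character(1), "label"),
    delta_mu_debye = if (!is.null(stark)) stark$delta_mu else NULL,
    delta_mu_ci = if (!is.null(stark)) stark$delta_mu_ci else NULL,
    slope = if (!is.null(stark)) stark$slope else NULL,
    linearity_r2 = if (!is.null(stark)) stark$linearity_r2 else NULL)
  spath <- file.path(cfg$output_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, spath)

  manifest <- list(
    package_version = as.character(packageVersion("starkir")),
    config = unclass(cfg),
    outputs = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(md5sum(p)))))
  mpath <- file.path(cfg$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(list(differences = diffs, reference = reference,
                 fits = fits, stark = stark, shapes = shapes,
                 features = feats, manifest = manifest,
                 coefficients = coef_tab, output_dir = cfg$output_dir))
}
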