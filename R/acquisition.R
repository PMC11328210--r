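#' Bias-interleaved acquisition series
#'
#' An `acquisition_series` bundles the spectra of one measurement
#' session with the schedule that produced them.  The protocol
#' alternates at-bias and zero-bias acquisitions so that each at-bias
#' repeat has a zero-bias partner from the same repeat cycle, which is
#' what lets the single-shot differences cancel slow drift.
#'
#' @param entries list of `stark_spectrum`, all on one grid.
#' @param schedule data frame with columns `slot`, `bias`, `repeat_index`,
#'   `t_on`, `t_off`.
#' @return An object of class `acquisition_series`.
#' @keywords internal
acquisition_series <- function(entries, schedule) {
  if (length(entries) > 1) {
    g0 <- entries[[1]]
    for (e in entries[-1]) {
      if (!same_grid(g0, e))
        stop("all spectra in a series must share one grid")
    }
  }
  structure(
    list(entries = entries, schedule = schedule,
         bias_levels = sort(unique(schedule$bias[schedule$bias != 0]))),
    class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf(
    "<acquisition_series> %d slots (%d filled), bias levels: %s V\n",
    nrow(x$schedule), length(x$entries),
    paste(x$bias_levels, collapse = ", ")))
  invisible(x)
}

#' Build the interleaved at-bias / zero-bias schedule
#'
#' For each repeat cycle the schedule visits every bias level followed
#' immediately by its zero-bias reference, giving `2 * n_repeats *
#' length(bias_levels)` slots.  `t_on` is the spectral acquisition
#' interval and `t_off` the ramp-plus-settle interval between slots;
#' both are carried as metadata (the settle time has no spectral effect
#' in this package, but the generator may scale drift with it).
#'
#' @param bias_levels nonempty numeric vector of applied voltages (V),
#'   all nonzero.
#' @param n_repeats repeats per level (>= 1); about 10 in routine use.
#' @param t_on,t_off acquisition / settle intervals in seconds (> 0).
#' @return An `acquisition_series` skeleton (schedule only, no spectra).
#' @examples
#' sk <- build_schedule(3, n_repeats = 10)
#' nrow(sk$schedule)  # 20 slots alternating 3 V / 0 V
#' @export
build_schedule <- function(bias_levels, n_repeats = 10L,
                           t_on = 20, t_off = 20) {
  if (length(bias_levels) == 0) stop("empty bias list")
  if (any(bias_levels == 0)) stop("bias levels must be nonzero (0 V is the reference)")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (t_on <= 0 || t_off <= 0) stop("t_on and t_off must be > 0")
  bias <- numeric(0)
  rep_idx <- integer(0)
  for (r in seq_len(n_repeats)) {
    for (v in bias_levels) {
      bias <- c(bias, v, 0)
      rep_idx <- c(rep_idx, r, r)
    }
  }
  schedule <- data.frame(slot = seq_along(bias), bias = bias,
                         repeat_index = rep_idx, t_on = t_on, t_off = t_off)
  acquisition_series(list(), schedule)
}

#' Averaged difference spectrum at one bias
#'
#' Container for the averaged at-bias minus zero-bias absorbance change
#' with its per-point standard error of the mean.
#'
#' @param grid wavenumbers, cm^-1.
#' @param delta difference absorbance values, a.u.
#' @param bias applied voltage, V.
#' @param n_repeats number of single-shot differences averaged.
#' @param sem per-point standard error (>= 0), same length as `delta`.
#' @return An object of class `difference_spectrum`.
#' @export
difference_spectrum <- function(grid, delta, bias, n_repeats = 1L,
                                sem = numeric(length(delta))) {
  if (length(grid) != length(delta) || length(grid) != length(sem))
    stop("grid, delta and sem must have equal length")
  if (any(sem < 0)) stop("sem must be >= 0")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(grid = as.numeric(grid), delta = as.numeric(delta),
                 bias = as.numeric(bias), n_repeats = as.integer(n_repeats),
                 sem = as.numeric(sem)),
            class = "difference_spectrum")
}

#' @export
print.difference_spectrum <- function(x, ...) {
  cat(sprintf(
    "<difference_spectrum> bias %g V, %d repeats, max|dA| = %.3g\n",
    x$bias, x$n_repeats, max(abs(x$delta))))
  invisible(x)
}

#' Single-shot difference spectrum
#'
#' Pointwise at-bias minus zero-bias subtraction for one repeat cycle,
#' `dA(nu) = A(nu)|V - A(nu)|0`.
#'
#' @param at_bias `stark_spectrum` acquired at nonzero bias.
#' @param at_zero `stark_spectrum` acquired at 0 V on the same grid.
#' @return A `difference_spectrum` with `n_repeats = 1` and zero sem.
#' @export
difference_single <- function(at_bias, at_zero) {
  if (at_zero$bias != 0) stop("reference spectrum must be at 0 V bias")
  if (!same_grid(at_bias, at_zero)) stop("grid mismatch between pair")
  difference_spectrum(at_bias$wavenumber,
                      at_bias$absorbance - at_zero$absorbance,
                      bias = at_bias$bias)
}

#' Average single-shot differences at one bias
#'
#' Pointwise mean over repeats with the standard error of the mean,
#' `sem = sd / sqrt(N)`.
#'
#' @param singles list of `difference_spectrum`, all at one bias on one
#'   grid.
#' @return A `difference_spectrum` with `n_repeats = length(singles)`.
#' @export
average_differences <- function(singles) {
  if (length(singles) == 0) stop("empty list of differences")
  bias <- vapply(singles, function(d) d$bias, numeric(1))
  if (length(unique(bias)) != 1)
    stop("all differences must be at the same bias")
  grid <- singles[[1]]$grid
  for (d in singles[-1]) {
    if (length(d$grid) != length(grid) || max(abs(d$grid - grid)) > 1e-9 * max(grid))
      stop("grid mismatch among differences")
  }
  m <- vapply(singles, function(d) d$delta, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n <- ncol(m)
  avg <- rowMeans(m)
  sem <- if (n > 1) apply(m, 1, sd) / sqrt(n) else numeric(length(grid))
  difference_spectrum(grid, avg, bias[1], n_repeats = n, sem = sem)
}

#' Difference spectra of a full acquisition series
#'
#' Pairs every at-bias entry with the zero-bias acquisition of the same
#' repeat cycle (adjacent slot in the schedule), computes the
#' single-shot differences, and averages them per bias level.  Also
#' returns the averaged zero-bias spectrum used as the fitting
#' reference.
#'
#' @param series a filled `acquisition_series`.
#' @return List with `differences` (list of `difference_spectrum`, one
#'   per bias level, in the order of `series$bias_levels`) and `reference`
#'   (`stark_spectrum`, mean zero-bias spectrum).
#' @export
series_differences <- function(series) {
  sched <- series$schedule
  if (length(series$entries) != nrow(sched))
    stop("series entries do not fill the schedule")
  ref_rows <- which(sched$bias == 0)
  diffs <- list()
  for (v in series$bias_levels) {
    rows <- which(sched$bias == v)
    singles <- lapply(rows, function(i) {
      # the paired reference follows immediately in the same cycle
      j <- i + 1L
      if (j > nrow(sched) || sched$bias[j] != 0 ||
          sched$repeat_index[j] != sched$repeat_index[i])
        stop("schedule slot ", i, " has no adjacent zero-bias partner")
      difference_single(series$entries[[i]], series$entries[[j]])
    })
    diffs[[as.character(v)]] <- average_differences(singles)
  }
  ref_mat <- vapply(series$entries[ref_rows], function(s) s$absorbance,
                    numeric(length(series$entries[[1]]$wavenumber)))
  ref_mat <- matrix(ref_mat, ncol = length(ref_rows))
  reference <- spectrum_new(series$entries[[1]]$wavenumber,
                            rowMeans(ref_mat), bias = 0,
                            label = "zero-bias average")
  list(differences = unname(diffs), reference = reference)
}

#' Write / read an acquisition series as CSV files plus a manifest
#'
#' The manifest is a plain CSV table with columns `file`, `bias`,
#' `repeat_index` listing one spectrum file per schedule slot, in slot
#' order.
#'
#' @param series a filled `acquisition_series`.
#' @param dir output directory (created if missing).
#' @return `write_series()` returns the manifest path invisibly;
#'   `read_series()` returns an `acquisition_series`.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sched <- series$schedule
  files <- sprintf("slot%03d_bias%+05.1fV_rep%02d.csv",
                   sched$slot, sched$bias, sched$repeat_index)
  for (i in seq_along(files))
    write_spectrum_csv(series$entries[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files, bias = sched$bias,
                         repeat_index = sched$repeat_index)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' @rdname write_series
#' @param t_on,t_off schedule metadata to record when reading back.
#' @export
read_series <- function(dir, t_on = 20, t_off = 20) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mpath)
  entries <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    entries[[i]] <- read_spectrum_csv(file.path(dir, manifest$file[i]),
                                      bias = manifest$bias[i],
                                      repeat_index = manifest$repeat_index[i])
    if (i > 1 && !same_grid(entries[[1]], entries[[i]]))
      stop("grid mismatch in series file: ", manifest$file[i])
  }
  schedule <- data.frame(slot = seq_len(nrow(manifest)),
                         bias = manifest$bias,
                         repeat_index = manifest$repeat_index,
                         t_on = t_on, t_off = t_off)
  acquisition_series(entries, schedule)
}
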