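#' Read and write single spectra as two-column CSV
#'
#' The on-disk convention is a plain comma-separated table with header
#' `wavenumber_cm-1,absorbance` and decimal points.  Bias and repeat
#' metadata travel in the series manifest, not in the spectrum file.
#'
#' @param path file path.
#' @param bias,repeat_index,label metadata attached to the returned
#'   spectrum.
#' @return `read_spectrum_csv()` returns a `stark_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, bias = 0, repeat_index = 1L, label = "") {
  df <- read.csv(path, check.names = FALSE)
  need <- c("wavenumber_cm-1", "absorbance")
  if (!all(need %in% names(df)))
    stop("CSV must have header 'wavenumber_cm-1,absorbance': ", path)
  spectrum_new(df[["wavenumber_cm-1"]], df[["absorbance"]],
               bias = bias, repeat_index = repeat_index, label = label)
}

#' @rdname read_spectrum_csv
#' @param s a `stark_spectrum`.
#' @export
write_spectrum_csv <- function(s, path) {
  df <- data.frame(a = s$wavenumber, b = s$absorbance)
  names(df) <- c("wavenumber_cm-1", "absorbance")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write single spectra in JCAMP-DX (XYDATA) form
#'
#' Minimal JCAMP-DX 4.24 support for fixed-step spectra: the writer
#' emits an `##XYDATA=(X++(Y..Y))` block in plain AFFN numbers; the
#' reader handles that layout (no ASDF/DIF compression) plus
#' `##PEAK TABLE=(XY..XY)` pairs.  Sufficient for round-tripping the
#' package's own output and typical exports of instrument software.
#'
#' @inheritParams read_spectrum_csv
#' @return `read_spectrum_jcamp()` returns a `stark_spectrum`.
#' @export
read_spectrum_jcamp <- function(path, bias = 0, repeat_index = 1L,
                                label = "") {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  start <- grep("^##(XYDATA|PEAK TABLE)=", lines)
  if (!length(start)) stop("no ##XYDATA/##PEAK TABLE block in ", path)
  kind <- lines[start[1]]
  end <- grep("^##END=", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body))]
  xfac <- grab("XFACTOR"); if (is.na(xfac)) xfac <- 1
  yfac <- grab("YFACTOR"); if (is.na(yfac)) yfac <- 1
  if (grepl("XY\\.\\.XY", kind)) {
    toks <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    x <- toks[c(TRUE, FALSE)] * xfac
    y <- toks[c(FALSE, TRUE)] * yfac
  } else {
    x <- numeric(0); y <- numeric(0)
    for (ln in body) {
      toks <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
      x <- c(x, toks[1])
      y <- c(y, toks[-1])
    }
    # x holds the leading abscissa of each line; rebuild the full grid
    first <- grab("FIRSTX"); last <- grab("LASTX")
    npt <- grab("NPOINTS")
    if (is.na(first) || is.na(last) || is.na(npt))
      stop("FIRSTX/LASTX/NPOINTS required for X++(Y..Y) data")
    x <- seq(first, last, length.out = npt)
    if (length(y) != npt) stop("NPOINTS does not match Y count in ", path)
    y <- y * yfac
  }
  ord <- order(x)
  spectrum_new(x[ord], y[ord], bias = bias, repeat_index = repeat_index,
               label = label)
}

#' @rdname read_spectrum_jcamp
#' @param s a `stark_spectrum`.
#' @export
write_spectrum_jcamp <- function(s, path) {
  nu <- s$wavenumber
  if (length(unique(round(diff(nu), 10))) != 1)
    stop("JCAMP X++(Y..Y) writer requires a uniform grid")
  hdr <- c(
    sprintf("##TITLE=%s", if (nzchar(s$label)) s$label else "spectrum"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", nu[1]),
    sprintf("##LASTX=%.10g", nu[length(nu)]),
    sprintf("##NPOINTS=%d", length(nu)),
    sprintf("##$BIAS VOLTS=%.10g", s$bias),
    "##XYDATA=(X++(Y..Y))")
  per <- 6L
  rows <- split(seq_along(nu), ceiling(seq_along(nu) / per))
  body <- vapply(rows, function(i) {
    paste(c(sprintf("%.6g", nu[i[1]]),
            sprintf("%.8g", s$absorbance[i])), collapse = " ")
  }, character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}
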