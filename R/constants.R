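#' Physical constants used by the Stark analysis
#'
#' One centralized table serving both unit systems used to evaluate the
#' Liptay forward model.  The Debye is defined through the esu system
#' (1 D = 1e-18 esu cm); its SI rendering 1e-21/c = 3.33564e-30 C m is the
#' exact counterpart of the conventionally quoted rounded value
#' 3.34e-30 C m.  Keeping the two renderings exactly consistent is what
#' lets the SI and cgs evaluations of the forward model agree to machine
#' precision.
#'
#' @format A named list:
#' \describe{
#'   \item{h_si}{Planck constant, J s}
#'   \item{c_si}{speed of light, m/s}
#'   \item{h_cgs}{Planck constant, erg s}
#'   \item{c_cgs}{speed of light, cm/s}
#'   \item{debye_si}{1 Debye in C m (exact esu-derived value)}
#'   \item{debye_cgs}{1 Debye in esu cm (1e-18, exact)}
#'   \item{statvolt_si}{1 statvolt in V}
#' }
#' @export
stark_constants <- list(
  h_si       = 6.62607015e-34,
  c_si       = 2.99792458e8,
  h_cgs      = 6.62607015e-27,
  c_cgs      = 2.99792458e10,
  debye_si   = 1e-21 / 2.99792458e8,   # = 3.33564e-30 C m
  debye_cgs  = 1e-18,
  statvolt_si = 2.99792458e2
)
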