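## CODATA 2018 constants, SI units unless noted. Centralized so every unit
## conversion in the package goes through one place.
.const <- list(
  e        = 1.602176634e-19,    # elementary charge, C
  eps0     = 8.8541878128e-12,   # vacuum permittivity, F/m
  hbar     = 1.054571817e-34,    # reduced Planck constant, J s
  c        = 2.99792458e8,       # speed of light, m/s
  debye    = 3.33564095e-30,     # 1 D in C m
  ev       = 1.602176634e-19     # 1 eV in J
)

#' Physical constants used by ppkin
#'
#' Returns the CODATA constants the package uses for unit conversions
#' (elementary charge, vacuum permittivity, hbar, speed of light, the
#' debye, the electronvolt), all in SI units.
#'
#' @return Named list of constants.
#' @export
ppkin_constants <- function() .const

## fs -> ps
.fs2ps <- function(x) x / 1000

## FWHM -> Gaussian sigma
.fwhm2sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
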