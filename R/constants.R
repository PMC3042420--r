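# Physical constants (CODATA) used throughout the package.

#' Physical constants
#'
#' CODATA values for the gas constant, the Faraday constant and the Celsius
#' zero point, as used by every electrochemical calculation in the package.
#'
#' @return A list with elements `R` (J mol^-1 K^-1), `F` (C mol^-1) and
#'   `zero_celsius` (K).
#' @examples
#' k <- phys_constants()
#' 1000 * k$R * 310.15 / k$F  # RT/F at 37 C, in mV (~26.7)
#' @export
phys_constants <- function() {
  list(R = 8.314462618, F = 96485.33212, zero_celsius = 273.15)
}

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @return RT/F in mV (about 26.7 mV at 310.15 K).
#' @export
rt_over_f <- function(temperature_K) {
  if (!is.numeric(temperature_K) || any(temperature_K <= 0))
    stop("temperature_K must be > 0 (kelvin)")
  k <- phys_constants()
  1000 * k$R * temperature_K / k$F
}

# default temperature for equilibrium calculations: recordings are made at
# 37 C; 25 C limiting mobilities are used uncorrected (documented
# approximation in the methods vignette)
BODY_TEMP_K <- 310.15
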