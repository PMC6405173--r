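#' Physical constants and unit conversions
#'
#' The engine works in a single coherent internal unit system:
#' length cm, volume flow cm^3/s, concentration mM (= umol/cm^3),
#' solute flux umol/(s.cm tubule), pressure mmHg, potential mV,
#' temperature 310 K. Quantities quoted in renal-physiology units
#' (nl/min, um) are converted at the API boundary with the constants
#' below; no other file owns a conversion factor.
#'
#' @format A list with elements:
#' \describe{
#'   \item{RT_mmHg_per_mM}{osmotic pressure of 1 mM ideal solute at 310 K,
#'     in mmHg (van't Hoff, R = 62.363 L mmHg / (mol K)).}
#'   \item{RT_over_F_mV}{thermal voltage RT/F at 310 K, in mV.}
#'   \item{visc_mmHg_s}{luminal fluid viscosity, mmHg s.}
#'   \item{cm3s_per_nlmin}{cm^3/s in one nl/min.}
#'   \item{cm_per_um}{cm in one um.}
#'   \item{T_K}{thermodynamic temperature, K.}
#' }
#' @export
ns_const <- list(
  T_K              = 310,
  RT_mmHg_per_mM   = 62.363 * 310 * 1e-3,  # 19.3325 mmHg per mM
  RT_over_F_mV     = 26.7127,              # (8.31446*310/96485.3) * 1000
  visc_mmHg_s      = 6.4e-6,
  cm3s_per_nlmin   = 1e-6 / 60,
  cm_per_um        = 1e-4,
  nephrons_per_kidney = 1e6,
  kidneys_per_person  = 2,
  min_per_day      = 1440
)

#' Convert a flow in nl/min to cm^3/s
#' @param q flow in nl/min
#' @return flow in cm^3/s
#' @keywords internal
nlmin_to_cm3s <- function(q) q * ns_const$cm3s_per_nlmin

#' Convert a flow in cm^3/s to nl/min
#' @param q flow in cm^3/s
#' @return flow in nl/min
#' @keywords internal
cm3s_to_nlmin <- function(q) q / ns_const$cm3s_per_nlmin

#' Convert a length in um to cm
#' @param x length in um
#' @return length in cm
#' @keywords internal
um_to_cm <- function(x) x * ns_const$cm_per_um
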