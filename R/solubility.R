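# Garcia & Gordon (1992) combined-fit coefficients for oxygen saturation,
# Benson & Krause data, yielding umol/kg. Scaled temperature
# Ts = ln[(298.15 - T) / (273.15 + T)].
.gg92 <- list(
  A = c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369),
  B = c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3),
  C0 = -2.75915e-7
)

# reference seawater density used to convert umol/kg -> mmol/m^3
#' Reference seawater density (kg/m^3) used for solubility unit conversion
#' @export
rho_seawater <- 1025

.gg92_ts <- function(T_c) log((298.15 - T_c) / (273.15 + T_c))

# log of saturation concentration in umol/kg
.gg92_log_c <- function(ts, S) {
  A <- .gg92$A; B <- .gg92$B
  A[1] + ts * (A[2] + ts * (A[3] + ts * (A[4] + ts * (A[5] + ts * A[6])))) +
    S * (B[1] + ts * (B[2] + ts * (B[3] + ts * B[4]))) +
    .gg92$C0 * S^2
}

#' Oxygen solubility (saturation concentration) in seawater
#'
#' Saturation concentration of dissolved oxygen at one atmosphere of
#' water-saturated air, from the Garcia & Gordon (1992) combined fit to the
#' Benson & Krause data, converted from umol/kg to mmol/m^3 with a fixed
#' reference density of 1025 kg/m^3.
#'
#' @param T_c temperature, degrees Celsius. The fit is valid for roughly
#'   \[-3, 40\] degC; values outside trigger a warning.
#' @param S practical salinity, psu; fit range roughly \[0, 42\].
#' @param density seawater density used for the unit conversion, kg/m^3.
#' @return saturation O2 concentration, mmol/m^3, decreasing in both
#'   temperature and salinity. Non-finite inputs propagate as `NA`.
#' @examples
#' o2_solubility(10, 35)
#' @export
o2_solubility <- function(T_c, S, density = rho_seawater) {
  bad_T <- is.finite(T_c) & (T_c < -3 | T_c > 40)
  bad_S <- is.finite(S) & (S < 0 | S > 42)
  if (any(bad_T)) warnf("%d temperature value(s) outside the solubility fit range [-3, 40] degC", sum(bad_T))
  if (any(bad_S)) warnf("%d salinity value(s) outside the solubility fit range [0, 42] psu", sum(bad_S))
  umol_kg <- exp(.gg92_log_c(.gg92_ts(T_c), S))
  umol_kg * density / 1000
}

#' Partial pressure of dissolved oxygen
#'
#' Converts an O2 concentration into partial pressure as fractional
#' saturation times the atmospheric O2 mole fraction: at 100% saturation
#' pO2 equals `x_o2` atm exactly, and pO2 is linear in O2 through the
#' origin.
#'
#' @param O2 dissolved oxygen, mmol/m^3 (non-negative).
#' @param T_c temperature, degC.
#' @param S salinity, psu.
#' @param x_o2 atmospheric mole fraction of O2 expressed in atm
#'   (default 0.209).
#' @return pO2 in atm.
#' @export
po2_from_o2 <- function(O2, T_c, S, x_o2 = 0.209) {
  sol <- o2_solubility(T_c, S)
  if (any(is.finite(sol) & sol <= 0))
    stopf("internal error: non-positive O2 solubility")
  x_o2 * O2 / sol
}

#' Apparent oxygen utilization
#'
#' AOU = O2sol - O2: the deficit of dissolved oxygen relative to
#' saturation, reflecting the balance of respiration-driven consumption and
#' ventilation. The identity `AOU + O2 == o2_solubility(T_c, S)` holds to
#' machine precision.
#'
#' @inheritParams po2_from_o2
#' @return AOU, mmol/m^3 (may be negative for supersaturated water).
#' @export
aou <- function(O2, T_c, S) {
  o2_solubility(T_c, S) - O2
}

# analytic partial derivatives of the solubility (mmol/m^3) with respect to
# temperature (per K == per degC) and salinity (per psu)
.solubility_partials <- function(T_c, S, density = rho_seawater) {
  ts <- .gg92_ts(T_c)
  C <- exp(.gg92_log_c(ts, S)) * density / 1000
  A <- .gg92$A; B <- .gg92$B
  df_dts <- A[2] + 2 * A[3] * ts + 3 * A[4] * ts^2 + 4 * A[5] * ts^3 +
    5 * A[6] * ts^4 + S * (B[2] + 2 * B[3] * ts + 3 * B[4] * ts^2)
  # d ts / d T for Ts = ln[(298.15 - T)/(273.15 + T)]
  dts_dT <- -(298.15 + 273.15) / ((298.15 - T_c) * (273.15 + T_c))
  df_dS <- B[1] + ts * (B[2] + ts * (B[3] + ts * B[4])) + 2 * .gg92$C0 * S
  list(dT = C * df_dts * dts_dT, dS = C * df_dS, C = C)
}
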