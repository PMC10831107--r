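#' Temperature-corrected metabolic temperature sensitivity
#'
#' Applies the linear temperature correction of the `E_o` trait:
#' `E_o + dEo_dT * (T_K - T_ref)`, with the input temperature converted
#' from degrees Celsius to kelvin. At `T_ref` (default 15 degC) the trait
#' is returned unchanged.
#'
#' @param T_c temperature, degC (vectorized).
#' @param traits a [trait_set].
#' @return effective E_o, eV.
#' @export
effective_eo <- function(T_c, traits) {
  stopifnot(inherits(traits, "trait_set"))
  traits$E_o + traits$dEo_dT * ((T_c + 273.15) - traits$T_ref)
}

#' Normalized Metabolic Index at given ocean state
#'
#' Evaluates \eqn{\phi = A_c \, pO_2 \exp\{E_o^{eff}/k_B (1/T - 1/T_{ref})\}}
#' elementwise: the ratio of oxygen supply to temperature-dependent resting
#' metabolic demand, normalized so that \eqn{\phi > 1} marks viable habitat.
#' The temperature in the Arrhenius factor is in kelvin and
#' \eqn{E_o^{eff}} carries the linear temperature correction
#' ([effective_eo]). Where O2 is exactly zero, \eqn{\phi} is 0 (anoxic
#' water is uninhabitable, not undefined).
#'
#' @param T_c temperature, degC.
#' @param S salinity, psu.
#' @param O2 dissolved oxygen, mmol/m^3 (non-negative).
#' @param traits a [trait_set].
#' @return \eqn{\phi} (unitless), same shape as the inputs; `NA` where any
#'   input is missing.
#' @examples
#' tr <- trait_set(A_c = 10, E_o = 0.4)
#' phi_eval(15, 35, o2_solubility(15, 35), tr)  # saturated at T_ref: 2.09
#' @export
phi_eval <- function(T_c, S, O2, traits) {
  stopifnot(inherits(traits, "trait_set"))
  if (any(is.finite(O2) & O2 < 0)) stopf("O2 must be non-negative")
  p <- po2_from_o2(O2, T_c, S)
  T_k <- T_c + 273.15
  eo <- effective_eo(T_c, traits)
  traits$A_c * p * exp(eo / traits$k_B * (1 / T_k - 1 / traits$T_ref))
}

#' Metabolic Index and its oxygen bookkeeping on gridded state
#'
#' Computes \eqn{\phi} at every grid cell of a hydrographic field (or of an
#' ensemble forecast set), together with pO2, the saturation concentration
#' O2sol and the apparent oxygen utilization AOU = O2sol - O2.
#' \eqn{\phi} is always computed cellwise from the native-resolution state;
#' any averaging (annual, depth-layer, region) is applied to \eqn{\phi}
#' afterwards, never to the drivers first.
#'
#' @param state a [hydro_field] (dims time, depth, lat, lon), a
#'   [forecast_set] (dims init, member, lead, depth, lat, lon), or a list
#'   with numeric components `T`, `S`, `O2` of identical shape.
#' @param traits a [trait_set].
#' @param ... unused.
#' @return for a `hydro_field`, a `phi_field` (list with `phi`, `pO2`,
#'   `O2sol`, `AOU` arrays on the same grid plus time labels); for a
#'   `forecast_set`, a `phi_forecast` (array `phi` on the forecast dims);
#'   otherwise a plain list of arrays.
#' @export
metabolic_index <- function(state, traits, ...) UseMethod("metabolic_index")

.phi_components <- function(T_c, S, O2, traits) {
  if (!identical(dim(T_c), dim(S)) || !identical(dim(T_c), dim(O2)) ||
      length(T_c) != length(S) || length(T_c) != length(O2))
    stopf("T, S and O2 fields must share one shape")
  sol <- o2_solubility(T_c, S)
  p <- 0.209 * O2 / sol
  T_k <- T_c + 273.15
  eo <- effective_eo(T_c, traits)
  phi <- traits$A_c * p * exp(eo / traits$k_B * (1 / T_k - 1 / traits$T_ref))
  list(phi = phi, pO2 = p, O2sol = sol, AOU = sol - O2)
}

#' @export
metabolic_index.default <- function(state, traits, ...) {
  stopifnot(is.list(state), all(c("T", "S", "O2") %in% names(state)))
  .phi_components(state$T, state$S, state$O2, traits)
}

#' @export
metabolic_index.hydro_field <- function(state, traits, ...) {
  comp <- .phi_components(state$vars$T, state$vars$S, state$vars$O2, traits)
  structure(
    c(comp, list(grid = state$grid, years = state$years,
                 months = state$months, traits = traits)),
    class = "phi_field")
}

#' @export
metabolic_index.forecast_set <- function(state, traits, ...) {
  comp <- .phi_components(state$vars$T, state$vars$S, state$vars$O2, traits)
  structure(
    c(comp, list(grid = state$grid, init_years = state$init_years,
                 leads = state$leads, traits = traits,
                 adjusted = state$adjusted)),
    class = "phi_forecast")
}

#' @export
print.phi_field <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<phi_field> %s; dims [time=%d, depth=%d, lat=%d, lon=%d]\n",
              x$traits$species, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Analytic partial derivatives of the Metabolic Index
#'
#' First-order partial derivatives of \eqn{\phi} with respect to the three
#' driver variables, holding the other two fixed:
#' \itemize{
#'   \item \eqn{\partial\phi/\partial O_2 = A_c \, 0.209 \, g(T) / O_2^{sol}}
#'     (per mmol/m^3) — positive, independent of O2 itself;
#'   \item \eqn{\partial\phi/\partial T} (per K) combines the solubility's
#'     temperature dependence inside pO2, the Arrhenius factor, and the
#'     linear E_o(T) correction;
#'   \item \eqn{\partial\phi/\partial S} (per psu) enters only through the
#'     solubility (saltier water holds less O2, so pO2 and \eqn{\phi} rise).
#' }
#' These are the exact derivatives of [phi_eval]; they agree with centered
#' finite differences to high relative accuracy and are the coefficients of
#' the first-order Taylor attribution ([taylor_decompose]).
#'
#' @inheritParams phi_eval
#' @return list with components `dO2`, `dT`, `dS` (same shape as inputs).
#' @export
phi_partials <- function(T_c, S, O2, traits) {
  stopifnot(inherits(traits, "trait_set"))
  sp <- .solubility_partials(T_c, S)
  C <- sp$C
  T_k <- T_c + 273.15
  eo <- effective_eo(T_c, traits)
  expo <- eo / traits$k_B * (1 / T_k - 1 / traits$T_ref)
  g <- exp(expo)
  # d/dT of the exponent: product rule on E_o_eff(T) * (1/T - 1/T_ref) / k_B
  dexpo_dT <- (traits$dEo_dT * (1 / T_k - 1 / traits$T_ref) -
                 eo / T_k^2) / traits$k_B
  a <- traits$A_c * 0.209
  dO2 <- a * g / C
  dT <- a * O2 * (g * dexpo_dT / C - g * sp$dT / C^2)
  dS <- -a * O2 * g * sp$dS / C^2
  miss <- is.na(T_c) | is.na(S) | is.na(O2)
  dO2[miss] <- NA_real_; dT[miss] <- NA_real_; dS[miss] <- NA_real_
  list(dO2 = dO2, dT = dT, dS = dS)
}
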