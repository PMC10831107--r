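#' First-order Taylor decomposition of the Metabolic Index
#'
#' Attributes yearly \eqn{\phi} variability to its three drivers:
#' \eqn{\phi(t) \approx \bar\phi + \phi_{O_2}(t) + \phi_T(t) + \phi_S(t)},
#' with each component the analytic partial derivative of \eqn{\phi}
#' (evaluated at the full-record time-mean state) times the driver's
#' anomaly. By default \eqn{\bar\phi} is \eqn{\phi} evaluated at the
#' time-mean drivers (`phi_bar = "phi_of_mean"`); the alternative
#' `"mean_phi"` (the time mean of \eqn{\phi(t)}) is available for
#' sensitivity, the two differing by the nonlinearity. The residual
#' \eqn{\phi(t) - \bar\phi - \sum_i \phi_i(t)} collects higher-order terms
#' and is stored, never dropped. The oxygen component is further split by
#' the identity \eqn{O_2 = O_2^{sol} - AOU} into
#' \eqn{\phi_{O_2^{sol}}} and \eqn{\phi_{AOU}}, which sum to
#' \eqn{\phi_{O_2}} to machine precision because \eqn{\phi} is linear in
#' O2 at fixed T, S.
#'
#' @param T_c,S,O2 yearly driver series: vectors, or arrays with time as
#'   the first dimension (per-cell decomposition).
#' @param traits a [trait_set].
#' @param phi_bar `"phi_of_mean"` (default) or `"mean_phi"`.
#' @return an object of class `phi_decomposition`: `phi` (the yearly
#'   \eqn{\phi} at the yearly drivers), `phi_bar`, components `phi_O2`,
#'   `phi_T`, `phi_S`, `phi_O2sol`, `phi_AOU`, `residual`, the `partials`
#'   at the mean state, and the mean state itself.
#' @export
taylor_decompose <- function(T_c, S, O2, traits,
                             phi_bar = c("phi_of_mean", "mean_phi")) {
  phi_bar <- match.arg(phi_bar)
  T_c <- as.array(T_c); S <- as.array(S); O2 <- as.array(O2)
  if (!identical(dim(T_c), dim(S)) || !identical(dim(T_c), dim(O2)))
    stopf("driver series must share one shape")
  dms <- dim(T_c)
  nt <- dms[1]
  if (nt < 3) stopf("need at least 3 years to decompose")
  ncell <- prod(dms[-1])
  tm <- matrix(T_c, nt); sm <- matrix(S, nt); om <- matrix(O2, nt)
  mT <- colMeans(tm); mS <- colMeans(sm); mO <- colMeans(om)
  pp <- phi_partials(mT, mS, mO, traits)
  comp <- function(x, mx, d) sweep(sweep(x, 2, mx, "-"), 2, d, "*")
  phi_T <- comp(tm, mT, pp$dT)
  phi_S <- comp(sm, mS, pp$dS)
  phi_O2 <- comp(om, mO, pp$dO2)
  # solubility / AOU split of the O2 component
  solm <- matrix(o2_solubility(T_c, S), nt)
  aoum <- solm - om
  phi_O2sol <- comp(solm, colMeans(solm), pp$dO2)
  phi_AOU <- -comp(aoum, colMeans(aoum), pp$dO2)
  phi_t <- matrix(phi_eval(T_c, S, O2, traits), nt)
  pb <- switch(phi_bar,
               phi_of_mean = phi_eval(mT, mS, mO, traits),
               mean_phi = colMeans(phi_t))
  residual <- sweep(phi_t, 2, pb, "-") - phi_T - phi_S - phi_O2
  reshape <- function(m) array(m, dms)
  structure(list(
    phi = reshape(phi_t),
    phi_bar = array(pb, if (length(dms) > 1) dms[-1] else 1L),
    phi_O2 = reshape(phi_O2), phi_T = reshape(phi_T),
    phi_S = reshape(phi_S),
    phi_O2sol = reshape(phi_O2sol), phi_AOU = reshape(phi_AOU),
    residual = reshape(residual),
    partials = pp,
    mean_state = list(T = mT, S = mS, O2 = mO),
    phi_bar_convention = phi_bar, traits = traits),
    class = "phi_decomposition")
}

#' @export
print.phi_decomposition <- function(x, ...) {
  cat(sprintf(
    "<phi_decomposition> %s; %d years x %d cell(s); phi_bar = %s\n",
    x$traits$species, dim(as.array(x$phi))[1],
    prod(dim(as.array(x$phi))[-1]), x$phi_bar_convention))
  invisible(x)
}

#' Oxygen-component split of a decomposition
#'
#' Returns the solubility and AOU sub-components of \eqn{\phi_{O_2}}
#' together with their closure error; the identity
#' \eqn{\phi_{O_2} = \phi_{O_2^{sol}} + \phi_{AOU}} is exact by linearity
#' of \eqn{\phi} in O2.
#'
#' @param decomp a `phi_decomposition`.
#' @return list with `phi_O2sol`, `phi_AOU` and `max_abs_error` of the
#'   closure.
#' @export
split_o2_component <- function(decomp) {
  stopifnot(inherits(decomp, "phi_decomposition"))
  err <- decomp$phi_O2 - (decomp$phi_O2sol + decomp$phi_AOU)
  list(phi_O2sol = decomp$phi_O2sol, phi_AOU = decomp$phi_AOU,
       max_abs_error = max(abs(err), na.rm = TRUE))
}

.vcov_time <- function(x, y = NULL) {
  # variance/covariance along the first (time) dimension, unbiased (n-1)
  nt <- dim(as.array(x))[1]
  xm <- matrix(x, nt)
  if (is.null(y)) apply(xm, 2, stats::var)
  else {
    ym <- matrix(y, nt)
    vapply(seq_len(ncol(xm)), function(j) stats::cov(xm[, j], ym[, j]),
           numeric(1))
  }
}

#' Variance budget of the Metabolic Index
#'
#' Decomposes the interannual variance of \eqn{\phi} into the variances of
#' its three Taylor components plus twice their pairwise covariances, with
#' the remainder reported as a residual term (the linear budget is
#' approximate). Two sub-budgets close exactly, as algebraic identities of
#' the variance of a sum: the oxygen-component variance into solubility,
#' AOU and their covariance, and the O2--T covariance into its solubility
#' and AOU parts. All moments use the unbiased (n-1) estimator on the
#' yearly series.
#'
#' @param decomp a `phi_decomposition`.
#' @return an object of class `variance_budget`: named list of budget
#'   terms (scalars for series input, arrays over cells otherwise);
#'   `as.data.frame()` turns it into a tidy term/value table.
#' @export
variance_budget <- function(decomp) {
  stopifnot(inherits(decomp, "phi_decomposition"))
  nt <- dim(as.array(decomp$phi))[1]
  if (nt < 3) stopf("need at least 3 years")
  v <- list(
    var_phi = .vcov_time(decomp$phi),
    var_O2 = .vcov_time(decomp$phi_O2),
    var_T = .vcov_time(decomp$phi_T),
    var_S = .vcov_time(decomp$phi_S),
    cov_O2_T = .vcov_time(decomp$phi_O2, decomp$phi_T),
    cov_O2_S = .vcov_time(decomp$phi_O2, decomp$phi_S),
    cov_T_S = .vcov_time(decomp$phi_T, decomp$phi_S),
    var_O2sol = .vcov_time(decomp$phi_O2sol),
    var_AOU = .vcov_time(decomp$phi_AOU),
    cov_O2sol_AOU = .vcov_time(decomp$phi_O2sol, decomp$phi_AOU),
    cov_O2sol_T = .vcov_time(decomp$phi_O2sol, decomp$phi_T),
    cov_AOU_T = .vcov_time(decomp$phi_AOU, decomp$phi_T))
  linear <- v$var_O2 + v$var_T + v$var_S +
    2 * (v$cov_O2_T + v$cov_O2_S + v$cov_T_S)
  v$residual_term <- v$var_phi - linear
  shape <- dim(as.array(decomp$phi))[-1]
  if (length(shape) && prod(shape) > 1)
    v <- lapply(v, function(x) array(x, shape))
  else v <- lapply(v, as.numeric)
  structure(v, class = "variance_budget")
}

#' @export
as.data.frame.variance_budget <- function(x, ...) {
  data.frame(term = names(x),
             value = vapply(x, function(v) mean(as.numeric(v), na.rm = TRUE),
                            numeric(1)),
             row.names = NULL)
}

#' @export
print.variance_budget <- function(x, ...) {
  cat("<variance_budget>\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Forecast skill of the Taylor driver components
#'
#' Treats each first-order driver component, computed from the
#' drift-adjusted forecast drivers with partial derivatives and means from
#' the forecast-side climatology, as a forecast of the unchanged
#' reconstruction \eqn{\phi}, and verifies it with the standard skill
#' machinery. This answers which driver carries the predictability of
#' habitat viability.
#'
#' @param fc_anom list of matrices `T`, `S`, `O2` of shape
#'   `(init, lead)`: region-series ensemble-mean drift-adjusted driver
#'   anomalies.
#' @param fc_clim list of vectors `T`, `S`, `O2` over leads: the forecast
#'   lead-dependent climatological driver means of the same region series.
#' @param init_years initialization years.
#' @param recon_phi yearly reconstruction \eqn{\phi} region series (raw;
#'   anomalies formed internally).
#' @param recon_years years of `recon_phi`.
#' @param traits a [trait_set].
#' @param alpha significance level.
#' @return named list of `skill_result` objects for components `O2`,
#'   `T`, `S` (plus `O2sol`-related attribution is available through
#'   [variance_budget]).
#' @export
component_skill <- function(fc_anom, fc_clim, init_years, recon_phi,
                            recon_years, traits, alpha = 0.05) {
  stopifnot(all(c("T", "S", "O2") %in% names(fc_anom)),
            all(c("T", "S", "O2") %in% names(fc_clim)))
  n_lead <- ncol(as.matrix(fc_anom$T))
  pp <- phi_partials(fc_clim$T, fc_clim$S, fc_clim$O2, traits)  # per lead
  comp_f <- list(
    O2 = sweep(as.matrix(fc_anom$O2), 2, pp$dO2, "*"),
    T = sweep(as.matrix(fc_anom$T), 2, pp$dT, "*"),
    S = sweep(as.matrix(fc_anom$S), 2, pp$dS, "*"))
  lapply(comp_f, assess_skill, init_years = init_years,
         recon = recon_phi, recon_years = recon_years, alpha = alpha)
}
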