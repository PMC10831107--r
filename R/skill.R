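#' Drift adjustment of initialized forecasts
#'
#' Removes the lead-time dependent model climatology: at every grid cell
#' (or series position) and lead, the mean across all ensemble members and
#' all initialization dates is subtracted, turning forecasts into
#' anomalies. After adjustment that mean is zero to machine precision; a
#' set that is already mean-zero per lead is unchanged, and any constant
#' lead-dependent drift is removed exactly.
#'
#' @param x a `forecast_set`, or a numeric array whose first three
#'   dimensions are `(init, member, lead)`.
#' @param ... unused.
#' @return the same type, as anomalies; a `forecast_set` gains a
#'   `climatology` slot (per-variable arrays over `(lead, ...)`) and
#'   `adjusted = TRUE`.
#' @export
drift_adjust <- function(x, ...) UseMethod("drift_adjust")

.drift_adjust_array <- function(x) {
  dms <- dim(x)
  if (length(dms) < 3) stopf("need dims (init, member, lead, ...)")
  if (dms[1] < 2)
    stopf("drift adjustment needs >= 2 initialization dates")
  ni <- dms[1]; nm <- dms[2]; nl <- dms[3]
  rest <- if (length(dms) > 3) prod(dms[-(1:3)]) else 1L
  xm <- array(x, c(ni * nm, nl * rest))
  clim <- colMeans(xm)           # mean over members x inits, per (lead, cell)
  anom <- sweep(xm, 2, clim, "-")
  list(anom = array(anom, dms),
       clim = array(clim, c(nl, if (length(dms) > 3) dms[-(1:3)] else NULL)))
}

#' @export
drift_adjust.default <- function(x, ...) .drift_adjust_array(x)$anom

#' @export
drift_adjust.forecast_set <- function(x, ...) {
  adj <- lapply(x$vars, .drift_adjust_array)
  x$vars <- lapply(adj, `[[`, "anom")
  x$climatology <- lapply(adj, `[[`, "clim")
  x$adjusted <- TRUE
  x
}

#' Ensemble mean of a forecast array
#'
#' @param x a `forecast_set` or array with member as the second dimension.
#' @param ... unused.
#' @return same structure with the member dimension averaged out
#'   (`NA`-aware).
#' @export
ensemble_mean <- function(x, ...) UseMethod("ensemble_mean")

#' @export
ensemble_mean.default <- function(x, ...) {
  dms <- dim(x)
  out <- apply(x, seq_along(dms)[-2], mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' @export
ensemble_mean.forecast_set <- function(x, ...) {
  x$vars <- lapply(x$vars, ensemble_mean)
  x
}

#' Anomaly correlation coefficient (uncentered)
#'
#' The uncentered correlation of aligned anomaly series:
#' \eqn{\sum F'_i R'_{i}/\sqrt{\sum F_i'^2 \sum R_i'^2}}. No re-centering
#' is applied beyond the anomaly definition used to build the inputs, so
#' this matches the forecast-verification convention exactly (it equals
#' the Pearson correlation only when both series are mean-zero).
#'
#' @param f,r aligned numeric anomaly series (forecast and reference).
#' @return the ACC in \[-1, 1\]; `NA` (with a warning) when either series
#'   has no signal, or when fewer than 3 complete pairs remain.
#' @export
acc <- function(f, r) {
  ok <- !is.na(f) & !is.na(r)
  f <- f[ok]; r <- r[ok]
  if (length(f) < 3) return(NA_real_)
  sf <- sum(f^2); sr <- sum(r^2)
  if (sf == 0 || sr == 0) {
    warnf("zero variance in an anomaly series; ACC undefined")
    return(NA_real_)
  }
  sum(f * r) / sqrt(sf * sr)
}

#' Normalized mean absolute error
#'
#' Mean absolute difference of aligned anomaly series, normalized by the
#' interannual standard deviation of the reference anomalies at that lead:
#' \eqn{\frac{1}{N}\sum |F'_i - R'_i| / \sigma_{R'}}.
#'
#' @inheritParams acc
#' @return NMAE (>= 0); `NA` with a warning when the reference has zero
#'   standard deviation.
#' @export
nmae <- function(f, r) {
  ok <- !is.na(f) & !is.na(r)
  f <- f[ok]; r <- r[ok]
  if (length(f) < 3) return(NA_real_)
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) {
    warnf("zero reference standard deviation; NMAE undefined")
    return(NA_real_)
  }
  mean(abs(f - r)) / s
}

# lag-1 autocorrelation (mean-centered, biased normalization as in acf)
.lag1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(0)
  xc <- x - mean(x)
  d <- sum(xc^2)
  if (d == 0) return(0)
  sum(xc[-n] * xc[-1]) / d
}

#' Effective degrees of freedom of two autocorrelated series
#'
#' Lag-1 red-noise correction: `N_eff = N (1 - r1 r2) / (1 + r1 r2)`,
#' where `r1`, `r2` are the lag-1 autocorrelations of the two series.
#' The result is floored at 3 (so significance tests stay defined even
#' for pathologically persistent series) and capped at N.
#'
#' @param x,y numeric series (aligned; `NA` pairs dropped).
#' @return effective sample size.
#' @export
effective_dof <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  r1 <- .lag1(x[ok]); r2 <- .lag1(y[ok])
  n_eff <- n * (1 - r1 * r2) / (1 + r1 * r2)
  max(3, min(n, n_eff))
}

#' Significance of a correlation with effective degrees of freedom
#'
#' Student's t-test that the correlation is nonzero:
#' `t = r sqrt((N_eff - 2) / (1 - r^2))` referred to a t distribution with
#' `N_eff - 2` degrees of freedom (two-sided).
#'
#' @param r correlation (e.g. an ACC).
#' @param n_eff effective sample size (>= 3).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p` (two-sided) and `sig` (`p < alpha`);
#'   `|r| = 1` gives `p = 0` by convention, missing `r` gives `sig = FALSE`.
#' @export
acc_significance <- function(r, n_eff, alpha = 0.05) {
  if (is.na(r)) return(list(t = NA_real_, p = NA_real_, sig = FALSE))
  if (n_eff < 3) stopf("n_eff must be >= 3")
  if (abs(r) >= 1) return(list(t = Inf * sign(r), p = 0, sig = TRUE))
  tt <- r * sqrt((n_eff - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n_eff - 2)
  list(t = tt, p = p, sig = p < alpha)
}

#' One-sided test for a difference of dependent correlations
#'
#' Tests whether the forecast's correlation with a common reference series
#' exceeds the baseline's, accounting for the shared predictand
#' (Meng--Rosenthal--Rubin z-test for two correlations sharing one
#' variable), with the sample size replaced by an effective degrees of
#' freedom. `r_fp` is the correlation between the two predictor series.
#'
#' @param r_f forecast--reference correlation.
#' @param r_p baseline--reference correlation.
#' @param r_fp correlation between the two predictors (`NA` when undefined,
#'   e.g. a constant series, in which case the result is missing).
#' @param n_eff effective sample size.
#' @param alpha significance level (default 0.05).
#' @return list with `z`, one-sided `p` for `r_f > r_p`, and `sig`.
#' @export
acc_difference_test <- function(r_f, r_p, r_fp, n_eff, alpha = 0.05) {
  if (anyNA(c(r_f, r_p, r_fp)))
    return(list(z = NA_real_, p = NA_real_, sig = FALSE))
  clamp <- function(r) max(-0.999999, min(0.999999, r))
  r_f <- clamp(r_f); r_p <- clamp(r_p)
  rbar2 <- (r_f^2 + r_p^2) / 2
  f <- min(1, (1 - r_fp) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_f) - atanh(r_p)) *
    sqrt((n_eff - 3) / (2 * (1 - r_fp) * h))
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, sig = p < alpha)
}

#' Predictability timescale from a significance mask
#'
#' The number of consecutive significant leads starting at lead year 1;
#' later isolated significant runs are ignored (a mask significant at
#' leads 1--5 and 8--9 yields 5).
#'
#' @param sig logical vector over leads 1..L (`NA` treated as not
#'   significant).
#' @return integer timescale in years, 0 when lead 1 is not significant.
#' @export
predictability_timescale <- function(sig) {
  sig[is.na(sig)] <- FALSE
  run <- which(!sig)
  if (!length(run)) length(sig) else run[1] - 1L
}

#' Verify ensemble-mean forecasts against a reconstruction
#'
#' Aligns drift-adjusted ensemble-mean forecast anomalies with
#' reconstruction anomalies (a forecast initialized in year i at lead tau
#' verifies against year i + tau; pairs whose verification year falls
#' outside the record are dropped and counted), then computes per lead the
#' ACC, NMAE, and the significance of the ACC with effective degrees of
#' freedom, plus the predictability timescale.
#'
#' @param fcst matrix `(n_init, n_lead)` of ensemble-mean forecast
#'   anomalies (drift-adjusted).
#' @param init_years integer initialization years (rows of `fcst`).
#' @param recon numeric reconstruction yearly series; anomalies are formed
#'   internally by removing its full-period mean.
#' @param recon_years years of `recon`.
#' @param alpha significance level (default 0.05).
#' @return an object of class `skill_result`: list with a per-lead
#'   `table` (lead, n, acc, nmae, p, sig), `timescale`, `n_dropped`, and
#'   the significance settings.
#' @export
assess_skill <- function(fcst, init_years, recon, recon_years,
                         alpha = 0.05) {
  fcst <- as.matrix(fcst)
  if (nrow(fcst) != length(init_years))
    stopf("fcst must have one row per initialization year")
  ranom <- recon - mean(recon, na.rm = TRUE)
  n_lead <- ncol(fcst)
  tab <- data.frame(lead = seq_len(n_lead), n = NA_integer_,
                    acc = NA_real_, nmae = NA_real_, p = NA_real_,
                    sig = FALSE)
  dropped <- 0L
  for (tau in seq_len(n_lead)) {
    vy <- init_years + tau
    keep <- vy %in% recon_years
    dropped <- dropped + sum(!keep)
    f <- fcst[keep, tau]
    r <- ranom[match(vy[keep], recon_years)]
    tab$n[tau] <- sum(!is.na(f) & !is.na(r))
    tab$acc[tau] <- acc(f, r)
    tab$nmae[tau] <- nmae(f, r)
    st <- acc_significance(tab$acc[tau], effective_dof(f, r), alpha)
    tab$p[tau] <- st$p
    tab$sig[tau] <- st$sig
  }
  structure(list(table = tab,
                 timescale = predictability_timescale(tab$sig),
                 n_dropped = dropped, alpha = alpha,
                 neff_method = "lag1 red-noise (Bretherton)",
                 acc_convention = "uncentered anomaly product"),
            class = "skill_result")
}

#' @export
print.skill_result <- function(x, ...) {
  cat(sprintf("<skill_result> timescale = %d yr (alpha = %g)\n",
              x$timescale, x$alpha))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Persistence forecast skill of a reconstruction
#'
#' The persistence baseline predicts the reconstruction's yearly anomaly
#' at year i + tau by its own anomaly at year i, using the same ACC/NMAE
#' and significance machinery as the initialized forecasts.
#'
#' @param recon numeric reconstruction yearly series.
#' @param recon_years years of `recon`.
#' @param init_years predictor years (defaults to all years that verify
#'   inside the record at lead 1).
#' @param n_lead number of lead years.
#' @param alpha significance level.
#' @return a `skill_result`.
#' @export
persistence_skill <- function(recon, recon_years,
                              init_years = recon_years[-length(recon_years)],
                              n_lead = 10, alpha = 0.05) {
  if (length(recon) <= n_lead + 2)
    stopf("series too short for %d lead years", n_lead)
  ranom <- recon - mean(recon, na.rm = TRUE)
  pred <- ranom[match(init_years, recon_years)]
  fcst <- matrix(pred, nrow = length(init_years), ncol = n_lead)
  assess_skill(fcst, init_years, recon, recon_years, alpha = alpha)
}

#' Initialized-forecast skill versus the persistence baseline
#'
#' Computes the skill of ensemble-mean initialized forecasts and of the
#' persistence baseline on the same verification years, their ACC
#' difference per lead, and the one-sided significance of the improvement
#' with the dependent-correlation test (the two ACCs share the
#' reconstruction as predictand; the inter-predictor correlation is
#' estimated from the aligned predictor series and the effective degrees
#' of freedom is the smaller of the two pairwise values).
#'
#' @inheritParams assess_skill
#' @return an object of class `skill_comparison`: `table` with per-lead
#'   columns for both forecasts plus `delta_acc`, `p_delta`, `sig_delta`,
#'   and the two timescales.
#' @export
skill_vs_persistence <- function(fcst, init_years, recon, recon_years,
                                 alpha = 0.05) {
  sk_f <- assess_skill(fcst, init_years, recon, recon_years, alpha)
  ranom <- recon - mean(recon, na.rm = TRUE)
  pred <- ranom[match(init_years, recon_years)]
  n_lead <- ncol(as.matrix(fcst))
  pmat <- matrix(pred, nrow = length(init_years), ncol = n_lead)
  sk_p <- assess_skill(pmat, init_years, recon, recon_years, alpha)
  tab <- data.frame(
    lead = sk_f$table$lead, n = sk_f$table$n,
    acc_dple = sk_f$table$acc, nmae_dple = sk_f$table$nmae,
    p_dple = sk_f$table$p, sig_dple = sk_f$table$sig,
    acc_pers = sk_p$table$acc, nmae_pers = sk_p$table$nmae,
    p_pers = sk_p$table$p, sig_pers = sk_p$table$sig)
  tab$delta_acc <- tab$acc_dple - tab$acc_pers
  tab$p_delta <- NA_real_; tab$sig_delta <- FALSE
  fm <- as.matrix(fcst)
  for (tau in seq_len(n_lead)) {
    vy <- init_years + tau
    keep <- vy %in% recon_years
    f <- fm[keep, tau]; p <- pmat[keep, tau]
    r <- ranom[match(vy[keep], recon_years)]
    ok <- !is.na(f) & !is.na(p)
    r_fp <- if (sum(ok) >= 3 && stats::sd(f[ok]) > 0 && stats::sd(p[ok]) > 0)
      stats::cor(f[ok], p[ok]) else NA_real_
    n_eff <- min(effective_dof(f, r), effective_dof(p, r))
    dt <- acc_difference_test(tab$acc_dple[tau], tab$acc_pers[tau],
                              r_fp, n_eff, alpha)
    tab$p_delta[tau] <- dt$p
    tab$sig_delta[tau] <- dt$sig
  }
  structure(list(table = tab,
                 timescale_dple = sk_f$timescale,
                 timescale_pers = sk_p$timescale,
                 n_dropped = sk_f$n_dropped, alpha = alpha),
            class = "skill_comparison")
}

#' @export
print.skill_comparison <- function(x, ...) {
  cat(sprintf(
    "<skill_comparison> timescale: forecast %d yr, persistence %d yr (alpha = %g)\n",
    x$timescale_dple, x$timescale_pers, x$alpha))
  print(x$table[, c("lead", "acc_dple", "acc_pers", "delta_acc",
                    "p_delta", "sig_delta")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-cell skill maps
#'
#' Applies the ACC/NMAE/significance machinery independently at every
#' ocean grid cell of yearly fields, for map-style diagnostics.
#'
#' @param phi_fcst ensemble-mean drift-adjusted forecast anomalies,
#'   array `(init, lead, depth, lat, lon)`.
#' @param init_years initialization years.
#' @param phi_recon yearly reconstruction field `(year, depth, lat, lon)`
#'   (anomalies formed per cell internally).
#' @param recon_years years of the reconstruction field.
#' @param alpha significance level.
#' @return list of arrays `acc`, `nmae`, `p`, `sig` over
#'   `(lead, depth, lat, lon)` and a `timescale` array over
#'   `(depth, lat, lon)`.
#' @export
skill_maps <- function(phi_fcst, init_years, phi_recon, recon_years,
                       alpha = 0.05) {
  df <- dim(phi_fcst); dr <- dim(phi_recon)
  if (!identical(df[-(1:2)], dr[-1]))
    stopf("forecast and reconstruction grids differ")
  n_lead <- df[2]
  ncell <- prod(dr[-1])
  fm <- array(phi_fcst, c(df[1], n_lead, ncell))
  rm_ <- matrix(phi_recon, nrow = dr[1])
  out <- lapply(c(acc = 1, nmae = 1, p = 1),
                function(.) array(NA_real_, c(n_lead, ncell)))
  sig <- array(FALSE, c(n_lead, ncell))
  ts <- rep(NA_integer_, ncell)
  for (c_ in seq_len(ncell)) {
    rser <- rm_[, c_]
    if (all(is.na(rser))) next
    sk <- assess_skill(fm[, , c_, drop = TRUE], init_years,
                       rser, recon_years, alpha)
    out$acc[, c_] <- sk$table$acc
    out$nmae[, c_] <- sk$table$nmae
    out$p[, c_] <- sk$table$p
    sig[, c_] <- sk$table$sig
    ts[c_] <- sk$timescale
  }
  shape <- c(n_lead, dr[-1])
  list(acc = array(out$acc, shape), nmae = array(out$nmae, shape),
       p = array(out$p, shape), sig = array(sig, shape),
       timescale = array(ts, dr[-1]))
}
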