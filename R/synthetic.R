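#' Parameters of the synthetic reconstruction / hindcast generator
#'
#' Prescribes the full statistical structure of the synthetic world:
#' red-noise (AR(1)) yearly anomalies per variable with cross-variable
#' coupling, within-year monthly white noise, mean vertical climatology
#' profiles, a lead-dependent forecast skill schedule, a removable
#' lead-dependent drift, and the ensemble geometry. These defaults are the
#' fixed study conditions of the package's synthetic experiments.
#'
#' @param ar1 named vector `c(T=, S=, O2=)` of AR(1) coefficients of the
#'   yearly anomalies, each in `[0, 1)`.
#' @param sd named vector of stationary interannual anomaly standard
#'   deviations (degC, psu, mmol/m^3); all positive.
#' @param monthly_sd named vector of within-year monthly white-noise
#'   standard deviations.
#' @param coupling 3x3 correlation matrix (order T, S, O2) of the
#'   *stationary yearly anomalies*. The generator converts it to the
#'   innovation correlation `rho_inn = rho * (1 - a_j a_k) /
#'   sqrt((1 - a_j^2)(1 - a_k^2))` so that the target is met exactly in
#'   population. The default couples warm anomalies with low oxygen.
#' @param clim list of climatology profiles `T`, `S`, `O2`: functions of
#'   depth (m) or vectors per depth level; the O2 profile must be
#'   non-negative.
#' @param alpha forecast--truth correlation schedule: either a vector over
#'   leads (shared by all variables) or an `n_leads x 3` matrix with
#'   columns T, S, O2. Each schedule must lie in `[0, 1]` and be
#'   non-increasing in lead.
#' @param drift lead-dependent mean drift added to every member and init:
#'   vector over leads or `n_leads x 3` matrix (units of each variable).
#' @param bias named member-independent constant offset per variable.
#' @param n_members ensemble size (>= 2 for a meaningful ensemble).
#' @param n_inits number of initialization years.
#' @param n_leads number of forecast lead years.
#' @param seed integer seed governing all generator randomness.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(ar1 = c(T = 0.5, S = 0.6, O2 = 0.7),
                         sd = c(T = 0.5, S = 0.1, O2 = 10),
                         monthly_sd = c(T = 0.3, S = 0.05, O2 = 5),
                         coupling = rbind(c(1, 0.2, -0.6),
                                          c(0.2, 1, 0),
                                          c(-0.6, 0, 1)),
                         clim = list(T = function(z) 4 + 14 * exp(-z / 200),
                                     S = function(z) 34 + 0.5 * exp(-z / 300),
                                     O2 = function(z) 80 + 150 * exp(-z / 250)),
                         alpha = 0.9^seq_len(n_leads),
                         drift = cbind(T = 0.3 * seq_len(n_leads) / n_leads,
                                       S = 0.02 * seq_len(n_leads) / n_leads,
                                       O2 = -5 * seq_len(n_leads) / n_leads),
                         bias = c(T = 0, S = 0, O2 = 0),
                         n_members = 10, n_inits = 64, n_leads = 10,
                         seed = 42) {
  v <- c("T", "S", "O2")
  ar1 <- ar1[v]; sd <- sd[v]; monthly_sd <- monthly_sd[v]; bias <- bias[v]
  if (any(is.na(ar1)) || any(ar1 < 0) || any(ar1 >= 1))
    stopf("ar1 coefficients must be named (T, S, O2) and lie in [0, 1)")
  if (any(is.na(sd)) || any(sd < 0)) stopf("anomaly sds must be non-negative")
  if (any(is.na(monthly_sd)) || any(monthly_sd < 0))
    stopf("monthly sds must be non-negative")
  coupling <- unname(as.matrix(coupling))
  if (!isTRUE(all.equal(coupling, t(coupling))) ||
      !isTRUE(all.equal(diag(coupling), rep(1, 3))))
    stopf("coupling must be a symmetric 3x3 correlation matrix")
  if (is.null(dim(alpha))) alpha <- matrix(alpha, length(alpha), 3)
  colnames(alpha) <- v
  if (nrow(alpha) != n_leads)
    stopf("alpha schedule must cover %d leads", n_leads)
  if (any(alpha < 0) || any(alpha > 1) ||
      any(apply(alpha, 2, function(x) any(diff(x) > 1e-12))))
    stopf("alpha must lie in [0, 1] and be non-increasing in lead")
  if (is.null(dim(drift))) drift <- matrix(drift, length(drift), 3)
  colnames(drift) <- v
  if (nrow(drift) != n_leads) stopf("drift must cover %d leads", n_leads)
  if (n_inits < 1 || n_leads < 1) stopf("need at least one init and lead")
  structure(list(ar1 = ar1, sd = sd, monthly_sd = monthly_sd,
                 coupling = coupling, clim = clim, alpha = alpha,
                 drift = drift, bias = bias, n_members = n_members,
                 n_inits = n_inits, n_leads = n_leads, seed = seed),
            class = "synth_params")
}

# resolve climatology profiles on the grid's depth levels
.resolve_clim <- function(params, grid) {
  out <- lapply(c(T = "T", S = "S", O2 = "O2"), function(v) {
    p <- params$clim[[v]]
    prof <- if (is.function(p)) p(grid$depth) else p
    if (length(prof) != length(grid$depth))
      stopf("climatology profile for %s must match the depth axis", v)
    prof
  })
  if (any(out$O2 < 0)) stopf("O2 climatology must be non-negative")
  out
}

# Cholesky-like factor tolerating zero-variance variables: rows/columns of
# variables with zero sd are zero, the positive block is factored normally
.safe_chol <- function(sigma) {
  d <- sqrt(diag(sigma))
  U <- matrix(0, nrow(sigma), ncol(sigma))
  pos <- which(d > 0)
  if (length(pos))
    U[pos, pos] <- chol(sigma[pos, pos, drop = FALSE])
  U
}

# innovation Cholesky factor achieving the target stationary coupling
.innovation_chol <- function(params) {
  a <- params$ar1; s <- params$sd; R <- params$coupling
  fac <- outer(1 - a^2, 1 - a^2, function(x, y) sqrt(x * y)) /
    (1 - outer(a, a))
  rho_inn <- R / fac
  diag(rho_inn) <- 1
  s_inn <- s * sqrt(1 - a^2)
  sigma <- diag(s_inn) %*% rho_inn %*% diag(s_inn)
  tryCatch(.safe_chol(sigma),
           error = function(e) stopf(
             "coupling matrix incompatible with the AR(1) coefficients (innovation covariance not positive definite)"))
}

# set land columns (NA in the region mask) to NA; x has (lat, lon) as the
# last two dimensions
.mask_land <- function(x, grid) {
  land <- which(is.na(as.vector(grid$region)))
  if (!length(land)) return(x)
  dms <- dim(x)
  nc <- length(grid$lat) * length(grid$lon)
  xm <- matrix(x, ncol = nc)
  xm[, land] <- NA_real_
  array(xm, dim = dms)
}

#' Generate a synthetic multi-decadal monthly reconstruction
#'
#' Builds monthly T/S/O2 fields as climatology profile plus a yearly
#' AR(1) anomaly (shared within the year) plus monthly white noise, at
#' every ocean cell. Yearly anomalies follow per-variable AR(1) processes
#' whose innovations are cross-correlated so the stationary anomalies
#' attain the prescribed coupling. The process is started from its
#' stationary distribution. Negative O2 values are clipped to zero and
#' counted. Deterministic given the seed; the true yearly anomalies are
#' stored in the result for ground-truth checks.
#'
#' @param grid a [grid_spec].
#' @param params a [synth_params].
#' @param n_years number of years to generate; the default covers every
#'   (init, lead) verification.
#' @param start_year first calendar year label.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a [hydro_field] with monthly fields and an `anomalies` slot
#'   (per-variable yearly anomaly arrays plus their year labels).
#' @export
generate_reconstruction <- function(grid, params,
                                    n_years = params$n_inits + params$n_leads,
                                    start_year = 1954,
                                    seed = params$seed) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "synth_params"))
  clim <- .resolve_clim(params, grid)
  U <- .innovation_chol(params)
  v <- c("T", "S", "O2")
  nd <- length(grid$depth); nla <- length(grid$lat); nlo <- length(grid$lon)
  ncell <- nd * nla * nlo
  ny <- n_years
  mpy <- grid$months_per_year
  with_seed(seed, {
    # stationary start
    sig_stat <- diag(params$sd) %*% params$coupling %*% diag(params$sd)
    A <- matrix(rnorm(ncell * 3), ncell, 3) %*% .safe_chol(sig_stat)
    ann <- lapply(v, function(.) array(NA_real_, c(ny, nd, nla, nlo)))
    names(ann) <- v
    for (y in seq_len(ny)) {
      A <- sweep(A, 2, params$ar1, "*") +
        matrix(rnorm(ncell * 3), ncell, 3) %*% U
      for (j in 1:3) ann[[j]][y, , , ] <- A[, j]
    }
    fields <- list()
    n_clipped <- 0L
    for (j in 1:3) {
      base <- ann[[j]][rep(seq_len(ny), each = mpy), , , , drop = FALSE]
      x <- sweep(base, 2, clim[[j]], "+") +
        rnorm(length(base), sd = params$monthly_sd[j])
      x <- .mask_land(x, grid)
      if (v[j] == "O2") {
        neg <- which(x < 0)
        n_clipped <- length(neg)
        if (n_clipped > 0) x[neg] <- 0
      }
      fields[[v[j]]] <- x
      ann[[j]] <- .mask_land(ann[[j]], grid)
    }
    if (n_clipped > 0)
      message(sprintf("generate_reconstruction: clipped %d negative O2 value(s) to 0",
                      n_clipped))
    yrs <- as.integer(start_year) - 1L + seq_len(ny)
    hydro_field(grid, T = fields$T, S = fields$S, O2 = fields$O2,
                years = rep(yrs, each = mpy),
                months = rep(seq_len(mpy), ny),
                anomalies = c(ann, list(years = yrs)),
                n_clipped = n_clipped)
  })
}

#' Population ensemble-mean anomaly correlation of the generator
#'
#' For synthetic forecasts built as `alpha * truth +
#' sqrt(1 - alpha^2) * noise` per member (truth and noise of equal
#' variance), averaging M members shrinks the noise variance by 1/M, so
#' the population correlation of the ensemble mean with truth is
#' `alpha / sqrt(alpha^2 + (1 - alpha^2) / M)`, which exceeds the
#' single-member skill `alpha` whenever `M > 1` and `0 < alpha < 1`.
#'
#' @param alpha prescribed single-member forecast--truth correlation(s).
#' @param n_members ensemble size M.
#' @return population anomaly correlation of the ensemble mean.
#' @export
ensemble_mean_acc <- function(alpha, n_members) {
  alpha / sqrt(alpha^2 + (1 - alpha^2) / n_members)
}

#' Generate initialized synthetic ensemble forecasts
#'
#' For each init year i, member m and lead year tau, the yearly forecast
#' anomaly of each variable is `alpha(tau) * truth(i + tau) +
#' sqrt(1 - alpha(tau)^2) * sd * noise(m) + drift(tau) + bias`, where
#' `truth` is the reconstruction's stored yearly anomaly, noise is
#' independent standard Gaussian per member, `drift` is a deterministic
#' lead-dependent offset common to all members and inits (removable by
#' [drift_adjust]) and `bias` a member-independent constant. Full fields
#' add the climatology profile; negative O2 is clipped at zero. The
#' population correlation of the ensemble mean with truth follows
#' [ensemble_mean_acc]. Deterministic given the seed.
#'
#' @param recon a reconstruction from [generate_reconstruction] (its
#'   stored yearly anomalies are the forecast target).
#' @param params a [synth_params].
#' @param seed RNG seed (defaults to `params$seed + 1000`).
#' @return a `forecast_set`: per-variable arrays on
#'   `(init, member, lead, depth, lat, lon)`, unadjusted (drift still in).
#' @export
generate_forecasts <- function(recon, params, seed = params$seed + 1000L) {
  stopifnot(inherits(recon, "hydro_field"), inherits(params, "synth_params"))
  if (params$n_members < 2)
    stopf("an ensemble needs at least 2 members (got %d)", params$n_members)
  grid <- recon$grid
  if (is.null(recon$anomalies))
    stopf("reconstruction carries no stored yearly anomalies")
  ny <- length(recon$anomalies$years)
  ni <- params$n_inits; nm <- params$n_members; nl <- params$n_leads
  if (ni + nl > ny)
    stopf("reconstruction too short: need %d years to verify every (init, lead), have %d",
          ni + nl, ny)
  clim <- .resolve_clim(params, grid)
  nd <- length(grid$depth); nla <- length(grid$lat); nlo <- length(grid$lon)
  ncell <- nd * nla * nlo
  v <- c("T", "S", "O2")
  with_seed(seed, {
    vars <- list()
    n_clipped <- 0L
    for (j in 1:3) {
      truth <- matrix(recon$anomalies[[j]], nrow = ny)  # (year, cell)
      Fv <- array(NA_real_, c(ni, nm, nl, nd, nla, nlo))
      for (tau in seq_len(nl)) {
        al <- params$alpha[tau, j]
        tr <- truth[seq_len(ni) + tau, , drop = FALSE]        # (init, cell)
        t3 <- aperm(array(tr, c(ni, ncell, nm)), c(1, 3, 2))  # (init, member, cell)
        noise <- array(rnorm(ni * nm * ncell), c(ni, nm, ncell))
        Fv[, , tau, , , ] <- al * t3 +
          sqrt(1 - al^2) * params$sd[j] * noise +
          params$drift[tau, j] + params$bias[j]
      }
      Fv <- .mask_land(sweep(Fv, 4, clim[[j]], "+"), grid)
      if (v[j] == "O2") {
        neg <- which(Fv < 0)
        n_clipped <- length(neg)
        if (n_clipped > 0) Fv[neg] <- 0
      }
      vars[[v[j]]] <- Fv
    }
    if (n_clipped > 0)
      message(sprintf("generate_forecasts: clipped %d negative O2 value(s) to 0",
                      n_clipped))
    structure(list(grid = grid, vars = vars,
                   init_years = recon$anomalies$years[seq_len(ni)],
                   leads = seq_len(nl), adjusted = FALSE,
                   alpha = params$alpha, n_clipped = n_clipped),
              class = "forecast_set")
  })
}
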