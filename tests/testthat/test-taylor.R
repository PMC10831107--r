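tr <- trait_set(A_c = 10, E_o = 0.4)

random_states <- function(n, seed = 20) {
  set.seed(seed)
  list(T = runif(n, 0, 25), S = runif(n, 31, 37), O2 = runif(n, 20, 320))
}

test_that("analytic partials match centered finite differences", {
  st <- random_states(25)
  pp <- phi_partials(st$T, st$S, st$O2, tr)
  for (i in seq_len(25)) {
    fd <- phi_fd_partials(st$T[i], st$S[i], st$O2[i], tr)
    expect_lt(abs(pp$dO2[i] - fd$dO2) / abs(fd$dO2), 1e-6)
    expect_lt(abs(pp$dT[i] - fd$dT) / abs(fd$dT), 1e-6)
    expect_lt(abs(pp$dS[i] - fd$dS) / abs(fd$dS), 1e-6)
  }
  # signs: more oxygen and more salt both raise phi
  expect_true(all(pp$dO2 > 0))
  expect_true(all(pp$dS > 0))
  # dphi/dO2 equals the closed form A_c x 0.209 / O2sol
  expect_equal(pp$dO2, 10 * 0.209 * exp(
    effective_eo(st$T, tr) / tr$k_B *
      (1 / (st$T + 273.15) - 1 / tr$T_ref)) / o2_solubility(st$T, st$S),
    tolerance = 1e-12)
  # missing state gives missing partials
  expect_true(all(is.na(unlist(phi_partials(NA_real_, 35, 200, tr)))))
})

test_that("constant drivers decompose to nothing but the mean", {
  d <- taylor_decompose(rep(10, 5), rep(35, 5), rep(200, 5), tr)
  expect_lt(max(abs(d$phi_O2)), 1e-14)
  expect_lt(max(abs(d$phi_T)), 1e-14)
  expect_lt(max(abs(d$phi_S)), 1e-14)
  expect_lt(max(abs(d$residual)), 1e-12)
  expect_equal(as.numeric(d$phi[1]), as.numeric(d$phi_bar))
})

test_that("an O2-only perturbation is captured exactly by the O2 component", {
  set.seed(22)
  n <- 24
  O2 <- 200 + rnorm(n, sd = 15)
  d <- taylor_decompose(rep(10, n), rep(35, n), O2, tr)
  expect_lt(max(abs(d$phi_T)), 1e-14)
  expect_lt(max(abs(d$phi_S)), 1e-14)
  # phi is linear in O2, so the first-order term is exact
  expect_equal(as.numeric(d$phi_O2),
               as.numeric(d$phi) - as.numeric(d$phi_bar),
               tolerance = 1e-12)
  expect_lt(max(abs(d$residual)), 1e-12)
})

test_that("components are mean-zero and the residual shrinks as epsilon^2", {
  set.seed(23)
  n <- 30
  base <- list(T = 10 + rnorm(n), S = 35 + 0.2 * rnorm(n),
               O2 = 200 + 20 * rnorm(n))
  d0 <- taylor_decompose(base$T, base$S, base$O2, tr)
  for (cmp in list(d0$phi_O2, d0$phi_T, d0$phi_S))
    expect_lt(abs(mean(cmp)), 1e-13)
  eps <- 2^-(0:4)
  resid <- vapply(eps, function(e) {
    d <- taylor_decompose(10 + e * (base$T - 10), 35 + e * (base$S - 35),
                          200 + e * (base$O2 - 200), tr)
    sqrt(mean(d$residual^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(resid) ~ log(eps)))[2]
  expect_lt(abs(slope - 2), 0.1)
})

test_that("the solubility/AOU split closes to machine precision", {
  set.seed(24)
  n <- 50
  d <- taylor_decompose(10 + rnorm(n), 35 + 0.3 * rnorm(n),
                        200 + 25 * rnorm(n), tr)
  sp <- split_o2_component(d)
  rel <- sp$max_abs_error / max(abs(d$phi_O2))
  expect_lt(rel, 1e-12)
  # switch-off cases: constant T, S make the solubility component vanish
  dO <- taylor_decompose(rep(10, n), rep(35, n), 200 + 25 * rnorm(n), tr)
  expect_lt(max(abs(dO$phi_O2sol)), 1e-14)
  expect_equal(dO$phi_O2, dO$phi_AOU, tolerance = 1e-14)
})

test_that("the variance budget closes where algebra says it must", {
  set.seed(25)
  n <- 40
  d <- taylor_decompose(8 + rnorm(n), 34 + 0.3 * rnorm(n),
                        180 + 25 * rnorm(n), tr)
  vb <- variance_budget(d)
  # oxygen sub-budget closes exactly (variance of a sum)
  expect_equal(vb$var_O2, vb$var_O2sol + vb$var_AOU + 2 * vb$cov_O2sol_AOU,
               tolerance = 1e-12)
  # O2-T covariance splits exactly
  expect_equal(vb$cov_O2_T, vb$cov_O2sol_T + vb$cov_AOU_T,
               tolerance = 1e-12)
  # full budget: linear terms + residual term reproduce var(phi)
  lin <- vb$var_O2 + vb$var_T + vb$var_S +
    2 * (vb$cov_O2_T + vb$cov_O2_S + vb$cov_T_S)
  expect_equal(vb$var_phi, lin + vb$residual_term, tolerance = 1e-12)
  # perfect anticorrelation shows up as 2cov = -2 var
  x <- rnorm(n)
  v1 <- stats::var(x); v2 <- stats::var(-x); cv <- stats::cov(x, -x)
  expect_equal(v1 + v2 + 2 * cv, 0, tolerance = 1e-12)
})

test_that("independent drivers give near-zero component covariances", {
  g <- tiny_grid()
  p <- synth_params(coupling = diag(3), n_inits = 490, n_leads = 10,
                    seed = 26)
  r <- quiet_recon(g, p, n_years = 500)
  ry <- annual_mean(r)
  d <- taylor_decompose(
    layer_region_average(ry$vars$T, g, "full", 1),
    layer_region_average(ry$vars$S, g, "full", 1),
    layer_region_average(ry$vars$O2, g, "full", 1), tr)
  vb <- variance_budget(d)
  # normalized covariances are small at n = 500
  expect_lt(abs(vb$cov_O2_T) / sqrt(vb$var_O2 * vb$var_T), 0.12)
  expect_lt(abs(vb$cov_O2_S) / sqrt(vb$var_O2 * vb$var_S), 0.12)
})

test_that("phi_bar conventions differ by the nonlinearity only", {
  set.seed(27)
  n <- 25
  Ts <- 10 + rnorm(n); Ss <- 35 + 0.2 * rnorm(n); Os <- 200 + 20 * rnorm(n)
  d1 <- taylor_decompose(Ts, Ss, Os, tr, phi_bar = "phi_of_mean")
  d2 <- taylor_decompose(Ts, Ss, Os, tr, phi_bar = "mean_phi")
  expect_equal(as.numeric(d2$phi_bar), mean(d1$phi))
  expect_false(isTRUE(all.equal(as.numeric(d1$phi_bar),
                                as.numeric(d2$phi_bar))))
  # components are identical; only phi_bar and residual shift
  expect_equal(d1$phi_O2, d2$phi_O2)
})

test_that("a component equal to the predictand verifies perfectly", {
  set.seed(28)
  n <- 30; n_lead <- 3
  r <- rnorm(n + n_lead)
  years <- seq_len(n + n_lead)
  ranom <- r - mean(r)
  clim <- list(T = rep(10, n_lead), S = rep(35, n_lead),
               O2 = rep(200, n_lead))
  pp <- phi_partials(clim$T, clim$S, clim$O2, tr)
  o2_anom <- sapply(seq_len(n_lead), function(tau)
    ranom[seq_len(n) + tau] / pp$dO2[tau])
  anoms <- list(T = matrix(rnorm(n * n_lead), n), S = matrix(0, n, n_lead),
                O2 = o2_anom)
  cs <- suppressWarnings(component_skill(anoms, clim, seq_len(n), r, years, tr))
  expect_true(all(cs$O2$table$acc > 1 - 1e-12))
  expect_equal(cs$O2$timescale, n_lead)
  expect_true(all(abs(cs$S$table$acc) < 1e-12 | is.na(cs$S$table$acc)))
})
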