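test_that("drift adjustment removes the lead-dependent climatology exactly", {
  set.seed(5)
  x <- array(rnorm(8 * 4 * 3 * 6), c(8, 4, 3, 6))
  drift <- c(0.5, 1.0, -2.0)
  xd <- sweep(x, 3, drift, "+")
  a <- drift_adjust(xd)
  # mean over (init, member) is zero at every (lead, cell)
  mus <- apply(a, c(3, 4), mean)
  expect_lt(max(abs(mus)), 1e-12)
  # a constant lead-dependent drift is removed exactly
  expect_equal(a, drift_adjust(x), tolerance = 1e-12)
  # idempotence on already mean-zero input
  expect_equal(drift_adjust(a), a, tolerance = 1e-12)
  expect_error(drift_adjust(array(1, c(1, 4, 3))), "2 initialization")
})

test_that("ACC implements the uncentered anomaly product", {
  expect_equal(acc(c(1, 2, -3), c(1, 2, -3)), 1)
  expect_equal(acc(c(1, 2, -3), -c(1, 2, -3)), -1)
  # hand evaluation: (0 + 0 + 1) / sqrt(2 * 2) = 0.5
  expect_equal(acc(c(1, 0, -1), c(0, 1, -1)), 0.5)
  # not a re-centered Pearson correlation on non-mean-zero series
  f <- c(1, 2, 3); r <- c(1, 2, 4)
  expect_equal(acc(f, r), sum(f * r) / sqrt(sum(f^2) * sum(r^2)))
  expect_false(isTRUE(all.equal(acc(f, r), stats::cor(f, r))))
  # positive rescaling of the forecast leaves ACC unchanged (A_c cancels)
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(acc(7.3 * a, b), acc(a, b))
  expect_warning(expect_true(is.na(acc(c(0, 0, 0), c(1, 2, 3)))),
                 "zero variance")
})

test_that("NMAE normalizes absolute error by the reference spread", {
  set.seed(7)
  r <- rnorm(40)
  expect_equal(nmae(r, r), 0)
  # constant offset of one reference sd gives exactly 1
  expect_equal(nmae(r + stats::sd(r), r), 1)
  # climatology (zero) forecast of unit-variance noise -> E|Z| = sqrt(2/pi)
  z <- rnorm(20000)
  expect_lt(abs(nmae(rep(0, 20000), z) - sqrt(2 / pi)), 0.02)
  expect_warning(expect_true(is.na(nmae(c(1, 2, 3), c(2, 2, 2)))),
                 "zero reference")
})

test_that("effective degrees of freedom follow the lag-1 red-noise form", {
  set.seed(9)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 200))
  y <- as.numeric(stats::arima.sim(list(ar = 0.7), 200))
  r1 <- aerohab:::.lag1(x); r2 <- aerohab:::.lag1(y)
  expect_equal(effective_dof(x, y), 200 * (1 - r1 * r2) / (1 + r1 * r2))
  # white noise loses almost nothing
  w1 <- rnorm(300); w2 <- rnorm(300)
  expect_gt(effective_dof(w1, w2), 250)
  expect_lte(effective_dof(w1, w2), 300)
  # floor at 3 for pathologically persistent series
  expect_gte(effective_dof(sin((1:50) / 50), sin((1:50) / 50)), 3)
  expect_lt(effective_dof(1:1000, 1:1000), 4)
})

test_that("correlation significance matches the t distribution", {
  s0 <- acc_significance(0, 30)
  expect_equal(s0$p, 1)
  expect_false(s0$sig)
  # r = 0.5 with N_eff = 20: t = 0.5 sqrt(18 / 0.75) = 2.449, p ~ 0.0247
  s <- acc_significance(0.5, 20)
  expect_equal(s$t, 0.5 * sqrt(18 / 0.75), tolerance = 1e-12)
  expect_equal(s$p, 0.024770, tolerance = 1e-4)
  expect_true(s$sig)
  expect_true(acc_significance(0.99, 50)$sig)
  expect_equal(acc_significance(1, 10)$p, 0)
  expect_false(acc_significance(NA_real_, 10)$sig)
})

test_that("the dependent-correlation improvement test behaves sanely", {
  expect_equal(acc_difference_test(0.6, 0.6, 0.5, 50)$p, 0.5)
  expect_false(acc_difference_test(0.6, 0.6, 0.5, 50)$sig)
  expect_true(acc_difference_test(0.9, 0.0, 0.1, 60)$sig)
  expect_true(is.na(acc_difference_test(0.5, 0.3, NA, 60)$p))
})

test_that("the improvement test holds its size under the null", {
  # trivariate Gaussian, both predictors equally correlated with the
  # predictand: rejection at the 5% one-sided level stays near nominal
  rho_xr <- 0.5; rho_yr <- 0.5; rho_xy <- 0.6
  Sig <- rbind(c(1, rho_xy, rho_xr), c(rho_xy, 1, rho_yr),
               c(rho_xr, rho_yr, 1))
  U <- chol(Sig)
  n <- 100; reps <- 500
  set.seed(41)
  rej <- 0L
  for (i in seq_len(reps)) {
    z <- matrix(rnorm(3 * n), n, 3) %*% U
    rf <- acc(z[, 1] - mean(z[, 1]), z[, 3] - mean(z[, 3]))
    rp <- acc(z[, 2] - mean(z[, 2]), z[, 3] - mean(z[, 3]))
    dt <- acc_difference_test(rf, rp, stats::cor(z[, 1], z[, 2]), n)
    rej <- rej + dt$sig
  }
  expect_lt(abs(rej / reps - 0.05), 0.03)
})

test_that("predictability timescale is the significant prefix length", {
  expect_equal(predictability_timescale(
    c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)), 5L)
  expect_equal(predictability_timescale(c(FALSE, TRUE, TRUE)), 0L)
  expect_equal(predictability_timescale(rep(TRUE, 10)), 10L)
  expect_equal(predictability_timescale(c(TRUE, NA, TRUE)), 1L)
})

test_that("persistence of an AR(1) series matches its autocorrelation", {
  set.seed(10)
  a <- 0.6; n <- 500
  x <- as.numeric(stats::arima.sim(list(ar = a), n))
  years <- seq_len(n)
  sk <- persistence_skill(x, years, n_lead = 3)
  for (tau in 1:3) {
    halfwidth <- 1.96 / sqrt(sk$table$n[tau] - 3)
    expect_lt(abs(atanh(sk$table$acc[tau]) - atanh(a^tau)), halfwidth)
  }
})

test_that("persistence of a period-2 series is perfect at lead 2", {
  x <- rep(c(1, -1), 25)
  sk <- persistence_skill(x, seq_len(50), n_lead = 2)
  expect_equal(sk$table$acc[2], 1)
  expect_equal(sk$table$acc[1], -1)
})

test_that("white-noise persistence stays at the nominal false-positive rate", {
  set.seed(12)
  hits <- 0L; total <- 0L
  for (i in 1:60) {
    x <- rnorm(60)
    sk <- persistence_skill(x, 1:60, n_lead = 5)
    hits <- hits + sum(sk$table$sig)
    total <- total + 5L
  }
  expect_lt(hits / total, 0.12)
})

test_that("a perfect forecast is the fixed point of verification", {
  set.seed(13)
  n <- 40; n_lead <- 4
  r <- rnorm(n + n_lead)
  years <- seq_len(n + n_lead)
  ranom <- r - mean(r)
  fcst <- sapply(seq_len(n_lead), function(tau) ranom[seq_len(n) + tau])
  cmp <- skill_vs_persistence(fcst, seq_len(n), r, years)
  expect_true(all(cmp$table$acc_dple == 1))
  expect_true(all(cmp$table$nmae_dple < 1e-12))
  expect_true(all(cmp$table$sig_dple))
  expect_equal(cmp$timescale_dple, n_lead)
})

test_that("forecasts verifying beyond the record are dropped and counted", {
  set.seed(14)
  r <- rnorm(30)
  fcst <- matrix(rnorm(28 * 3), 28, 3)
  sk <- assess_skill(fcst, seq_len(28), r, seq_len(30))
  expect_equal(sk$table$n, c(28L, 28L, 27L))
  expect_equal(sk$n_dropped, 1L)
})

test_that("per-cell skill maps agree with series verification", {
  g <- small_grid(n_depth = 2)
  p <- synth_params(n_members = 4, n_inits = 20, n_leads = 3, seed = 15)
  r <- quiet_recon(g, p)
  f <- quiet_fcst(r, p)
  tr <- trait_set(10, 0.4)
  phi_ry <- annual_mean(metabolic_index(r, tr))
  phi_f <- ensemble_mean(drift_adjust(metabolic_index(f, tr)$phi))
  maps <- skill_maps(phi_f, f$init_years, phi_ry$phi, phi_ry$years)
  expect_identical(dim(maps$acc), c(3L, 2L, 2L, 2L))
  # one cell cross-checked against the series machinery
  sk <- assess_skill(phi_f[, , 1, 2, 2], f$init_years,
                     phi_ry$phi[, 1, 2, 2], phi_ry$years)
  expect_equal(maps$acc[, 1, 2, 2], sk$table$acc)
  expect_equal(maps$timescale[1, 2, 2], sk$timescale)
})
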