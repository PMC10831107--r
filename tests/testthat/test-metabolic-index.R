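tr_med <- trait_set(A_c = 10, E_o = 0.4)

test_that("effective E_o applies the linear temperature correction", {
  expect_equal(effective_eo(15, tr_med), 0.4)  # 15 degC is T_ref
  expect_equal(effective_eo(25, tr_med), 0.4 + 0.022 * 10)
  tr0 <- trait_set(A_c = 10, E_o = 0.4, dEo_dT = 0)
  expect_equal(effective_eo(c(-2, 10, 30), tr0), rep(0.4, 3))
})

test_that("trait validation rejects bad values", {
  expect_error(trait_set(A_c = -1, E_o = 0.4), "positive")
  expect_warning(trait_set(A_c = 10, E_o = 1.4), "outside")
})

test_that("phi at saturation and reference temperature is A_c * 0.209", {
  sol <- o2_solubility(15, 35)
  expect_equal(phi_eval(15, 35, sol, tr_med), 10 * 0.209)
  # doubling A_c doubles phi everywhere
  tr2 <- trait_set(A_c = 20, E_o = 0.4)
  set.seed(3)
  T_c <- runif(50, 0, 25); S <- runif(50, 32, 37); O2 <- runif(50, 10, 300)
  expect_equal(phi_eval(T_c, S, O2, tr2), 2 * phi_eval(T_c, S, O2, tr_med))
})

test_that("phi matches an independent step-by-step scalar evaluation", {
  # hand evaluation: solubility -> pO2 -> corrected E_o -> exponent -> product
  T_c <- 5; S <- 34; O2 <- 300
  sol <- gg92_oracle_umol_kg(T_c, S) * 1.025
  p <- 0.209 * O2 / sol
  eo <- 0.4 + 0.022 * ((T_c + 273.15) - 288.15)
  expo <- exp(eo / 8.617333e-5 * (1 / (T_c + 273.15) - 1 / 288.15))
  expect_equal(phi_eval(T_c, S, O2, tr_med), 10 * p * expo,
               tolerance = 1e-12)
})

test_that("phi is zero in anoxic water and increasing in O2", {
  expect_equal(phi_eval(10, 35, 0, tr_med), 0)
  O2 <- seq(0, 300, by = 10)
  expect_true(all(diff(phi_eval(8, 34, O2, tr_med)) > 0))
  expect_error(phi_eval(10, 35, -5, tr_med), "non-negative")
})

test_that("metabolic_index on a field returns co-registered components", {
  g <- small_grid()
  p <- synth_params(n_members = 3, n_inits = 8, n_leads = 3, seed = 5)
  r <- quiet_recon(g, p)
  ph <- metabolic_index(r, tr_med)
  expect_s3_class(ph, "phi_field")
  expect_identical(dim(ph$phi), dim(r$vars$T))
  # AOU identity cellwise; NA exactly where inputs are missing
  expect_equal(ph$AOU, ph$O2sol - r$vars$O2, tolerance = 1e-14)
  expect_identical(is.na(ph$phi), is.na(r$vars$T))
  expect_true(all(ph$phi >= 0, na.rm = TRUE))
})

test_that("annual mean averages January-December and enforces policy", {
  x <- array(rep(1:12, 2), dim = c(24, 1, 1, 1))
  years <- rep(c(2000L, 2001L), each = 12)
  ym <- annual_mean(x, years = years)
  expect_equal(as.numeric(ym), c(6.5, 6.5))
  # constant field stays constant
  xc <- array(3, dim = c(24, 1, 1, 1))
  expect_equal(as.numeric(annual_mean(xc, years = years)), c(3, 3))
  # one missing month under the strict policy -> missing year
  x[5, 1, 1, 1] <- NA
  expect_true(is.na(annual_mean(x, years = years)[1]))
  expect_false(is.na(annual_mean(x, years = years, min_months = 11)[1]))
  # partial trailing year dropped with a warning
  xp <- array(rnorm(30), dim = c(30, 1, 1, 1))
  yp <- c(rep(2000L, 12), rep(2001L, 12), rep(2002L, 6))
  expect_warning(ymp <- annual_mean(xp, years = yp), "partial")
  expect_equal(dim(ymp)[1], 2L)
})

test_that("layer/region averaging is thickness- then area-weighted", {
  g <- small_grid(n_depth = 4)
  x <- array(5, dim = c(3, 4, 2, 2))
  expect_equal(layer_region_average(x, g, "full", 1), rep(5, 3))
  # two equal-area cells at one latitude, values 1 and 3 -> 2
  g2 <- grid_spec(lat = 45, lon = c(-130, -125),
                  depth_edges = c(0, 300, 600),
                  region = matrix(1L, 1, 2))
  x2 <- array(NA_real_, c(1, 2, 1, 2))
  x2[1, , 1, 1] <- 1; x2[1, , 1, 2] <- 3
  expect_equal(layer_region_average(x2, g2, "full", 1), 2)
  # thickness weights 150 m and 450 m, values 0 and 4 -> 3
  g3 <- grid_spec(lat = 45, lon = -130, depth_edges = c(0, 150, 600),
                  region = matrix(1L, 1, 1))
  x3 <- array(c(0, 4), c(1, 2, 1, 1))
  expect_equal(layer_region_average(x3, g3, "full", 1), 3)
  expect_error(layer_region_average(x, g, "full", 9), "region")
})

test_that("phi is computed cellwise before averaging, not on averaged drivers", {
  g <- small_grid()
  p <- synth_params(n_members = 3, n_inits = 10, n_leads = 3, seed = 21)
  r <- quiet_recon(g, p)
  ry <- annual_mean(r)
  phi_first <- layer_region_average(annual_mean(metabolic_index(r, tr_med))$phi,
                                    g, "upper", 1)
  drivers_first <- phi_eval(
    layer_region_average(ry$vars$T, g, "upper", 1),
    layer_region_average(ry$vars$S, g, "upper", 1),
    layer_region_average(ry$vars$O2, g, "upper", 1), tr_med)
  # the two orders genuinely differ (nonlinearity) ...
  expect_gt(max(abs(phi_first - drivers_first)), 1e-6)
  # ... and the pipeline's path is the phi-first one
  manual <- layer_region_average(
    annual_mean(phi_eval(r$vars$T, r$vars$S, r$vars$O2, tr_med),
                years = r$years), g, "upper", 1)
  expect_equal(phi_first, manual, tolerance = 1e-14)
})

test_that("trait tables read back as trait sets", {
  path <- system.file("extdata", "ecotypes_synthetic.tsv",
                      package = "aerohab")
  trs <- read_traits(path)
  expect_length(trs, 5)
  expect_s3_class(trs[["synthetic_medium_Eo"]], "trait_set")
  expect_equal(trs[["synthetic_medium_Eo"]]$E_o, 0.4)
})
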