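# Small synthetic worlds shared across tests.

# one-cell water column: 2 depth levels, a single labeled region
tiny_grid <- function(n_depth = 2) {
  grid_spec(lat = 45, lon = -130,
            depth_edges = seq(0, 600, length.out = n_depth + 1),
            region = matrix(1L, 1, 1))
}

# small coastal domain: 2 x 2 cells, one region, few depths
small_grid <- function(n_depth = 4) {
  grid_spec(lat = c(40, 45), lon = c(-130, -125),
            depth_edges = seq(0, 600, length.out = n_depth + 1),
            region = matrix(1L, 2, 2))
}

quiet_recon <- function(...) suppressMessages(generate_reconstruction(...))
quiet_fcst <- function(...) suppressMessages(generate_forecasts(...))

# params for a world where a single driver carries all forecast skill
single_driver_params <- function(driver, alpha_lead, n_members = 8,
                                 n_inits = 40, n_leads = 5, seed = 7) {
  al <- matrix(0, n_leads, 3)
  colnames(al) <- c("T", "S", "O2")
  al[, driver] <- alpha_lead
  synth_params(coupling = diag(3), alpha = al,
               n_members = n_members, n_inits = n_inits, n_leads = n_leads,
               seed = seed)
}

# region-series phi skill + component skill for one world
world_phi_skill <- function(grid, params, traits, alpha = 0.05) {
  recon <- quiet_recon(grid, params)
  fcst <- quiet_fcst(recon, params)
  phi_ry <- annual_mean(metabolic_index(recon, traits))
  ryears <- phi_ry$years
  r_ser <- layer_region_average(phi_ry$phi, grid, "full", 1)
  phi_f <- metabolic_index(fcst, traits)$phi
  f_em <- ensemble_mean(drift_adjust(
    layer_region_average(phi_f, grid, "full", 1)))
  sk <- assess_skill(f_em, fcst$init_years, r_ser, ryears, alpha = alpha)
  dr <- list(); cl <- list()
  for (v in c("T", "S", "O2")) {
    em <- ensemble_mean(layer_region_average(fcst$vars[[v]], grid,
                                             "full", 1))
    cl[[v]] <- colMeans(em)
    dr[[v]] <- sweep(em, 2, cl[[v]], "-")
  }
  comp <- component_skill(dr, cl, fcst$init_years, r_ser, ryears,
                          traits, alpha = alpha)
  list(skill = sk, components = comp)
}
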