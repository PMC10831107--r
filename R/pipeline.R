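# region-series of driver variables / phi for one (layer, region)
.series_key <- function(region, layer) sprintf("r%s_%s", region, layer)

#' Run the full habitat-predictability pipeline
#'
#' Orchestrates an end-to-end run from one configuration: generate (or
#' read) the reconstruction and ensemble forecasts; compute the
#' normalized Metabolic Index for every ecotype; verify ensemble-mean
#' forecasts of \eqn{\phi} against the reconstruction with a persistence
#' baseline per region and depth layer; decompose \eqn{\phi} into driver
#' components with the variance budget and component-wise skill; derive
#' habitat envelopes and vertical habitable ranges; and assemble the
#' trait-sweep report. Artifacts are written to `out_dir` as delimited
#' tables plus a machine-readable manifest; identical configurations and
#' seeds give bit-identical outputs.
#'
#' @param config a `run_config` (see [default_config], [read_config]).
#' @param out_dir output directory, created if needed.
#' @param stages character subset of
#'   `c("generate", "index", "skill", "decompose", "sweep")`; earlier
#'   results a requested stage depends on are always computed, the stage
#'   list controls which artifacts are written.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the per-ecotype results (`skill`,
#'   `components`, `budget`, `envelopes`), the tidy `sweep` table, the
#'   `manifest`, and the generated `recon`/`forecasts`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("aerohab_run_"),
                         stages = c("generate", "index", "skill",
                                    "decompose", "sweep"),
                         quiet = FALSE) {
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) if (!quiet)
    message(sprintf("[aerohab +%5.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage: inputs -------------------------------------------------------
  if (config$mode == "synthetic") {
    g <- config$grid
    grid <- grid_spec(n_lat = g$n_lat, n_lon = g$n_lon,
                      depth_edges = seq(g$depth_min, g$depth_max,
                                        length.out = g$n_depth + 1))
    sy <- config$synth
    params <- do.call(synth_params, c(
      sy[setdiff(names(sy), "start_year")], list(seed = config$seed)))
    say("generating reconstruction (%d years) and forecasts (%d x %d x %d)",
        params$n_inits + params$n_leads, params$n_inits, params$n_members,
        params$n_leads)
    recon <- generate_reconstruction(grid, params,
                                     start_year = sy$start_year %||% 1954)
    fcst <- generate_forecasts(recon, params)
  } else {
    say("reading netCDF inputs")
    recon <- read_hydro_nc(config$paths$reconstruction)
    grid <- recon$grid
    fcst <- read_forecast_nc(config$paths$forecasts, grid)
  }
  if ("generate" %in% stages && isTRUE(config$write_netcdf)) {
    write_hydro_nc(recon, file.path(out_dir, "reconstruction.nc"))
    write_forecast_nc(fcst, file.path(out_dir, "forecasts.nc"))
  }
  regions <- config$regions %||% region_labels(grid)
  layers <- config$layers
  traits <- config_traits(config)
  recon_yearly <- annual_mean(recon)
  ryears <- recon_yearly$years
  n_lead <- length(fcst$leads)

  # forecast driver bookkeeping for component skill: region series of the
  # raw forecast drivers, drift statistics taken on the series
  driver_series <- list()
  for (v in c("T", "S", "O2")) {
    for (rg in regions) for (ly in layers) {
      key <- .series_key(rg, ly)
      em <- ensemble_mean(layer_region_average(fcst$vars[[v]], grid,
                                               layer = ly, region = rg))
      clim <- colMeans(em)                      # lead-dependent climatology
      driver_series[[v]][[key]] <-
        list(anom = sweep(em, 2, clim, "-"), clim = clim)
    }
  }

  skill_rows <- list(); comp_rows <- list(); budget_rows <- list()
  env_rows <- list(); results <- list()

  for (sp in names(traits)) {
    tr <- traits[[sp]]
    say("ecotype %s: metabolic index and skill", sp)
    phi_r <- metabolic_index(recon, tr)          # cellwise, monthly
    phi_r_yearly <- annual_mean(phi_r)           # phi first, then averaging
    phi_f <- metabolic_index(fcst, tr)$phi       # (init, member, lead, ...)
    res_sp <- list(traits = tr, skill = list(), components = list(),
                   budget = list(), envelopes = list())
    for (rg in regions) for (ly in layers) {
      key <- .series_key(rg, ly)
      r_ser <- layer_region_average(phi_r_yearly$phi, grid, ly, rg)
      f_ser <- layer_region_average(phi_f, grid, ly, rg)  # (init, member, lead)
      f_em <- ensemble_mean(drift_adjust(f_ser))          # (init, lead)
      cmp <- skill_vs_persistence(f_em, fcst$init_years, r_ser, ryears,
                                  alpha = config$alpha)
      res_sp$skill[[key]] <- cmp
      skill_rows[[length(skill_rows) + 1L]] <- cbind(
        data.frame(species = sp, E_o = tr$E_o, A_c = tr$A_c,
                   region = rg, layer = ly), cmp$table,
        timescale_dple = cmp$timescale_dple,
        timescale_pers = cmp$timescale_pers)

      # Taylor decomposition + budget on recon yearly drivers
      dr <- lapply(recon_yearly$vars, layer_region_average,
                   grid = grid, layer = ly, region = rg)
      dec <- taylor_decompose(dr$T, dr$S, dr$O2, tr, phi_bar = config$phi_bar)
      vb <- variance_budget(dec)
      res_sp$budget[[key]] <- vb
      budget_rows[[length(budget_rows) + 1L]] <- cbind(
        data.frame(species = sp, E_o = tr$E_o, region = rg, layer = ly),
        as.data.frame(vb))

      # component-wise forecast skill
      cs <- component_skill(
        fc_anom = lapply(driver_series, function(d) d[[key]]$anom),
        fc_clim = lapply(driver_series, function(d) d[[key]]$clim),
        init_years = fcst$init_years, recon_phi = r_ser,
        recon_years = ryears, traits = tr, alpha = config$alpha)
      res_sp$components[[key]] <- cs
      for (cn in names(cs)) {
        comp_rows[[length(comp_rows) + 1L]] <- cbind(
          data.frame(species = sp, E_o = tr$E_o, region = rg, layer = ly,
                     component = cn), cs[[cn]]$table,
          timescale = cs[[cn]]$timescale)
      }
    }
    # habitat envelopes and vertical ranges on the full-depth region profile
    for (rg in regions) {
      prof <- vapply(seq_along(grid$depth), function(d)
        mean(apply(matrix(phi_r_yearly$phi[, d, , ], nrow = dim(phi_r_yearly$phi)[1]),
                   1, wmean_na,
                   w = as.vector(grid$area * .region_mask(grid, rg)))),
        numeric(1))
      sgp <- vapply(seq_along(grid$depth), function(d)
        stats::sd(apply(matrix(phi_r_yearly$phi[, d, , ], nrow = dim(phi_r_yearly$phi)[1]),
                        1, wmean_na,
                        w = as.vector(grid$area * .region_mask(grid, rg)))),
        numeric(1))
      iv <- vertical_habitable_range(prof, sgp, grid)
      if (nrow(iv))
        env_rows[[length(env_rows) + 1L]] <- cbind(
          data.frame(species = sp, E_o = tr$E_o, region = rg), iv)
      res_sp$envelopes[[as.character(rg)]] <- iv
    }
    results[[sp]] <- res_sp
  }

  skill_tab <- do.call(rbind, skill_rows)
  comp_tab <- do.call(rbind, comp_rows)
  budget_tab <- do.call(rbind, budget_rows)
  env_tab <- if (length(env_rows)) do.call(rbind, env_rows) else
    data.frame()
  sweep_tab <- trait_sweep_report(skill_tab, comp_tab)

  if ("skill" %in% stages)
    utils::write.csv(skill_tab, file.path(out_dir, "skill.csv"),
                     row.names = FALSE)
  if ("decompose" %in% stages) {
    utils::write.csv(budget_tab, file.path(out_dir, "variance_budget.csv"),
                     row.names = FALSE)
    utils::write.csv(comp_tab, file.path(out_dir, "component_skill.csv"),
                     row.names = FALSE)
  }
  if ("index" %in% stages && nrow(env_tab))
    utils::write.csv(env_tab, file.path(out_dir, "habitable_ranges.csv"),
                     row.names = FALSE)
  if ("sweep" %in% stages)
    utils::write.csv(sweep_tab, file.path(out_dir, "trait_sweep.csv"),
                     row.names = FALSE)

  manifest <- write_manifest(config, out_dir)
  say("done: %d ecotypes x %d regions x %d layers -> %s",
      length(traits), length(regions), length(layers), out_dir)
  invisible(list(results = results, skill = skill_tab,
                 components = comp_tab, budget = budget_tab,
                 envelopes = env_tab, sweep = sweep_tab,
                 manifest = manifest, recon = recon, forecasts = fcst,
                 grid = grid, out_dir = out_dir))
}

#' Tidy trait-sweep report
#'
#' Assembles the per-ecotype skill and component-skill tables into one
#' tidy table of ACC, significance and predictability timescale against
#' `(E_o, lead)` per region and layer — the data behind a trait-sweep
#' heatmap.
#'
#' @param skill_tab per-ecotype skill table (from [run_pipeline]).
#' @param comp_tab per-ecotype component-skill table (optional).
#' @return data.frame with columns region, layer, species, E_o, lead,
#'   acc, sig, delta_acc, timescale and, when available, the component
#'   ACCs `acc_O2`, `acc_T`, `acc_S`.
#' @export
trait_sweep_report <- function(skill_tab, comp_tab = NULL) {
  out <- skill_tab[, c("region", "layer", "species", "E_o", "lead",
                       "acc_dple", "sig_dple", "delta_acc",
                       "timescale_dple")]
  names(out) <- c("region", "layer", "species", "E_o", "lead", "acc",
                  "sig", "delta_acc", "timescale")
  if (!is.null(comp_tab) && nrow(comp_tab)) {
    for (cn in unique(comp_tab$component)) {
      sub <- comp_tab[comp_tab$component == cn,
                      c("region", "layer", "species", "lead", "acc")]
      names(sub)[5] <- paste0("acc_", cn)
      out <- merge(out, sub, by = c("region", "layer", "species", "lead"),
                   sort = FALSE)
    }
  }
  out[order(out$region, out$layer, out$E_o, out$lead), , drop = FALSE]
}

#' Write the run manifest
#'
#' Records package version, seed, a hash of the canonicalized
#' configuration, and the MD5 checksum of every artifact in the run
#' directory, as `manifest.json`. Reruns of the same configuration and
#' seed produce an identical manifest.
#'
#' @param config the `run_config` used.
#' @param out_dir the run directory.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, out_dir) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- file.path(out_dir, ".config.json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  files <- sort(setdiff(list.files(out_dir), c("manifest.json")))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "aerohab",
    version = as.character(utils::packageVersion("aerohab")),
    seed = config$seed,
    config_hash = cfg_hash,
    files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
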