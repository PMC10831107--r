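.need_ncdf4 <- function() {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stopf("netCDF support requires the 'ncdf4' package")
}

#' Write a hydrographic field to CF-style netCDF
#'
#' Variables `temperature` (degC), `salinity` (psu) and `oxygen`
#' (mmol m-3) on dimensions `(lon, lat, depth, time)` (netCDF order;
#' time unlimited-style last), with coordinate variables, a `region`
#' integer mask (land as fill), and year/month label variables.
#'
#' @param x a [hydro_field].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hydro_nc <- function(x, path) {
  .need_ncdf4()
  g <- x$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  ddep <- ncdf4::ncdim_def("depth", "m", g$depth)
  dtim <- ncdf4::ncdim_def("time", "months since start", seq_along(x$years))
  fill <- 1e20
  vr <- function(nm, un) ncdf4::ncvar_def(nm, un, list(dlon, dlat, ddep, dtim),
                                          fill, prec = "double")
  vars <- list(temperature = vr("temperature", "degC"),
               salinity = vr("salinity", "psu"),
               oxygen = vr("oxygen", "mmol m-3"))
  vreg <- ncdf4::ncvar_def("region", "1", list(dlon, dlat), -1L,
                           prec = "integer")
  vyear <- ncdf4::ncvar_def("year", "1", list(dtim), prec = "integer")
  vmon <- ncdf4::ncvar_def("month", "1", list(dtim), prec = "integer")
  nc <- ncdf4::nc_create(path, c(vars, list(region = vreg, year = vyear,
                                            month = vmon)))
  on.exit(ncdf4::nc_close(nc))
  # internal layout (time, depth, lat, lon) -> file layout (lon, lat, depth, time)
  flip <- function(a) aperm(a, c(4, 3, 2, 1))
  ncdf4::ncvar_put(nc, vars$temperature, flip(x$vars$T))
  ncdf4::ncvar_put(nc, vars$salinity, flip(x$vars$S))
  ncdf4::ncvar_put(nc, vars$oxygen, flip(x$vars$O2))
  reg <- t(g$region)
  reg[is.na(reg)] <- -1L
  ncdf4::ncvar_put(nc, vreg, reg)
  ncdf4::ncvar_put(nc, vyear, x$years)
  ncdf4::ncvar_put(nc, vmon, x$months)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8-style")
  ncdf4::ncatt_put(nc, 0, "depth_edges", paste(g$depth_edges, collapse = ","))
  invisible(path)
}

#' Read a hydrographic field written by [write_hydro_nc]
#'
#' @param path netCDF file path.
#' @param layer_bounds depth-layer partition to attach to the rebuilt grid.
#' @return a [hydro_field].
#' @export
read_hydro_nc <- function(path, layer_bounds = list(upper = c(0, 200),
                                                    lower = c(200, 600))) {
  .need_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- ncdf4::ncvar_get(nc, "lon"); lat <- ncdf4::ncvar_get(nc, "lat")
  edges <- as.numeric(strsplit(
    ncdf4::ncatt_get(nc, 0, "depth_edges")$value, ",")[[1]])
  reg <- t(ncdf4::ncvar_get(nc, "region"))
  reg[reg == -1L] <- NA_integer_
  storage.mode(reg) <- "integer"
  g <- grid_spec(lat = lat, lon = lon, depth_edges = edges, region = reg,
                 layer_bounds = layer_bounds)
  unflip <- function(a) aperm(a, c(4, 3, 2, 1))
  hydro_field(g,
              T = unflip(ncdf4::ncvar_get(nc, "temperature", collapse_degen = FALSE)),
              S = unflip(ncdf4::ncvar_get(nc, "salinity", collapse_degen = FALSE)),
              O2 = unflip(ncdf4::ncvar_get(nc, "oxygen", collapse_degen = FALSE)),
              years = as.integer(ncdf4::ncvar_get(nc, "year")),
              months = as.integer(ncdf4::ncvar_get(nc, "month")))
}

#' Write an ensemble forecast set to CF-style netCDF
#'
#' Per-variable arrays on `(lon, lat, depth, lead_year, member,
#' init_year)` in the file, corresponding to the package's
#' `(init, member, lead, depth, lat, lon)` layout.
#'
#' @param x a `forecast_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forecast_nc <- function(x, path) {
  .need_ncdf4()
  g <- x$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  ddep <- ncdf4::ncdim_def("depth", "m", g$depth)
  dlead <- ncdf4::ncdim_def("lead_year", "years", x$leads)
  dmem <- ncdf4::ncdim_def("member", "1", seq_len(dim(x$vars$T)[2]))
  dini <- ncdf4::ncdim_def("init_year", "year", x$init_years)
  fill <- 1e20
  dims <- list(dlon, dlat, ddep, dlead, dmem, dini)
  vr <- function(nm, un) ncdf4::ncvar_def(nm, un, dims, fill, prec = "double")
  vars <- list(temperature = vr("temperature", "degC"),
               salinity = vr("salinity", "psu"),
               oxygen = vr("oxygen", "mmol m-3"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  flip <- function(a) aperm(a, c(6, 5, 4, 3, 2, 1))
  ncdf4::ncvar_put(nc, vars$temperature, flip(x$vars$T))
  ncdf4::ncvar_put(nc, vars$salinity, flip(x$vars$S))
  ncdf4::ncvar_put(nc, vars$oxygen, flip(x$vars$O2))
  ncdf4::ncatt_put(nc, 0, "drift_adjusted", as.integer(isTRUE(x$adjusted)))
  ncdf4::ncatt_put(nc, 0, "depth_edges", paste(g$depth_edges, collapse = ","))
  invisible(path)
}

#' Read a forecast set written by [write_forecast_nc]
#'
#' @param path netCDF file path.
#' @param grid the [grid_spec] of the matching reconstruction.
#' @return a `forecast_set`.
#' @export
read_forecast_nc <- function(path, grid) {
  .need_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  unflip <- function(a) aperm(a, c(6, 5, 4, 3, 2, 1))
  init_years <- as.integer(ncdf4::ncvar_get(nc, "init_year"))
  leads <- as.integer(ncdf4::ncvar_get(nc, "lead_year"))
  adj <- isTRUE(ncdf4::ncatt_get(nc, 0, "drift_adjusted")$value == 1L)
  structure(list(
    grid = grid,
    vars = list(T = unflip(ncdf4::ncvar_get(nc, "temperature", collapse_degen = FALSE)),
                S = unflip(ncdf4::ncvar_get(nc, "salinity", collapse_degen = FALSE)),
                O2 = unflip(ncdf4::ncvar_get(nc, "oxygen", collapse_degen = FALSE))),
    init_years = init_years, leads = leads, adjusted = adj,
    n_clipped = NA_integer_), class = "forecast_set")
}
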