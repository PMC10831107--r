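#' Grid specification for the study domain
#'
#' Defines the abstract lat/lon/depth grid used throughout: cell-center
#' coordinates, depth-layer edges spanning the upper 0--600 m, cosine-of-
#' latitude area weights, an integer region mask naming labeled coastal
#' "ecosystems" (0 = open ocean, `NA` = land), and the two canonical depth
#' habitats (surface layer 0--200 m and thermocline layer 200--600 m).
#'
#' @param n_lat,n_lon number of horizontal cells (used when `lat`/`lon` are
#'   not given).
#' @param lat,lon cell-center coordinates in degrees.
#' @param depth_edges strictly increasing vector of layer interface depths
#'   in meters; the default splits 0--600 m into 10 levels.
#' @param region integer matrix `(n_lat, n_lon)`: positive labels for
#'   regions, 0 for open ocean, `NA` for land. The default carves two
#'   labeled regions out of the domain and keeps a land cell.
#' @param layer_bounds named list of `c(top, bottom)` pairs in meters that
#'   must partition the depth span.
#' @param months_per_year months per model year (12).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_lat = 6, n_lon = 6,
                      lat = seq(30, 55, length.out = n_lat),
                      lon = seq(-140, -115, length.out = n_lon),
                      depth_edges = seq(0, 600, length.out = 11),
                      region = NULL,
                      layer_bounds = list(upper = c(0, 200),
                                          lower = c(200, 600)),
                      months_per_year = 12) {
  n_lat <- length(lat); n_lon <- length(lon)
  if (length(depth_edges) < 2 || any(diff(depth_edges) <= 0))
    stopf("depth_edges must be strictly increasing with >= 2 entries")
  span <- range(depth_edges)
  bounds <- do.call(rbind, layer_bounds)
  ord <- order(bounds[, 1])
  bounds <- bounds[ord, , drop = FALSE]
  if (bounds[1, 1] != span[1] || bounds[nrow(bounds), 2] != span[2] ||
      (nrow(bounds) > 1 && any(bounds[-1, 1] != bounds[-nrow(bounds), 2])))
    stopf("layer_bounds must partition the depth span [%g, %g] m",
          span[1], span[2])
  if (is.null(region)) {
    region <- matrix(0L, n_lat, n_lon)
    region[, seq_len(max(1L, n_lon %/% 3))] <- 1L
    region[, seq.int(n_lon - max(1L, n_lon %/% 3) + 1L, n_lon)] <- 2L
    region[1L, n_lon] <- NA_integer_  # a land cell
  }
  if (!identical(dim(region), c(n_lat, n_lon)))
    stopf("region mask must be a %d x %d matrix", n_lat, n_lon)
  depth <- (depth_edges[-1] + depth_edges[-length(depth_edges)]) / 2
  structure(list(
    lat = lat, lon = lon,
    depth = depth, depth_edges = depth_edges,
    thickness = diff(depth_edges),
    area = matrix(rep(cos(lat * pi / 180), n_lon), n_lat, n_lon),
    region = region,
    layer_bounds = layer_bounds,
    months_per_year = months_per_year
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  labs <- sort(unique(x$region[!is.na(x$region) & x$region > 0]))
  cat(sprintf(
    "<grid_spec> %d x %d cells, %d depth levels (%g-%g m), regions {%s}, %d land cell(s)\n",
    length(x$lat), length(x$lon), length(x$depth),
    min(x$depth_edges), max(x$depth_edges),
    paste(labs, collapse = ","), sum(is.na(x$region))))
  invisible(x)
}

#' Region labels present on a grid
#' @param grid a [grid_spec].
#' @return sorted integer vector of positive region labels.
#' @export
region_labels <- function(grid) {
  sort(unique(grid$region[!is.na(grid$region) & grid$region > 0]))
}

#' Gridded hydrographic state
#'
#' Container for co-registered temperature, salinity and dissolved-oxygen
#' fields on `(time, depth, lat, lon)`, with year/month labels. Land cells
#' carry `NA`, never silent zeros.
#'
#' @param grid a [grid_spec].
#' @param T,S,O2 numeric arrays `(time, depth, lat, lon)`; degC, psu,
#'   mmol/m^3.
#' @param years,months integer vectors along the time axis.
#' @param anomalies optional list of per-variable yearly anomaly arrays
#'   (ground truth from the synthetic generator).
#' @param n_clipped count of O2 values clipped at zero during generation.
#' @return an object of class `hydro_field`.
#' @export
hydro_field <- function(grid, T, S, O2, years, months,
                        anomalies = NULL, n_clipped = 0L) {
  stopifnot(inherits(grid, "grid_spec"))
  dms <- c(length(years), length(grid$depth), length(grid$lat),
           length(grid$lon))
  for (nm in c("T", "S", "O2")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dms)))
      stopf("%s must have dims (time=%d, depth=%d, lat=%d, lon=%d)",
            nm, dms[1], dms[2], dms[3], dms[4])
  }
  if (any(is.finite(O2) & O2 < 0)) stopf("O2 must be non-negative")
  if (length(months) != length(years))
    stopf("years and months must have equal length")
  structure(list(grid = grid, vars = list(T = T, S = S, O2 = O2),
                 years = years, months = months,
                 anomalies = anomalies, n_clipped = n_clipped),
            class = "hydro_field")
}

#' @export
print.hydro_field <- function(x, ...) {
  cat(sprintf(
    "<hydro_field> years %d-%d (%d time steps), %d depths, %d x %d cells; O2 clipped at 0: %d value(s)\n",
    min(x$years), max(x$years), length(x$years), length(x$grid$depth),
    length(x$grid$lat), length(x$grid$lon), x$n_clipped))
  invisible(x)
}

#' @export
print.forecast_set <- function(x, ...) {
  d <- dim(x$vars$T)
  cat(sprintf(
    "<forecast_set>%s %d inits (%d-%d) x %d members x %d leads on %d x %d x %d cells\n",
    if (isTRUE(x$adjusted)) " [drift-adjusted anomalies]" else "",
    d[1], min(x$init_years), max(x$init_years), d[2], d[3], d[4], d[5], d[6]))
  invisible(x)
}
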