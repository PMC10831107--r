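#' Calendar-year average of a monthly field
#'
#' Averages January--December within each calendar year, along the first
#' (time) dimension. By default a year is reported only when all
#' `months_per_year` months are present and non-missing; relaxing
#' `min_months` allows years with at least that many valid months. A
#' partial trailing (or leading) year is dropped with a warning.
#'
#' @param x a monthly array with time as the first dimension, a
#'   [hydro_field], or a `phi_field`.
#' @param years integer year label per time step (array method).
#' @param min_months minimum valid months required per year; default all.
#' @param ... passed between methods.
#' @return the yearly object: an array whose first dimension indexes the
#'   complete years (named by year), or a yearly `hydro_field`/`phi_field`.
#' @export
annual_mean <- function(x, ...) UseMethod("annual_mean")

#' @rdname annual_mean
#' @export
annual_mean.default <- function(x, years, min_months = NULL, ...) {
  x <- as.array(x)
  dms <- dim(x)
  if (length(years) != dms[1])
    stopf("length(years) must match the first dimension of x")
  mpy <- max(table(years))
  min_months <- min_months %||% mpy
  full <- names(which(table(years) == mpy))
  if (length(full) < length(unique(years)))
    warnf("dropping %d partial year(s)", length(unique(years)) - length(full))
  yrs <- sort(as.integer(full))
  ncell <- prod(dms[-1])
  xm <- matrix(x, nrow = dms[1], ncol = ncell)
  out <- matrix(NA_real_, length(yrs), ncell)
  for (k in seq_along(yrs)) {
    rows <- which(years == yrs[k])
    sub <- xm[rows, , drop = FALSE]
    nok <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    mu[nok < min_months] <- NA_real_
    out[k, ] <- mu
  }
  res <- array(out, dim = c(length(yrs), dms[-1]))
  dimnames(res) <- c(list(as.character(yrs)),
                     vector("list", length(dms) - 1L))
  attr(res, "years") <- yrs
  res
}

#' @rdname annual_mean
#' @export
annual_mean.hydro_field <- function(x, min_months = NULL, ...) {
  vs <- lapply(x$vars, annual_mean, years = x$years, min_months = min_months)
  yrs <- attr(vs[[1]], "years")
  hydro_field(x$grid, T = vs$T, S = vs$S, O2 = vs$O2,
              years = yrs, months = rep(0L, length(yrs)),
              anomalies = x$anomalies, n_clipped = x$n_clipped)
}

#' @rdname annual_mean
#' @export
annual_mean.phi_field <- function(x, min_months = NULL, ...) {
  out <- x
  for (nm in c("phi", "pO2", "O2sol", "AOU"))
    out[[nm]] <- annual_mean(x[[nm]], years = x$years,
                             min_months = min_months)
  out$years <- attr(out$phi, "years")
  out$months <- rep(0L, length(out$years))
  out
}

# resolve a layer argument to depth indices
.layer_index <- function(grid, layer) {
  if (is.character(layer)) {
    if (identical(layer, "full")) {
      bounds <- range(grid$depth_edges)
    } else {
      if (is.null(grid$layer_bounds[[layer]]))
        stopf("unknown layer '%s'", layer)
      bounds <- grid$layer_bounds[[layer]]
    }
  } else bounds <- layer
  idx <- which(grid$depth > bounds[1] & grid$depth < bounds[2])
  if (!length(idx)) stopf("layer [%g, %g] m contains no depth level",
                          bounds[1], bounds[2])
  idx
}

# resolve a region argument to a logical (lat, lon) matrix of ocean cells
.region_mask <- function(grid, region) {
  if (identical(region, "all")) {
    m <- !is.na(grid$region)
  } else {
    m <- !is.na(grid$region) & grid$region == region
  }
  if (!any(m)) stopf("region '%s' contains no ocean cell", as.character(region))
  m
}

#' Depth-layer and region average of a gridded field
#'
#' Collapses the spatial dimensions of a field in the fixed order used
#' throughout the package: first a thickness-weighted vertical mean over
#' the depth levels of the requested layer, then an area-weighted
#' horizontal mean over the cells of the requested region. Missing cells
#' are dropped together with their weights at each step.
#'
#' @param x numeric array whose last three dimensions are
#'   `(depth, lat, lon)`; any leading dimensions (time, or
#'   init/member/lead) are preserved.
#' @param grid a [grid_spec].
#' @param layer `"upper"`, `"lower"`, `"full"`, or a numeric
#'   `c(top, bottom)` in meters.
#' @param region a positive integer region label, `0` for open ocean, or
#'   `"all"` for every ocean cell.
#' @return an array over the leading dimensions of `x` (a vector when there
#'   is a single leading dimension).
#' @export
layer_region_average <- function(x, grid, layer = "full", region = "all") {
  stopifnot(inherits(grid, "grid_spec"))
  dms <- dim(x) %||% length(x)
  k <- length(dms)
  if (k < 3) stopf("x must have at least (depth, lat, lon) dimensions")
  nd <- length(grid$depth); nla <- length(grid$lat); nlo <- length(grid$lon)
  if (!identical(as.integer(dms[(k - 2):k]), as.integer(c(nd, nla, nlo))))
    stopf("trailing dims of x must be (depth=%d, lat=%d, lon=%d)",
          nd, nla, nlo)
  idx <- .layer_index(grid, layer)
  rmask <- .region_mask(grid, region)
  lead_dims <- if (k > 3) dms[seq_len(k - 3)] else 1L
  M <- prod(lead_dims)
  xm <- array(x, dim = c(M, nd, nla * nlo))
  wz <- grid$thickness[idx]
  # thickness-weighted vertical mean (NA-aware)
  num <- matrix(0, M, nla * nlo); den <- matrix(0, M, nla * nlo)
  for (j in seq_along(idx)) {
    slab <- xm[, idx[j], , drop = FALSE]
    dim(slab) <- c(M, nla * nlo)
    ok <- !is.na(slab)
    slab[!ok] <- 0
    num <- num + wz[j] * slab
    den <- den + wz[j] * ok
  }
  vmean <- num / den
  vmean[den == 0] <- NA_real_
  # area-weighted horizontal mean over the region (NA-aware)
  wa <- as.vector(grid$area) * as.vector(rmask)
  ok <- !is.na(vmean)
  vnum <- vmean; vnum[!ok] <- 0
  out <- as.vector(vnum %*% wa) / as.vector(ok %*% wa)
  if (k > 3 && length(lead_dims) > 1) dim(out) <- lead_dims
  out
}
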