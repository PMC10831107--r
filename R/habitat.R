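#' Habitable mask from the Metabolic Index
#'
#' Viable habitat is where \eqn{\phi} strictly exceeds the threshold
#' (default 1: supply meets resting demand with headroom for activity).
#' Missing values stay missing.
#'
#' @param phi numeric array of \eqn{\phi} values.
#' @param threshold habitability threshold (default 1).
#' @return logical array of the same shape; `NA` preserved.
#' @export
habitable_mask <- function(phi, threshold = 1) {
  phi > threshold
}

#' Interannual habitat envelope
#'
#' From yearly \eqn{\phi}, computes the time-mean field, the pointwise
#' interannual standard deviation \eqn{\sigma_\phi} (unbiased, n-1), and
#' three habitability masks: at the mean (\eqn{\bar\phi > 1}), at the lower
#' envelope (\eqn{\bar\phi - 3\sigma_\phi > 1}) and at the upper envelope
#' (\eqn{\bar\phi + 3\sigma_\phi > 1}). The shift zone — habitable at the
#' upper envelope but not at the lower — marks where interannual
#' variability can contract or expand the habitat. The masks are nested:
#' `mask_min` is contained in `mask_mean` is contained in `mask_max`.
#'
#' @param phi yearly \eqn{\phi} with time as the first dimension (a plain
#'   array or the `phi` slot of an annual-mean `phi_field`).
#' @param n_sigma half-width of the envelope in standard deviations
#'   (default 3).
#' @return an object of class `habitat_envelope`: list with `mean_phi`,
#'   `sigma_phi`, `mask_mean`, `mask_min`, `mask_max`, `shift_zone`.
#' @export
interannual_envelope <- function(phi, n_sigma = 3) {
  if (inherits(phi, "phi_field")) phi <- phi$phi
  phi <- as.array(phi)
  dms <- dim(phi)
  if (dms[1] < 3) stopf("need at least 3 years to form an envelope")
  m <- matrix(phi, nrow = dms[1])
  mu <- colMeans(m)
  sg <- apply(m, 2, stats::sd)
  shape <- if (length(dms) > 1) dms[-1] else 1L
  mean_phi <- array(mu, dim = shape)
  sigma_phi <- array(sg, dim = shape)
  env <- list(
    mean_phi = mean_phi,
    sigma_phi = sigma_phi,
    mask_mean = habitable_mask(mean_phi),
    mask_min = habitable_mask(mean_phi - n_sigma * sigma_phi),
    mask_max = habitable_mask(mean_phi + n_sigma * sigma_phi))
  env$shift_zone <- env$mask_max & !env$mask_min
  structure(env, class = "habitat_envelope")
}

#' @export
print.habitat_envelope <- function(x, ...) {
  cat(sprintf(
    "<habitat_envelope> cells: habitable(mean)=%d, habitable(min)=%d, habitable(max)=%d, shift zone=%d\n",
    sum(x$mask_mean, na.rm = TRUE), sum(x$mask_min, na.rm = TRUE),
    sum(x$mask_max, na.rm = TRUE), sum(x$shift_zone, na.rm = TRUE)))
  invisible(x)
}

# contiguous TRUE runs of a logical profile -> (top, bottom) edge intervals
.depth_intervals <- function(flag, depth_edges) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(top = depth_edges[starts[keep]],
             bottom = depth_edges[ends[keep] + 1L])
}

#' Vertical habitable depth ranges
#'
#' Converts a mean \eqn{\phi} profile (and optionally its interannual
#' standard deviation profile) into maximal contiguous habitable depth
#' intervals, reported at cell edges as half-open `[top, bottom)` ranges in
#' meters. With a sigma profile, intervals habitable at the upper envelope
#' (\eqn{\bar\phi + n\sigma}) but not at the lower (\eqn{\bar\phi -
#' n\sigma}) are reported as `"shift"` intervals: depth ranges of potential
#' habitat contraction or expansion.
#'
#' @param mean_phi numeric vector of \eqn{\bar\phi} by depth level.
#' @param sigma_phi optional vector of \eqn{\sigma_\phi} by depth level.
#' @param grid a [grid_spec] (supplies the depth edges), or `depth_edges`
#'   directly.
#' @param threshold habitability threshold (default 1).
#' @param n_sigma envelope half-width (default 3).
#' @return data.frame with columns `top`, `bottom` (m) and `type`
#'   (`"habitable"` or `"shift"`).
#' @export
vertical_habitable_range <- function(mean_phi, sigma_phi = NULL, grid,
                                     threshold = 1, n_sigma = 3) {
  depth_edges <- if (inherits(grid, "grid_spec")) grid$depth_edges else grid
  if (any(diff(depth_edges) <= 0)) stopf("depth axis must be increasing")
  if (length(mean_phi) != length(depth_edges) - 1L)
    stopf("profile length must match the number of depth levels")
  hab <- .depth_intervals(mean_phi > threshold, depth_edges)
  hab$type <- rep("habitable", nrow(hab))
  if (is.null(sigma_phi)) return(hab)
  up <- mean_phi + n_sigma * sigma_phi > threshold
  lo <- mean_phi - n_sigma * sigma_phi > threshold
  sh <- .depth_intervals(up & !lo, depth_edges)
  sh$type <- rep("shift", nrow(sh))
  out <- rbind(hab, sh)
  rownames(out) <- NULL
  out
}
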