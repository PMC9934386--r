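#' Kernel utilization distribution
#'
#' Isotropic Gaussian kernel density of a set of positions on a regular grid
#' in a Lambert azimuthal equal-area plane, the home-range estimator used for
#' the seasonal maps. The smoothing factor is the kernel standard deviation
#' in kilometers (default 100 km); the grid is padded at least three
#' bandwidths beyond the data extent and the density is normalized to
#' integrate to 1. To weight each bird equally, restrict `positions` to the
#' first year of data per individual upstream.
#'
#' @param positions A tibble of daily positions with `lat`/`lon` columns (or
#'   pre-projected `x_km`/`y_km`, in which case `center` must be supplied and
#'   matching).
#' @param smoothing_km Gaussian kernel standard deviation, km (default 100).
#' @param cell_km Grid cell side, km (default 25).
#' @param center Optional projection center; default the spherical mean of
#'   the positions.
#' @return A `ud_grid` object: list with `x`, `y` (cell-center coordinates,
#'   km), `density` (matrix, rows = x, cols = y, integrating to 1),
#'   `cell_km`, `smoothing_km`, `center`, `n`. Supports [tidy()] and
#'   [autoplot()].
#' @export
utilization_distribution <- function(positions, smoothing_km = 100,
                                     cell_km = 25, center = NULL) {
  if (smoothing_km <= 0 || cell_km <= 0) {
    stop("utilization_distribution(): bandwidth and cell size must be positive")
  }
  if (all(c("x_km", "y_km") %in% names(positions))) {
    px <- positions$x_km; py <- positions$y_km
    if (is.null(center)) stop("utilization_distribution(): projected input needs center")
  } else {
    center <- center %||% spherical_mean(positions$lat, positions$lon)
    xy <- laea_project(positions$lat, positions$lon, center)
    px <- xy$x_km; py <- xy$y_km
  }
  if (length(px) == 0) stop("utilization_distribution(): no positions")
  pad <- 3 * smoothing_km
  xs <- seq(min(px) - pad, max(px) + pad + cell_km, by = cell_km)
  ys <- seq(min(py) - pad, max(py) + pad + cell_km, by = cell_km)
  # separable Gaussian: nx x N and ny x N factor matrices
  gx <- stats::dnorm(outer(xs, px, "-"), sd = smoothing_km)
  gy <- stats::dnorm(outer(ys, py, "-"), sd = smoothing_km)
  dens <- gx %*% t(gy) / length(px)
  total <- sum(dens) * cell_km^2
  dens <- dens / total
  structure(list(x = xs, y = ys, density = dens, cell_km = cell_km,
                 smoothing_km = smoothing_km, center = center, n = length(px)),
            class = "ud_grid")
}

#' Isopleth mask of a utilization distribution
#'
#' The smallest-area set of grid cells containing at least the requested
#' probability mass: cells are ranked by density and accumulated until the
#' level is reached (the usual home-range isopleth, e.g. `level = 0.95`).
#'
#' @param ud A `ud_grid` object.
#' @param level Probability mass in (0, 1).
#' @return A logical matrix of the grid's shape: `TRUE` for cells inside the
#'   isopleth. The contained mass and area (km^2) are attached as attributes
#'   `"mass"` and `"area_km2"`.
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 1)
  mass <- ud$density * ud$cell_km^2
  ord <- order(ud$density, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud$density), ncol(ud$density))
  mask[ord[seq_len(k)]] <- TRUE
  attr(mask, "mass") <- cum[k]
  attr(mask, "area_km2") <- k * ud$cell_km^2
  mask
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("utilization distribution: %d x %d grid (%.0f km cells), smoothing %.0f km, n = %d\n",
              length(x$x), length(x$y), x$cell_km, x$smoothing_km, x$n))
  invisible(x)
}
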