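#' 95% kernel home-range area for one point set
#'
#' Gaussian-kernel 2-D utilization density with a per-axis normal-reference
#' bandwidth (Silverman's rule of thumb, [stats::bw.nrd0()]), evaluated on a
#' regular grid padded by three bandwidths, and the area of the smallest set
#' of cells containing 95% of the density mass.
#'
#' @param x,y Planar coordinates in km.
#' @param isopleth Utilization level (default 0.95).
#' @param grid_n Grid resolution per axis.
#' @param bw Optional length-2 bandwidth (km, per axis sd of the Gaussian
#'   kernel); default is `bw.nrd0` on each axis.
#' @return A list with `area_km2`, `bandwidth`, `n`.
#' @examples
#' set.seed(1)
#' kernel_isopleth_area(rnorm(500, sd = 2), rnorm(500, sd = 2))
#' @export
kernel_isopleth_area <- function(x, y, isopleth = 0.95, grid_n = 200,
                                 bw = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) abort("Need at least 2 locations for a kernel home range.")
  if (sd(x) == 0 && sd(y) == 0) {
    abort("All locations identical: kernel home range is degenerate.")
  }
  if (is.null(bw)) bw <- c(bw.nrd0(x), bw.nrd0(y))
  bw <- pmax(bw, 1e-6)
  # MASS::kde2d interprets h as full bandwidth = 4 * kernel sd
  lims <- c(range(x) + c(-3, 3) * bw[1], range(y) + c(-3, 3) * bw[2])
  kde <- MASS::kde2d(x, y, h = 4 * bw, n = grid_n, lims = lims)
  cell <- diff(kde$x[1:2]) * diff(kde$y[1:2])
  mass <- as.vector(kde$z) * cell
  mass <- mass / sum(mass)
  ord <- order(mass, decreasing = TRUE)
  n_cells <- which(cumsum(mass[ord]) >= isopleth)[1]
  list(area_km2 = n_cells * cell, bandwidth = bw, n = n)
}

#' Kernel home ranges for a set of individuals
#'
#' Computes the 95% kernel isopleth area for each requested individual from
#' its detection locations. Individuals with fewer than `min_locs` locations
#' are excluded (returned with `NA` area and `usable = FALSE`).
#'
#' @param detections Detection tibble with `id`, `x_km`, `y_km` (or lon/lat,
#'   projected via [project_coordinates()]).
#' @param ids Individuals to estimate; default every id present.
#' @param min_locs Minimum locations for a usable estimate.
#' @param isopleth,grid_n,bw Passed to [kernel_isopleth_area()].
#' @return A tibble: `id`, `n_locs`, `area_km2`, `bw_x`, `bw_y`, `usable`.
#' @export
kernel_home_ranges <- function(detections, ids = NULL, min_locs = 10,
                               isopleth = 0.95, grid_n = 200, bw = NULL) {
  d <- project_coordinates(detections)
  ids <- ids %||% unique(d$id)
  d <- d |> filter(.data$id %in% ids)
  map(ids, function(i) {
    di <- d[d$id == i, ]
    if (nrow(di) < min_locs) {
      return(tibble(id = i, n_locs = nrow(di), area_km2 = NA_real_,
                    bw_x = NA_real_, bw_y = NA_real_, usable = FALSE))
    }
    est <- tryCatch(
      kernel_isopleth_area(di$x_km, di$y_km, isopleth, grid_n, bw),
      error = function(e) NULL
    )
    if (is.null(est)) {
      return(tibble(id = i, n_locs = nrow(di), area_km2 = NA_real_,
                    bw_x = NA_real_, bw_y = NA_real_, usable = FALSE))
    }
    tibble(id = i, n_locs = est$n, area_km2 = est$area_km2,
           bw_x = est$bandwidth[1], bw_y = est$bandwidth[2], usable = TRUE)
  }) |> list_rbind()
}

#' Per-community spatial-dispersal threshold radii
#'
#' For each community, the threshold is the radius of a circle whose area is
#' the mean 95% kernel home-range area of its usable members:
#' `r = sqrt(mean(area) / pi)`. Communities with no usable member estimate
#' receive the global mean radius, with a warning.
#'
#' @param home_ranges Tibble from [kernel_home_ranges()].
#' @param membership Tibble with `id`, `community` (e.g. from
#'   [detect_communities()]).
#' @param pooled If `TRUE`, pool all member locations into one kernel per
#'   community instead of averaging member-specific areas. Requires
#'   `detections`.
#' @param detections Detection tibble, only needed when `pooled = TRUE`.
#' @param ... Passed to [kernel_isopleth_area()] when `pooled = TRUE`.
#' @return A tibble: `community`, `n_members`, `mean_area_km2`,
#'   `threshold_km`, `imputed`.
#' @examples
#' hr <- tibble::tibble(id = c("a", "b"), area_km2 = c(110, 120),
#'                      usable = TRUE)
#' mem <- tibble::tibble(id = c("a", "b"), community = 1)
#' threshold_radii(hr, mem)
#' @export
threshold_radii <- function(home_ranges, membership, pooled = FALSE,
                            detections = NULL, ...) {
  if (pooled) {
    if (is.null(detections)) abort("`pooled = TRUE` needs `detections`.")
    d <- project_coordinates(detections) |>
      dplyr::inner_join(membership, by = "id")
    out <- d |>
      group_by(.data$community) |>
      summarise(
        n_members = dplyr::n_distinct(.data$id),
        mean_area_km2 = kernel_isopleth_area(.data$x_km, .data$y_km, ...)$area_km2,
        .groups = "drop"
      ) |>
      mutate(threshold_km = circular_radius(.data$mean_area_km2),
             imputed = FALSE)
    return(out)
  }
  joined <- membership |>
    left_join(home_ranges, by = "id") |>
    group_by(.data$community) |>
    summarise(
      n_members = sum(.data$usable %in% TRUE),
      mean_area_km2 = mean(.data$area_km2[.data$usable %in% TRUE]),
      .groups = "drop"
    )
  if (any(joined$n_members == 0L)) {
    warn("Some communities have no usable home-range estimate; substituting the global mean radius.")
  }
  global_mean <- mean(joined$mean_area_km2[joined$n_members > 0L])
  joined |>
    mutate(
      imputed = .data$n_members == 0L,
      mean_area_km2 = if_else(.data$imputed, global_mean, .data$mean_area_km2),
      threshold_km = circular_radius(.data$mean_area_km2)
    ) |>
    select("community", "n_members", "mean_area_km2", "threshold_km", "imputed")
}
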