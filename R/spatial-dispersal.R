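#' Net-displacement series for calves
#'
#' For each individual, the Euclidean distance (km, planar frame) between
#' its first detection location and every successive location, ordered in
#' time. Individuals with fewer than two detections are dropped with a
#' message.
#'
#' @param detections Detection tibble with `id`, `occasion`, `x_km`/`y_km`
#'   (or lon/lat) and `age_months`.
#' @param ids Individuals to include; default [calf_ids()].
#' @return A tibble of class `displacement_series`: `id`, `occasion`,
#'   `age_months`, `distance_km` (first row of each id is 0).
#' @export
displacement_series <- function(detections, ids = NULL) {
  d <- project_coordinates(detections)
  stopifnot("age_months" %in% names(d))
  ids <- ids %||% calf_ids(d)
  d <- d |>
    filter(.data$id %in% ids) |>
    arrange(.data$id, .data$occasion)
  n_by_id <- d |> count(.data$id)
  few <- n_by_id$id[n_by_id$n < 2L]
  if (length(few)) {
    inform(sprintf("%d individual(s) with fewer than 2 detections dropped from displacement series.",
                   length(few)))
    d <- d |> filter(!.data$id %in% few)
  }
  out <- d |>
    group_by(.data$id) |>
    mutate(distance_km = sqrt((.data$x_km - first(.data$x_km))^2 +
                                (.data$y_km - first(.data$y_km))^2)) |>
    ungroup() |>
    select("id", "occasion", "age_months", "distance_km")
  class(out) <- c("displacement_series", class(out))
  out
}

#' Classify spatial dispersal with smoothed-crossing confirmation
#'
#' A calf whose final detection lies at or below its community threshold is
#' not a spatial disperser; its threshold exceedances (if any) are sorties.
#' For calves whose final detection is beyond the threshold, a local-linear
#' smoother (tricube weights, default span 0.75) is fitted to distance vs.
#' age and evaluated at the observation ages. If the fitted line never
#' exceeds the threshold the calf is not a disperser (all exceedances are
#' sorties). Otherwise, among observed detections from the first
#' fitted-line exceedance onward, a beyond-threshold fraction above one
#' half confirms spatial dispersal; the spatial dispersal age is the age at
#' the first observed exceedance in that confirmed phase, and earlier
#' exceedances remain sorties. Series too short to smooth fall back to the
#' final-distance rule and are flagged low-confidence.
#'
#' First-sortie age by default excludes sorties before
#' `mother_sortie_max_age` (8 months), which are attributed to travel with
#' the mother; all sortie ages are retained in `sortie_ages`.
#'
#' @param series A [displacement_series()] tibble.
#' @param threshold Either a single radius (km) or a tibble with `id` and
#'   `threshold_km`.
#' @param span Smoother span.
#' @param min_smooth_points Minimum detections needed to fit the smoother.
#' @param mother_sortie_max_age Age (months) below which sorties are
#'   attributed to the mother.
#' @param exclude_mother_sorties Apply the above exclusion to
#'   `first_sortie_age_months`.
#' @return Tibble of class `spatial_outcomes`: `id`, `n`, `threshold_km`,
#'   `final_km`, `max_km`, `spatial_flag`, `spatial_age_months`,
#'   `crossing_age_months`, `post_crossing_fraction`, `sortie_ages`
#'   (list), `first_sortie_age_months`, `low_confidence`.
#' @export
classify_spatial <- function(series, threshold, span = 0.75,
                             min_smooth_points = 4,
                             mother_sortie_max_age = 8,
                             exclude_mother_sorties = TRUE) {
  thr_tbl <- if (is.data.frame(threshold)) {
    as_tibble(threshold)[, c("id", "threshold_km")]
  } else {
    tibble(id = unique(series$id), threshold_km = as.numeric(threshold))
  }
  out <- split(as_tibble(series), series$id) |>
    imap(function(s, i) {
      s <- s |> arrange(.data$occasion)
      thr <- thr_tbl$threshold_km[thr_tbl$id == i]
      if (length(thr) == 0L || is.na(thr[1])) {
        abort(sprintf("No threshold available for individual %s.", i))
      }
      thr <- thr[1]
      classify_spatial_one(s, i, thr, span, min_smooth_points)
    }) |>
    list_rbind() |>
    mutate(
      first_sortie_age_months = map_dbl(.data$sortie_ages, function(a) {
        if (exclude_mother_sorties) a <- a[a >= mother_sortie_max_age]
        if (length(a) == 0L) NA_real_ else min(a)
      })
    )
  class(out) <- c("spatial_outcomes", class(out))
  out
}

classify_spatial_one <- function(s, id, thr, span, min_smooth_points) {
  dist <- s$distance_km
  age <- s$age_months
  n <- length(dist)
  beyond <- dist > thr
  final_km <- dist[n]
  max_km <- max(dist)
  res <- tibble(
    id = id, n = n, threshold_km = thr, final_km = final_km, max_km = max_km,
    spatial_flag = 0L, spatial_age_months = NA_real_,
    crossing_age_months = NA_real_, post_crossing_fraction = NA_real_,
    sortie_ages = list(numeric(0)), low_confidence = FALSE
  )
  if (final_km <= thr) {
    res$sortie_ages <- list(age[beyond])
    return(res)
  }
  if (n < min_smooth_points) {
    # too short to smooth: final-distance rule, flagged
    res$spatial_flag <- 1L
    res$spatial_age_months <- age[which(beyond)[1]]
    res$low_confidence <- TRUE
    res$sortie_ages <- list(age[beyond & age < res$spatial_age_months])
    return(res)
  }
  fit <- tryCatch(
    loess(dist ~ age, degree = 1, span = span, family = "gaussian",
          surface = "direct"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res$spatial_flag <- 1L
    res$spatial_age_months <- age[which(beyond)[1]]
    res$low_confidence <- TRUE
    res$sortie_ages <- list(age[beyond & age < res$spatial_age_months])
    return(res)
  }
  fitted_vals <- predict(fit, newdata = data.frame(age = age))
  cross <- which(fitted_vals > thr)
  if (length(cross) == 0L) {
    # smoothed displacement never shifted: exceedances are sorties
    res$sortie_ages <- list(age[beyond])
    return(res)
  }
  ci <- cross[1]
  res$crossing_age_months <- age[ci]
  post <- seq(ci, n)
  frac <- mean(beyond[post])
  res$post_crossing_fraction <- frac
  if (frac > 0.5) {
    res$spatial_flag <- 1L
    first_beyond_post <- post[which(beyond[post])[1]]
    res$spatial_age_months <- age[first_beyond_post]
    res$sortie_ages <- list(age[beyond & seq_len(n) < first_beyond_post])
  } else {
    res$sortie_ages <- list(age[beyond])
  }
  res
}

#' Combine social and spatial outcomes into a four-level dispersal record
#'
#' Crosses the two binary flags into the exhaustive, mutually exclusive
#' classification `none` / `social` (social-only) / `spatial`
#' (spatial-only) / `both` (social-and-spatial), carrying distances, ages
#' and sortie history. Calves with an undetermined social outcome keep
#' `NA` class and are excluded from models by default.
#'
#' @param social Output of [classify_social()].
#' @param spatial Output of [classify_spatial()].
#' @return Tibble of class `dispersal_records`: one row per calf with
#'   `dispersal_class` (factor), flags, ages (months), `dispersal_age_months`
#'   (earliest evidence of either kind), distances (km), sortie and visit
#'   counts, and bookkeeping flags.
#' @export
combine_outcomes <- function(social, spatial) {
  rec <- dplyr::inner_join(
    as_tibble(social), as_tibble(spatial), by = "id"
  ) |>
    mutate(
      dispersal_class = factor(
        dplyr::case_when(
          .data$undetermined ~ NA_character_,
          .data$social_flag == 1L & .data$spatial_flag == 1L ~ "both",
          .data$social_flag == 1L ~ "social",
          .data$spatial_flag == 1L ~ "spatial",
          TRUE ~ "none"
        ),
        levels = c("none", "social", "spatial", "both")
      ),
      dispersal_age_months = pmin(.data$social_age_months,
                                  .data$spatial_age_months, na.rm = TRUE)
    ) |>
    select("id", "dispersal_class", "natal_community", "social_flag",
           "spatial_flag", "social_age_months", "spatial_age_months",
           "dispersal_age_months", "final_km", "max_km", "threshold_km",
           "destinations", "n_exploratory_visits", "sortie_ages",
           "first_sortie_age_months", "single_terminal", "undetermined",
           "low_confidence")
  class(rec) <- c("dispersal_records", class(rec))
  rec
}

#' Run the full dispersal classification pipeline
#'
#' Orchestrates the whole classification stage on a detection table:
#' projects coordinates, estimates ages from heights, builds the
#' adult-female association network and its community partition, assigns
#' calf detections to communities and classifies social dispersal, derives
#' per-community threshold radii from 95% kernel home ranges, computes
#' net-displacement series and classifies spatial dispersal, and combines
#' both into four-level dispersal records.
#'
#' @param detections Detection tibble (simulated or field).
#' @param curve A [growth_curve()] for photogrammetric ageing.
#' @param partition Optional precomputed [detect_communities()] partition.
#' @param seed Seed for community detection.
#' @param min_locs Minimum locations per adult female home range.
#' @param span Spatial smoother span.
#' @param weaning_age Weaning cap (months) for natal assignment.
#' @param assign_method Group-assignment rule, `"majority"` or
#'   `"unanimous"`.
#' @param hr_grid_n Kernel grid resolution.
#' @return An object of class `dispersal_analysis`: list with `records`,
#'   `partition`, `thresholds`, `home_ranges`, `timelines`, `series`,
#'   `natal`.
#' @examples
#' \donttest{
#' soc <- simulate_society(sim_config(n_communities = 4,
#'   members_per_community = c(10, 12), n_calves = 20, seed = 3))
#' an <- run_dispersal_analysis(soc$detections)
#' an$records
#' }
#' @export
run_dispersal_analysis <- function(detections, curve = growth_curve(),
                                   partition = NULL, seed = 1L,
                                   min_locs = 10, span = 0.75,
                                   weaning_age = 18,
                                   assign_method = "majority",
                                   hr_grid_n = 200) {
  d <- project_coordinates(detections)
  d <- add_estimated_ages(d, curve)
  af <- adult_females(d)
  if (is.null(partition)) {
    gbi <- build_gbi(d, adult_ids = af)
    sri <- simple_ratio_index(gbi)
    partition <- detect_communities(sri, seed = seed)
  }
  calves <- calf_ids(d)
  tl <- community_timelines(d, partition, ids = calves, method = assign_method)
  nat <- natal_community(tl, weaning_age)
  soc <- classify_social(tl, nat, weaning_age)
  hr <- kernel_home_ranges(d, ids = partition_membership(partition)$id,
                           min_locs = min_locs, grid_n = hr_grid_n)
  thr <- threshold_radii(hr, partition_membership(partition))
  # per-calf threshold: natal community's radius, global mean when unknown
  global_thr <- mean(thr$threshold_km)
  thr_by_calf <- nat |>
    left_join(thr |> select("community", "threshold_km"),
              by = c(natal_community = "community")) |>
    mutate(threshold_km = dplyr::coalesce(.data$threshold_km, global_thr)) |>
    select("id", "threshold_km")
  series <- displacement_series(d, ids = calves)
  kept <- unique(series$id)
  spa <- classify_spatial(series, thr_by_calf |> filter(.data$id %in% kept),
                          span = span)
  records <- combine_outcomes(soc, spa) |>
    left_join(d |> distinct(.data$id, .data$sex), by = "id") |>
    dplyr::relocate("sex", .after = "id")
  structure(
    list(records = records, partition = partition, thresholds = thr,
         home_ranges = hr, timelines = tl, series = series, natal = nat),
    class = "dispersal_analysis"
  )
}

#' @export
print.dispersal_analysis <- function(x, ...) {
  cat("<dispersal_analysis>\n")
  cat(sprintf("  %d calves classified against %d communities (Q = %.3f)\n",
              nrow(x$records), x$partition$n_communities,
              x$partition$modularity))
  print(table(x$records$dispersal_class, useNA = "ifany"))
  invisible(x)
}
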