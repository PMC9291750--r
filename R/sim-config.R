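#' Configuration for the synthetic fission-fusion society
#'
#' Bundles every parameter of the society generator with validated defaults.
#' The defaults emulate the survey design the classifier targets: 12 spatially
#' overlapping adult-female communities of 60-90 members, 7 years of 3
#' precipitation-season surveys with paired secondary samples (42 occasions),
#' calves born in the first two years with planted dispersal fates, and
#' per-occasion detection probability 0.9.
#'
#' Movement is a fixed home-range centre per adult female with
#' per-occasion bivariate-normal scatter (`hr_sigma`), so each female's 95%
#' utilization isopleth has the closed-form area
#' \eqn{\chi^2_{2,0.95}\,\pi\,\sigma^2 \approx 5.991 \pi \sigma^2}. The
#' default `hr_sigma = 2.5` km gives ~118 km^2, matching field estimates of
#' ~115 km^2 for adult females. Calves range over a tighter core around the
#' natal centre (`calf_sigma`), reflecting that pre-dispersal calves do not
#' use the full adult range.
#'
#' @param n_communities Number of adult-female communities (>= 2).
#' @param members_per_community Length-2 integer range; each community's size
#'   is drawn uniformly from it.
#' @param hr_center_spacing Distance (km) between neighbouring community
#'   centres on a planar grid.
#' @param hr_sigma Adult per-occasion movement scatter (km).
#' @param calf_sigma Calf per-occasion scatter about its current centre (km).
#' @param center_jitter_sd SD (km) of individual home-range-centre jitter
#'   around the community centre.
#' @param n_years,seasons_per_year,secondary_per_primary Survey calendar:
#'   `n_years * seasons_per_year * secondary_per_primary` occasions.
#' @param p_detect Per-occasion detection probability.
#' @param group_mixing Probability that a fission-fusion group is merged with
#'   a group from an adjacent community (cross-community group).
#' @param crp_theta Concentration of the Chinese-restaurant group-formation
#'   process; larger values give more, smaller groups.
#' @param n_calves Number of calves born in study years 1-2.
#' @param fate_probs Named list (`F`, `M`) of 4-probability vectors over
#'   dispersal fates `none`, `social`, `spatial`, `both`; each sums to 1.
#'   Ignored when `covariate_effects` is supplied.
#' @param dispersal_age_mean,dispersal_age_sd,dispersal_age_range Normal
#'   dispersal-age distribution (months), truncated to the range; the lower
#'   bound must exceed weaning (18 months).
#' @param sortie_rate Per-occasion probability of a single-occasion
#'   threshold exceedance (with return) before dispersal.
#' @param spatial_shift_mean,spatial_shift_sd Mean (named `spatial`, `both`)
#'   and SD (km) of the planted relocation distance for spatial dispersers.
#' @param height_noise_sd Photogrammetric height measurement noise (cm).
#' @param growth A [growth_curve()] shared with the ageing module.
#' @param covariate_effects Optional multinomial-logit generator for fates: a
#'   named list with elements `social`, `spatial`, `both`, each a named
#'   coefficient vector over any of `(Intercept)`, `sexM`, `forage`,
#'   `dist_town`, `dist_boma`, `density`; `none` is the reference.
#' @param start_year First calendar year of the survey.
#' @param origin_lonlat Named vector (`lon`, `lat`) anchoring the planar
#'   simulation frame on the globe (degrees).
#' @param seed Integer; fully determines the simulated society.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_communities = 3, members_per_community = c(8, 10),
#'                   n_calves = 12, seed = 42)
#' @export
sim_config <- function(n_communities = 12,
                       members_per_community = c(60L, 90L),
                       hr_center_spacing = 10,
                       hr_sigma = 2.5,
                       calf_sigma = 1.2,
                       center_jitter_sd = 1.5,
                       n_years = 7,
                       seasons_per_year = 3,
                       secondary_per_primary = 2,
                       p_detect = 0.9,
                       group_mixing = 0.05,
                       crp_theta = 10,
                       n_calves = 200,
                       fate_probs = list(
                         F = c(none = 0.74, social = 0.06,
                               spatial = 0.13, both = 0.07),
                         M = c(none = 0.31, social = 0.18,
                               spatial = 0.12, both = 0.39)
                       ),
                       dispersal_age_mean = 46,
                       dispersal_age_sd = 16,
                       dispersal_age_range = c(20, 78),
                       sortie_rate = 0.03,
                       spatial_shift_mean = c(spatial = 11, both = 16.5),
                       spatial_shift_sd = 2,
                       height_noise_sd = 10,
                       growth = growth_curve(),
                       covariate_effects = NULL,
                       start_year = 2012,
                       origin_lonlat = c(lon = 36.0, lat = -4.0),
                       seed = 1L) {
  if (n_communities < 2) abort("`n_communities` must be at least 2.")
  members_per_community <- as.integer(round(members_per_community))
  if (length(members_per_community) == 1L) {
    members_per_community <- rep(members_per_community, 2L)
  }
  if (members_per_community[1] < 5L) {
    abort("`members_per_community` too small to form fission-fusion groups (need >= 5).")
  }
  for (r in c(p_detect, group_mixing, sortie_rate)) {
    if (r < 0 || r > 1) abort("Rates must lie in [0, 1].")
  }
  fates <- c("none", "social", "spatial", "both")
  for (s in c("F", "M")) {
    fp <- fate_probs[[s]]
    if (is.null(fp) || !setequal(names(fp), fates)) {
      abort("`fate_probs` must contain vectors named over none/social/spatial/both for both sexes.")
    }
    if (abs(sum(fp) - 1) > 1e-8 || any(fp < 0)) {
      abort(sprintf("`fate_probs$%s` must be a probability vector summing to 1.", s))
    }
    fate_probs[[s]] <- fp[fates]
  }
  if (dispersal_age_range[1] <= 18) {
    abort("Planted dispersal ages must exceed the 18-month weaning cap.")
  }
  if (!is.null(covariate_effects)) {
    if (!all(c("social", "spatial", "both") %in% names(covariate_effects))) {
      abort("`covariate_effects` needs elements social, spatial, both.")
    }
  }
  stopifnot(inherits(growth, "growth_curve"),
            hr_sigma > 0, calf_sigma > 0, crp_theta > 0, n_calves >= 1)
  structure(
    list(
      n_communities = as.integer(n_communities),
      members_per_community = members_per_community,
      hr_center_spacing = hr_center_spacing,
      hr_sigma = hr_sigma,
      calf_sigma = calf_sigma,
      center_jitter_sd = center_jitter_sd,
      n_years = as.integer(n_years),
      seasons_per_year = as.integer(seasons_per_year),
      secondary_per_primary = as.integer(secondary_per_primary),
      p_detect = p_detect,
      group_mixing = group_mixing,
      crp_theta = crp_theta,
      n_calves = as.integer(n_calves),
      fate_probs = fate_probs,
      dispersal_age_mean = dispersal_age_mean,
      dispersal_age_sd = dispersal_age_sd,
      dispersal_age_range = dispersal_age_range,
      sortie_rate = sortie_rate,
      spatial_shift_mean = spatial_shift_mean,
      spatial_shift_sd = spatial_shift_sd,
      height_noise_sd = height_noise_sd,
      growth = growth,
      covariate_effects = covariate_effects,
      start_year = as.integer(start_year),
      origin_lonlat = origin_lonlat,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d communities of %d-%d adult females, %d occasions (%d y x %d seasons x %d)\n",
              x$n_communities, x$members_per_community[1], x$members_per_community[2],
              x$n_years * x$seasons_per_year * x$secondary_per_primary,
              x$n_years, x$seasons_per_year, x$secondary_per_primary))
  cat(sprintf("  %d calves, p_detect %.2f, group_mixing %.2f, seed %d\n",
              x$n_calves, x$p_detect, x$group_mixing, x$seed))
  invisible(x)
}

# analytic 95% isopleth radius of the generating movement model
generating_threshold <- function(config) {
  config$hr_sigma * sqrt(qchisq(0.95, df = 2))
}

#' Write / read a simulation configuration as a YAML file
#'
#' Scalar and vector fields round-trip; the growth curve is stored by its
#' parameters.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$growth <- unclass(config$growth)
  x$growth$h_inf <- as.list(config$growth$h_inf)
  x$fate_probs <- lapply(config$fate_probs, as.list)
  x$spatial_shift_mean <- as.list(config$spatial_shift_mean)
  x$origin_lonlat <- as.list(config$origin_lonlat)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  g <- x$growth
  x$growth <- growth_curve(h0 = g$h0, h_inf = unlist(g$h_inf), k = g$k,
                           adult_cap = g$adult_cap, eps = g$eps)
  x$fate_probs <- lapply(x$fate_probs, unlist)
  x$spatial_shift_mean <- unlist(x$spatial_shift_mean)
  x$origin_lonlat <- unlist(x$origin_lonlat)
  do.call(sim_config, x)
}
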