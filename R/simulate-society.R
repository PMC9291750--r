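#' Simulate a multi-level fission-fusion society with known dispersal truth
#'
#' Generates a photographic-resight detection table together with the ground
#' truth needed to validate every stage of the dispersal pipeline: the adult
#' female community roster, and for each calf its birth community, planted
#' dispersal fate (`none`, `social`, `spatial`, `both`), planted dispersal
#' age, destination community and planted sortie occasions.
#'
#' Adult females move around fixed home-range centres (bivariate-normal
#' per-occasion scatter). Each occasion, the members of a community present
#' are partitioned into fission-fusion groups by a Chinese-restaurant
#' process; with probability `group_mixing` a group is merged with a group
#' from an adjacent community. Calves sample groups of their natal community
#' (and stay near the natal centre) until their planted dispersal age, then:
#' social dispersers switch group-sampling to a neighbouring community
#' without relocating; spatial dispersers relocate beyond the natal
#' community's generating threshold radius while still sampling natal
#' groups; social-and-spatial dispersers relocate and switch to the
#' community nearest their new centre. Sorties are single-occasion
#' exceedances with return. Detection is Bernoulli(`p_detect`) per
#' individual and occasion, and measured heights follow the shared growth
#' curve plus noise.
#'
#' Group membership is a social label: recorded coordinates are individual
#' draws from each animal's own movement model, so members of one group are
#' not constrained to a common location (the downstream analysis never uses
#' within-group spatial coherence).
#'
#' @param config A [sim_config()].
#' @return An object of class `society`: a list with tibbles `detections`
#'   (one row per individual per detection: `id`, `occasion`, `year`,
#'   `season`, `secondary`, `date`, `group_id`, `x_km`, `y_km`, `lon`,
#'   `lat`, `sex`, `age_class`, `height_cm`), `truth` (per-calf ground
#'   truth), `adults` (roster with true community), `communities` (centres
#'   and socio-ecological covariates), plus the `config`.
#' @examples
#' soc <- simulate_society(sim_config(n_communities = 3,
#'   members_per_community = c(8, 10), n_calves = 10, seed = 7))
#' soc$truth
#' @export
simulate_society <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  K <- config$n_communities
  cal <- occasion_calendar(config)
  n_occ <- nrow(cal)

  ## -- communities: grid centres + covariates ------------------------------
  ncol_grid <- ceiling(sqrt(K))
  idx <- seq_len(K) - 1L
  communities <- tibble(
    community = seq_len(K),
    center_x = (idx %% ncol_grid) * config$hr_center_spacing,
    center_y = (idx %/% ncol_grid) * config$hr_center_spacing,
    forage = runif(K, 0.1, 0.6),
    dist_town = runif(K, 2, 30),
    dist_boma = runif(K, 0.5, 10),
    density = runif(K, 0.5, 2)
  )
  cdist <- as.matrix(stats::dist(communities[, c("center_x", "center_y")]))
  neighbours <- lapply(seq_len(K), function(k) {
    ord <- order(cdist[k, ])
    setdiff(ord, k)[seq_len(min(4L, K - 1L))] # up to 4 nearest communities
  })

  ## -- adult females -------------------------------------------------------
  sizes <- sample(seq(config$members_per_community[1],
                      config$members_per_community[2]), K, replace = TRUE)
  n_adults <- sum(sizes)
  adults <- tibble(
    id = sprintf("A%04d", seq_len(n_adults)),
    community = rep(seq_len(K), sizes),
    sex = "F",
    age_start_months = round(runif(n_adults, 60, 240))
  ) |>
    mutate(
      center_x = communities$center_x[.data$community] +
        rnorm(n_adults, 0, config$center_jitter_sd),
      center_y = communities$center_y[.data$community] +
        rnorm(n_adults, 0, config$center_jitter_sd)
    )

  ## -- calves: fates, ages, destinations -----------------------------------
  truth <- plant_calves(config, communities, neighbours, max(cal$t_months))

  ## -- presence table ------------------------------------------------------
  ad_pres <- tidyr::expand_grid(id = adults$id, occasion = cal$occasion) |>
    left_join(adults |> select("id", "community", "center_x", "center_y"),
              by = "id") |>
    left_join(cal, by = "occasion") |>
    mutate(assoc = .data$community, kind = "adult")

  calf_pres <- tidyr::expand_grid(id = truth$id, occasion = cal$occasion) |>
    left_join(truth, by = "id") |>
    left_join(cal, by = "occasion") |>
    mutate(age_months = .data$t_months - .data$birth_t) |>
    filter(.data$age_months >= 0) |>
    mutate(
      dispersed = !is.na(.data$dispersal_age_months) &
        .data$age_months >= .data$dispersal_age_months,
      assoc = if_else(.data$dispersed & .data$fate %in% c("social", "both"),
                      .data$destination_community, .data$birth_community),
      kind = "calf"
    )

  ## planted sorties: pre-dispersal occasions, never among a calf's first
  ## two present occasions (the first detection anchors net displacement)
  calf_pres <- calf_pres |>
    group_by(.data$id) |>
    arrange(.data$occasion, .by_group = TRUE) |>
    mutate(sortie = !.data$dispersed & row_number() > 2L &
             runif(dplyr::n()) < config$sortie_rate) |>
    ungroup()
  sortie_tbl <- calf_pres |>
    filter(.data$sortie) |>
    group_by(.data$id) |>
    summarise(sortie_occasions = paste(.data$occasion, collapse = ";"),
              .groups = "drop")
  truth <- truth |>
    left_join(sortie_tbl, by = "id") |>
    mutate(sortie_occasions = dplyr::coalesce(.data$sortie_occasions, ""))

  ## -- group formation per occasion ----------------------------------------
  pres <- bind_rows(
    ad_pres |> select("id", "occasion", "assoc", "kind"),
    calf_pres |> select("id", "occasion", "assoc", "kind")
  ) |> arrange(.data$occasion, .data$assoc, .data$id)

  pres_split <- split(pres, pres$occasion)
  grouped <- lapply(pres_split, function(po) {
    occ <- po$occasion[1]
    ids_by_comm <- split(po$id, po$assoc)
    groups <- list()   # each: list(ids, community)
    for (cm in names(ids_by_comm)) {
      ids <- ids_by_comm[[cm]]
      part <- crp_partition(length(ids), config$crp_theta)
      ids <- ids[sample.int(length(ids))] # random seating order
      for (g in split(ids, part)) {
        groups[[length(groups) + 1L]] <- list(ids = g, community = as.integer(cm))
      }
    }
    ## cross-community merges
    gcomm <- vapply(groups, `[[`, integer(1), "community")
    merged <- rep(FALSE, length(groups))
    target <- seq_along(groups)
    for (i in sample.int(length(groups))) {
      if (merged[i]) next
      if (runif(1) >= config$group_mixing) next
      nb <- neighbours[[gcomm[i]]]
      cand <- which(!merged & gcomm %in% nb & target == seq_along(groups))
      cand <- setdiff(cand, i)
      if (length(cand) == 0L) next
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      target[j] <- i
      merged[i] <- TRUE
      merged[j] <- TRUE
    }
    gid <- sprintf("O%03dG%03d", occ, match(target, sort(unique(target))))
    tibble(
      id = unlist(lapply(groups, `[[`, "ids")),
      occasion = occ,
      group_id = rep(gid, vapply(groups, function(g) length(g$ids), integer(1)))
    )
  })
  group_tbl <- list_rbind(grouped)

  ## -- locations ------------------------------------------------------------
  ad_loc <- ad_pres |>
    mutate(
      x_km = .data$center_x + rnorm(dplyr::n(), 0, config$hr_sigma),
      y_km = .data$center_y + rnorm(dplyr::n(), 0, config$hr_sigma),
      sex = "F"
    ) |>
    left_join(adults |> select("id", "age_start_months"), by = "id") |>
    mutate(age_months = .data$age_start_months + .data$t_months) |>
    select("id", "occasion", "t_months", "x_km", "y_km", "sex", "age_months")

  gen_r <- generating_threshold(config)
  n_cp <- nrow(calf_pres)
  calf_loc <- calf_pres |>
    mutate(
      cur_x = if_else(.data$dispersed & .data$fate %in% c("spatial", "both"),
                      .data$natal_x + .data$shift_x, .data$natal_x),
      cur_y = if_else(.data$dispersed & .data$fate %in% c("spatial", "both"),
                      .data$natal_y + .data$shift_y, .data$natal_y),
      ang = runif(n_cp, 0, 2 * pi),
      x_km = if_else(.data$sortie,
                     .data$natal_x + 1.3 * gen_r * cos(.data$ang),
                     .data$cur_x + rnorm(n_cp, 0, config$calf_sigma)),
      y_km = if_else(.data$sortie,
                     .data$natal_y + 1.3 * gen_r * sin(.data$ang),
                     .data$cur_y + rnorm(n_cp, 0, config$calf_sigma))
    ) |>
    select("id", "occasion", "t_months", "x_km", "y_km", "sex", "age_months")

  ## -- detections -----------------------------------------------------------
  det <- bind_rows(ad_loc, calf_loc) |>
    mutate(detected = runif(dplyr::n()) < config$p_detect) |>
    filter(.data$detected) |>
    left_join(group_tbl, by = c("id", "occasion")) |>
    left_join(cal |> select("occasion", "year", "season", "secondary", "date"),
              by = "occasion") |>
    mutate(
      height_cm = height_at_age(pmin(.data$age_months, 300), .data$sex,
                                config$growth) +
        rnorm(dplyr::n(), 0, config$height_noise_sd),
      age_class = assign_age_class(.data$age_months)
    )

  ll <- tm_inverse(det$x_km, det$y_km,
                   lon0 = config$origin_lonlat[["lon"]],
                   lat0 = config$origin_lonlat[["lat"]])
  det$lon <- ll$lon
  det$lat <- ll$lat

  detections <- det |>
    arrange(.data$occasion, .data$group_id, .data$id) |>
    select("id", "occasion", "year", "season", "secondary", "date",
           "group_id", "x_km", "y_km", "lon", "lat", "sex", "age_class",
           "height_cm")

  truth_out <- truth |>
    select("id", "sex", "birth_community", "fate", "dispersal_age_months",
           "destination_community", "birth_t", "natal_x", "natal_y",
           "shift_km", "sortie_occasions")

  structure(
    list(detections = detections, truth = truth_out, adults = adults,
         communities = communities, config = config),
    class = "society"
  )
}

#' @export
print.society <- function(x, ...) {
  cat("<society>\n")
  cat(sprintf("  %d detections of %d adults + %d calves in %d communities\n",
              nrow(x$detections), nrow(x$adults), nrow(x$truth),
              nrow(x$communities)))
  invisible(x)
}

## survey calendar: (year, season, secondary) -> occasion index and a
## continuous month clock t_months from study start
occasion_calendar <- function(config) {
  sy <- config$seasons_per_year
  sec <- config$secondary_per_primary
  season_month <- floor((seq_len(sy) - 1L) * 12 / sy) + 1L
  grid <- tidyr::expand_grid(
    year_index = seq_len(config$n_years),
    season = seq_len(sy),
    secondary = seq_len(sec)
  )
  grid |>
    mutate(
      occasion = row_number(),
      year = config$start_year + .data$year_index - 1L,
      month = season_month[.data$season],
      t_months = (.data$year_index - 1L) * 12 + (.data$month - 1L) +
        (.data$secondary - 1L) * 0.25,
      date = as.Date(sprintf("%d-%02d-%02d", .data$year, .data$month,
                             1L + (.data$secondary - 1L) * 7L))
    ) |>
    select("occasion", "year_index", "year", "season", "secondary",
           "month", "t_months", "date")
}

## sequential Chinese-restaurant partition of n items, concentration theta
crp_partition <- function(n, theta) {
  g <- integer(n)
  g[1L] <- 1L
  k <- 1L
  counts <- 1
  if (n > 1L) {
    for (i in 2:n) {
      j <- sample.int(k + 1L, 1L, prob = c(counts, theta))
      if (j > k) {
        k <- k + 1L
        counts <- c(counts, 1)
      } else {
        counts[j] <- counts[j] + 1
      }
      g[i] <- j
    }
  }
  g
}

## draw calf ground truth: sex, birth community/time, fate, dispersal age,
## relocation vector and destination community. Planted dispersal ages are
## bounded by each calf's observable window (study end minus 4 months) so
## every planted fate is expressed during the study.
plant_calves <- function(config, communities, neighbours, t_end) {
  n <- config$n_calves
  K <- config$n_communities
  fates <- c("none", "social", "spatial", "both")
  sex <- sample(c("F", "M"), n, replace = TRUE)
  birth_comm <- sample.int(K, n, replace = TRUE)
  birth_t <- runif(n, 0, 24) # months from study start, years 1-2

  if (is.null(config$covariate_effects)) {
    fate <- vapply(sex, function(s) {
      sample(fates, 1L, prob = config$fate_probs[[s]])
    }, character(1))
  } else {
    X <- cbind(
      `(Intercept)` = 1,
      sexM = as.numeric(sex == "M"),
      forage = communities$forage[birth_comm],
      dist_town = communities$dist_town[birth_comm],
      dist_boma = communities$dist_boma[birth_comm],
      density = communities$density[birth_comm]
    )
    eta <- vapply(c("social", "spatial", "both"), function(f) {
      b <- config$covariate_effects[[f]]
      as.vector(X[, names(b), drop = FALSE] %*% b)
    }, numeric(n))
    P <- cbind(none = 1, exp(eta))
    P <- P / rowSums(P)
    fate <- vapply(seq_len(n), function(i) {
      sample(fates, 1L, prob = P[i, fates])
    }, character(1))
  }

  disp_age <- rep(NA_real_, n)
  for (i in which(fate != "none")) {
    upper <- max(min(config$dispersal_age_range[2], t_end - birth_t[i] - 4),
                 config$dispersal_age_range[1] + 1)
    disp_age[i] <- rtrunc_norm(1L, config$dispersal_age_mean,
                               config$dispersal_age_sd,
                               c(config$dispersal_age_range[1], upper))
  }

  gen_r <- generating_threshold(config)
  shift_km <- rep(0, n)
  shift_x <- rep(0, n)
  shift_y <- rep(0, n)
  relocates <- fate %in% c("spatial", "both")
  if (any(relocates)) {
    len <- vapply(fate[relocates], function(f) {
      rtrunc_norm(1L, config$spatial_shift_mean[[f]],
                  config$spatial_shift_sd, c(gen_r + 3, Inf))
    }, numeric(1))
    ang <- runif(sum(relocates), 0, 2 * pi)
    shift_km[relocates] <- len
    shift_x[relocates] <- len * cos(ang)
    shift_y[relocates] <- len * sin(ang)
  }

  natal_x <- communities$center_x[birth_comm] +
    rnorm(n, 0, config$center_jitter_sd)
  natal_y <- communities$center_y[birth_comm] +
    rnorm(n, 0, config$center_jitter_sd)

  dest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (fate[i] == "social") {
      nb <- neighbours[[birth_comm[i]]]
      dest[i] <- nb[sample.int(min(2L, length(nb)), 1L)]
    } else if (fate[i] == "both") {
      px <- natal_x[i] + shift_x[i]
      py <- natal_y[i] + shift_y[i]
      d2 <- (communities$center_x - px)^2 + (communities$center_y - py)^2
      ord <- order(d2)
      dest[i] <- ord[ord != birth_comm[i]][1L]
    }
  }

  tibble(
    id = sprintf("C%04d", seq_len(n)),
    sex = sex,
    birth_community = birth_comm,
    birth_t = birth_t,
    fate = fate,
    dispersal_age_months = disp_age,
    destination_community = dest,
    natal_x = natal_x, natal_y = natal_y,
    shift_x = shift_x, shift_y = shift_y, shift_km = shift_km
  )
}

## truncated-normal draws by rejection (ranges used are wide enough)
rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}
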