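# Shared simulated societies, built once per test run.
.society_cache <- new.env(parent = emptyenv())

cached_society <- function(name, cfg) {
  if (is.null(.society_cache[[name]])) {
    .society_cache[[name]] <- simulate_society(cfg)
  }
  .society_cache[[name]]
}

# small 4-community society used across module tests
small_cfg <- function(...) {
  sim_config(n_communities = 4, members_per_community = c(14, 16),
             n_calves = 30, seed = 11, ...)
}

small_society <- function() cached_society("small", small_cfg())

cached_analysis_small <- function() {
  if (is.null(.society_cache[["small_analysis"]])) {
    .society_cache[["small_analysis"]] <-
      run_dispersal_analysis(small_society()$detections, seed = 1)
  }
  .society_cache[["small_analysis"]]
}

# full default-scale society shared by the acceptance checks
default_society <- function() cached_society("default", sim_config(seed = 101))

default_analysis <- function() {
  if (is.null(.society_cache[["default_analysis"]])) {
    .society_cache[["default_analysis"]] <-
      run_dispersal_analysis(default_society()$detections, seed = 1)
  }
  .society_cache[["default_analysis"]]
}

# build a detection tibble by hand from group membership lists:
# groups = list(list(occasion=, ids=, sexes=, classes=))
manual_detections <- function(groups) {
  rows <- lapply(seq_along(groups), function(g) {
    gr <- groups[[g]]
    n <- length(gr$ids)
    tibble::tibble(
      id = gr$ids,
      occasion = gr$occasion,
      year = 2012L + (gr$occasion - 1L) %/% 6L,
      group_id = sprintf("O%03dG%03d", gr$occasion, g),
      x_km = gr$x %||% rep(0, n),
      y_km = gr$y %||% rep(0, n),
      sex = gr$sexes %||% rep("F", n),
      age_class = gr$classes %||% rep("adult", n),
      age_months = gr$ages %||% rep(60, n)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- rlang::`%||%`
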