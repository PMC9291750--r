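#' Read and write detection tables
#'
#' Detection tables are plain CSV with one row per individual per sighting
#' (`id`, `occasion`, `date`, `group_id`, `x_km`, `y_km`, `lon`, `lat`,
#' `sex`, `age_class`, `height_cm`; extra columns pass through).
#'
#' @param path CSV path.
#' @param detections Detection tibble.
#' @return `read_detections()` returns a tibble; writers return the path
#'   invisibly.
#' @export
read_detections <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(date = as.Date(.data$date))
}

#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(as_tibble(detections), path)
  invisible(path)
}

#' Write analysis outputs as CSV
#'
#' Writes the per-calf dispersal records (list columns flattened to
#' `;`-separated strings), the threshold table, home-range estimates, and
#' the community membership into a directory.
#'
#' @param analysis A `dispersal_analysis` from [run_dispersal_analysis()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dispersal_outputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "dispersal_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- analysis$records |>
    mutate(
      destinations = map_chr(.data$destinations,
                             function(d) paste(d, collapse = ";")),
      sortie_ages = map_chr(.data$sortie_ages, function(a) {
        paste(round(a, 1), collapse = ";")
      })
    )
  readr::write_csv(rec, file.path(dir, "dispersal_records.csv"))
  readr::write_csv(analysis$thresholds, file.path(dir, "threshold_radii.csv"))
  readr::write_csv(analysis$home_ranges, file.path(dir, "home_ranges.csv"))
  readr::write_csv(analysis$partition$membership,
                   file.path(dir, "community_membership.csv"))
  invisible(dir)
}

#' Write an association matrix as a long-format edge list
#'
#' @param assoc Matrix from [simple_ratio_index()].
#' @param path CSV path (`id_a`, `id_b`, `sri`; upper triangle only).
#' @export
write_association_edges <- function(assoc, path) {
  ids <- rownames(assoc)
  ut <- which(upper.tri(assoc), arr.ind = TRUE)
  readr::write_csv(
    tibble(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
           sri = assoc[ut]),
    path
  )
  invisible(path)
}
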