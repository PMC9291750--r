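#' Append estimated ages (months) to a detection table
#'
#' Each detection's height is inverted through the growth curve
#' ([age_from_height()]). Because the curve flattens with age, single-height
#' ages are precise for young animals and noisy near the asymptote, so ages
#' are anchored where possible: for every individual with at least one
#' detection whose height-based age is below `anchor_max_age` months, a
#' birth date is estimated as the median of (detection time - height age)
#' over those young detections, and all of that individual's ages are then
#' computed as elapsed time since the estimated birth. Individuals never
#' seen young fall back to per-detection height ages.
#'
#' @param detections Detection tibble with `date`, `sex`, `height_cm`.
#' @param curve A [growth_curve()].
#' @param anchor_max_age Maximum height-based age (months) for a detection
#'   to serve as a birth-date anchor.
#' @return The input tibble with `age_months` and `age_basis`
#'   (`"anchored"` or `"height"`) columns added.
#' @export
add_estimated_ages <- function(detections, curve = growth_curve(),
                               anchor_max_age = 24) {
  d <- as_tibble(detections)
  stopifnot(all(c("date", "sex", "height_cm") %in% names(d)))
  t_months <- date_to_months(d$date)
  inv <- age_from_height(d$height_cm, d$sex, curve)
  d$.age_h <- inv$age_months
  d$.anchor <- !inv$censored & !inv$rejected & inv$age_months <= anchor_max_age
  d$.t <- t_months
  d |>
    group_by(.data$id) |>
    mutate(
      .birth = if (any(.data$.anchor)) {
        median(.data$.t[.data$.anchor] - .data$.age_h[.data$.anchor])
      } else NA_real_,
      age_months = if_else(is.na(.data$.birth), .data$.age_h,
                           .data$.t - .data$.birth),
      age_basis = if_else(is.na(.data$.birth), "height", "anchored")
    ) |>
    ungroup() |>
    mutate(age_months = pmax(.data$age_months, 0)) |>
    select(-".age_h", -".anchor", -".t", -".birth")
}

## calendar date -> continuous month scale
date_to_months <- function(date) {
  lt <- as.POSIXlt(date)
  (lt$year + 1900) * 12 + lt$mon + (lt$mday - 1) / 30.44
}
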