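#' Number of non-overlapping home-range equivalents in an area
#'
#' A coarse capacity check used when judging whether a study area is large
#' enough to detect a range of dispersal movements: how many average
#' home ranges tile the area without overlap.
#'
#' @param study_area_km2 Study-area size in km^2.
#' @param home_range_km2 Average individual home-range size in km^2.
#' @return Integer number of home-range equivalents (rounded to nearest).
#' @examples
#' home_range_equivalents(2200, 115)
#' @export
home_range_equivalents <- function(study_area_km2, home_range_km2) {
  stopifnot(study_area_km2 > 0, home_range_km2 > 0)
  round(study_area_km2 / home_range_km2)
}

#' Radius of a circle with a given area
#'
#' Converts a home-range area to the radius of the circle of equal area,
#' `sqrt(A / pi)`. Used to turn mean community home-range areas into spatial
#' dispersal thresholds.
#'
#' @param area_km2 Area in km^2.
#' @return Radius in km.
#' @examples
#' circular_radius(115) # ~6.05 km
#' @export
circular_radius <- function(area_km2) {
  stopifnot(all(area_km2 > 0))
  sqrt(area_km2 / pi)
}

# modal value of a vector; ties broken by `tiebreak` ("first" = value whose
# first occurrence is earliest)
modal_value <- function(x, tiebreak = c("first")) {
  tiebreak <- match.arg(tiebreak)
  if (length(x) == 0L) return(x[NA_integer_])
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) {
    out <- top
  } else {
    # earliest-seen among tied values
    out <- as.character(x[x %in% type_like(top, x)][1L])
  }
  type_like(out, x)
}

# coerce character back to the type of template vector
type_like <- function(chr, template) {
  if (is.numeric(template)) as.numeric(chr) else chr
}

# deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 214748307L
}
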