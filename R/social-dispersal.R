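#' Identifiers of adult females in a detection table
#'
#' Adults are defined by field age class at first sighting (`"adult"`), or
#' by an estimated age of at least `min_age_months` at first sighting when
#' an `age_months` column is present.
#'
#' @param detections Detection tibble with `id`, `sex`, `age_class` and
#'   optionally `age_months`.
#' @param min_age_months Adult age threshold in months.
#' @return Character vector of adult-female ids.
#' @export
adult_females <- function(detections, min_age_months = 48) {
  d <- as_tibble(detections) |>
    arrange(.data$occasion) |>
    group_by(.data$id) |>
    slice(1L) |>
    ungroup()
  is_adult <- d$age_class == "adult"
  if ("age_months" %in% names(d)) {
    is_adult <- is_adult | (!is.na(d$age_months) & d$age_months >= min_age_months)
  }
  d$id[d$sex == "F" & is_adult]
}

#' Identifiers of calves (first sighted as calves)
#'
#' @param detections Detection tibble with `id`, `age_class`, `occasion`.
#' @return Character vector of ids first sighted in the calf age class.
#' @export
calf_ids <- function(detections) {
  d <- as_tibble(detections) |>
    arrange(.data$occasion) |>
    group_by(.data$id) |>
    slice(1L) |>
    ungroup()
  d$id[d$age_class == "calf"]
}

#' Assign one group observation to an adult-female community
#'
#' Majority vote over the community labels of the adult females present in
#' the group; a tie (or no adult females) gives `NA` (unassigned). With
#' `method = "unanimous"` the group is assigned only when every adult female
#' present belongs to the same community.
#'
#' @param communities Integer vector: community label of each adult female
#'   in the group (may be empty).
#' @param method `"majority"` (default) or `"unanimous"`.
#' @return A list with `community` (integer or `NA`) and `support` (the
#'   fraction of adult females in the winning community, `NA` if
#'   unassigned).
#' @examples
#' assign_detection_community(c(2L, 2L, 2L))
#' assign_detection_community(c(1L, 1L, 2L, 2L)) # tie -> NA
#' @export
assign_detection_community <- function(communities,
                                       method = c("majority", "unanimous")) {
  method <- match.arg(method)
  communities <- communities[!is.na(communities)]
  if (length(communities) == 0L) {
    return(list(community = NA_integer_, support = NA_real_))
  }
  tab <- table(communities)
  if (method == "unanimous") {
    if (length(tab) > 1L) return(list(community = NA_integer_, support = NA_real_))
    return(list(community = as.integer(names(tab)), support = 1))
  }
  top <- tab[tab == max(tab)]
  if (length(top) > 1L) {
    return(list(community = NA_integer_, support = NA_real_))
  }
  list(community = as.integer(names(top)),
       support = unname(max(tab)) / length(communities))
}

#' Community assignment timeline for each calf
#'
#' Assigns every calf detection to an adult-female community via
#' [assign_detection_community()] applied to the adult females in the same
#' group, producing the per-calf chronological timeline used by
#' [natal_community()] and [classify_social()].
#'
#' @param detections Detection tibble with `id`, `occasion`, `group_id`,
#'   and `age_months` (see [add_estimated_ages()]).
#' @param partition A [detect_communities()] partition (or a tibble with
#'   `id`, `community`).
#' @param ids Calf ids to track; default [calf_ids()].
#' @param method Passed to [assign_detection_community()].
#' @return Tibble: `id`, `occasion`, `age_months`, `community` (`NA` =
#'   unassigned), `support`.
#' @export
community_timelines <- function(detections, partition, ids = NULL,
                                method = c("majority", "unanimous")) {
  method <- match.arg(method)
  d <- as_tibble(detections)
  stopifnot("age_months" %in% names(d))
  mem <- partition_membership(partition)
  ids <- ids %||% calf_ids(d)

  votes <- d |>
    dplyr::inner_join(mem, by = "id") |>
    group_by(.data$group_id) |>
    summarise(.assign = list(assign_detection_community(.data$community, method)),
              .groups = "drop") |>
    mutate(community = map_int(.data$.assign, function(a) as.integer(a$community)),
           support = map_dbl(.data$.assign, function(a) as.numeric(a$support))) |>
    select("group_id", "community", "support")

  d |>
    filter(.data$id %in% ids) |>
    left_join(votes, by = "group_id") |>
    arrange(.data$id, .data$occasion) |>
    select("id", "occasion", "age_months", "community", "support")
}

#' Natal community of each calf
#'
#' The modal assigned community among a calf's detections at or below the
#' weaning age; ties are broken in favour of the community of the earliest
#' detection. Calves with no assigned pre-weaning detection get `NA` and
#' cannot be classified socially.
#'
#' @param timelines Output of [community_timelines()].
#' @param weaning_age Maximum age (months) at which a calf is assumed to
#'   still travel with its mother.
#' @return Tibble: `id`, `natal_community`, `n_natal_obs`.
#' @export
natal_community <- function(timelines, weaning_age = 18) {
  timelines |>
    group_by(.data$id) |>
    summarise(
      natal_community = {
        early <- .data$community[.data$age_months <= weaning_age &
                                   !is.na(.data$community)]
        if (length(early) == 0L) NA_integer_ else as.integer(modal_value(early))
      },
      n_natal_obs = sum(.data$age_months <= weaning_age &
                          !is.na(.data$community)),
      .groups = "drop"
    )
}

#' Classify social dispersal from a community timeline
#'
#' Operationalizes the temporal rules for social dispersal: a calf that is
#' (a) always assigned to its natal community did not disperse socially;
#' (b) one that visited other communities but was later detected back in
#' the natal community did not disperse (the visits are counted as
#' exploratory); (c) one that switched to, and was subsequently always
#' associated with, non-natal communities is a social disperser provided
#' the switch happened after weaning. The social dispersal age is the age
#' at the first detection of the terminal non-natal run. A terminal
#' non-natal run consisting of a single detection cannot show "subsequently
#' always associated": such calves are flagged `single_terminal = TRUE`
#' but still counted as social dispersers in the headline classification.
#' Unassigned detections are ignored throughout; calves with fewer than two
#' assigned detections or no natal community are `undetermined`.
#'
#' @param timelines Output of [community_timelines()].
#' @param natal Optional tibble from [natal_community()]; computed if
#'   missing.
#' @param weaning_age Weaning cap in months (switches at or below it do not
#'   count as social dispersal).
#' @return Tibble: `id`, `natal_community`, `social_flag`,
#'   `social_age_months`, `destinations` (list of community labels),
#'   `n_exploratory_visits`, `single_terminal`, `undetermined`,
#'   `n_assigned`.
#' @export
classify_social <- function(timelines, natal = NULL, weaning_age = 18) {
  natal <- natal %||% natal_community(timelines, weaning_age)
  split(timelines, timelines$id) |>
    imap(function(tl, i) {
      tl <- tl |> arrange(.data$occasion) |> filter(!is.na(.data$community))
      nat <- natal$natal_community[natal$id == i]
      nat <- if (length(nat)) nat[1] else NA_integer_
      base <- tibble(
        id = i, natal_community = nat, social_flag = NA_integer_,
        social_age_months = NA_real_, destinations = list(integer(0)),
        n_exploratory_visits = NA_integer_, single_terminal = FALSE,
        undetermined = TRUE, n_assigned = nrow(tl)
      )
      if (nrow(tl) < 2L || is.na(nat)) return(base)
      is_natal <- tl$community == nat
      seg <- rle(is_natal)
      n_nonnatal_blocks <- sum(!seg$values)
      base$undetermined <- FALSE
      if (seg$values[length(seg$values)]) {
        # terminal run natal: rules (a)/(b)
        base$social_flag <- 0L
        base$n_exploratory_visits <- n_nonnatal_blocks
        return(base)
      }
      # terminal run non-natal
      L <- seg$lengths[length(seg$lengths)]
      switch_idx <- nrow(tl) - L + 1L
      switch_age <- tl$age_months[switch_idx]
      base$n_exploratory_visits <- n_nonnatal_blocks - 1L
      if (switch_age <= weaning_age) {
        # permanent shift cannot be attributed to the calf itself
        base$social_flag <- 0L
        return(base)
      }
      base$social_flag <- 1L
      base$social_age_months <- switch_age
      base$destinations <- list(unique(tl$community[switch_idx:nrow(tl)]))
      base$single_terminal <- L == 1L
      base
    }) |>
    list_rbind()
}

#' Age first seen in a bachelor herd
#'
#' A bachelor herd is a group with strictly more males than females among
#' individuals of known sex. Returns, per individual, the minimum age at a
#' detection in such a group (`NA` if never).
#'
#' @param detections Detection tibble with `id`, `group_id`, `sex`,
#'   `age_months`.
#' @param ids Individuals to report; default all.
#' @return Tibble: `id`, `first_bachelor_age_months`.
#' @export
bachelor_herd_ages <- function(detections, ids = NULL) {
  d <- as_tibble(detections)
  stopifnot(all(c("group_id", "sex", "age_months") %in% names(d)))
  ids <- ids %||% unique(d$id)
  herd <- d |>
    filter(.data$sex %in% c("F", "M")) |>
    group_by(.data$group_id) |>
    summarise(bachelor = sum(.data$sex == "M") > sum(.data$sex == "F"),
              .groups = "drop")
  d |>
    filter(.data$id %in% ids) |>
    left_join(herd, by = "group_id") |>
    group_by(.data$id) |>
    summarise(
      first_bachelor_age_months = if (any(.data$bachelor %in% TRUE)) {
        min(.data$age_months[.data$bachelor %in% TRUE])
      } else NA_real_,
      .groups = "drop"
    )
}

## accept either a community_partition object or a bare membership tibble
partition_membership <- function(partition) {
  if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    as_tibble(partition)[, c("id", "community")]
  }
}
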