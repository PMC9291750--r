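#' Tidy a dispersoc model fit
#'
#' Returns the coefficient table (one row per term, with `outcome` rows
#' for multinomial fits) in broom layout.
#'
#' @param x A `disp_fit`.
#' @param ... Unused.
#' @return A tibble of coefficients.
#' @export
tidy.disp_fit <- function(x, ...) {
  x$coefs
}

#' One-row model summary for a dispersoc fit
#'
#' @param x A `disp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `kind`, `n`, `k`, `loglik`, `aicc`, and
#'   fit-specific extras (`re_sd`, `adj_r_squared`, `separation`).
#' @export
glance.disp_fit <- function(x, ...) {
  tibble(
    kind = x$kind, n = x$n, k = x$k, loglik = x$loglik, aicc = x$aicc,
    re_sd = x$re_sd %||% NA_real_,
    adj_r_squared = x$adj_r_squared %||% NA_real_,
    separation = x$separation %||% FALSE
  )
}

#' Tidy a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return The membership tibble (`id`, `community`).
#' @export
tidy.community_partition <- function(x, ...) {
  x$membership
}

#' One-row summary of a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return Tibble with `n_individuals`, `n_communities`, `modularity`.
#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_individuals = nrow(x$membership),
         n_communities = x$n_communities,
         modularity = x$modularity)
}

#' Tidy a full dispersal analysis into its per-calf records
#'
#' @param x A `dispersal_analysis`.
#' @param ... Unused.
#' @return The `records` tibble.
#' @export
tidy.dispersal_analysis <- function(x, ...) {
  x$records
}

#' One-row summary of a dispersal analysis
#'
#' @param x A `dispersal_analysis`.
#' @param ... Unused.
#' @return Tibble with calf counts by class, community count and
#'   modularity.
#' @export
glance.dispersal_analysis <- function(x, ...) {
  tab <- table(x$records$dispersal_class)
  tibble(
    n_calves = nrow(x$records),
    n_none = as.integer(tab[["none"]]),
    n_social = as.integer(tab[["social"]]),
    n_spatial = as.integer(tab[["spatial"]]),
    n_both = as.integer(tab[["both"]]),
    n_undetermined = sum(is.na(x$records$dispersal_class)),
    n_communities = x$partition$n_communities,
    modularity = x$partition$modularity
  )
}
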