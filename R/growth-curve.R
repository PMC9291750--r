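#' Sex-specific saturating growth curve for photogrammetric ageing
#'
#' A von Bertalanffy height-at-age model,
#' \deqn{h(a) = H_\infty - (H_\infty - h_0)\, e^{-k a},}
#' with a shared birth height and sex-specific asymptotic heights. Measured
#' heights are converted to ages by inverting this curve
#' ([age_from_height()]). The defaults are self-consistent with the
#' synthetic-society simulator, which generates heights from the same curve.
#'
#' @param h0 Birth height, cm.
#' @param h_inf Named numeric of asymptotic heights by sex, cm
#'   (names `"F"`, `"M"`).
#' @param k Growth-rate constant per month.
#' @param adult_cap Age (months) at which ages are censored as adult.
#' @param eps Relative band below the asymptote within which heights are
#'   treated as adult (inversion is unstable there).
#' @return An object of class `growth_curve`.
#' @examples
#' gc <- growth_curve()
#' height_at_age(c(0, 12, 48), "F", gc)
#' @export
growth_curve <- function(h0 = 180,
                         h_inf = c(F = 430, M = 500),
                         k = 0.045,
                         adult_cap = 48,
                         eps = 0.02) {
  stopifnot(h0 > 0, all(h_inf > h0), k > 0, adult_cap > 0, eps > 0, eps < 1)
  if (!all(c("F", "M") %in% names(h_inf))) {
    abort("`h_inf` must be named with sexes \"F\" and \"M\".")
  }
  structure(
    list(h0 = h0, h_inf = h_inf, k = k, adult_cap = adult_cap, eps = eps),
    class = "growth_curve"
  )
}

#' Expected height at a given age
#'
#' @param age_months Ages in months.
#' @param sex Character vector of `"F"`/`"M"` (recycled).
#' @param curve A [growth_curve()].
#' @return Heights in cm.
#' @export
height_at_age <- function(age_months, sex, curve = growth_curve()) {
  stopifnot(inherits(curve, "growth_curve"), all(age_months >= 0))
  hi <- unname(curve$h_inf[as.character(sex)])
  hi - (hi - curve$h0) * exp(-curve$k * age_months)
}

#' Estimate age in months from a measured height
#'
#' Inverts the growth curve: `a = -log((H_inf - h) / (H_inf - h0)) / k`.
#' Heights in the asymptotic band (within `eps` of `H_inf`) cannot be aged
#' and are censored at the adult cap with `censored = TRUE`. Implausibly
#' small (< h0/2) or non-finite heights are rejected (`NA` with
#' `rejected = TRUE`).
#'
#' @param height_cm Measured heights, cm.
#' @param sex `"F"`/`"M"` per height (recycled).
#' @param curve A [growth_curve()].
#' @return A tibble with columns `height_cm`, `sex`, `age_months`,
#'   `censored`, `rejected`.
#' @examples
#' age_from_height(c(180, 300, 430), "F")
#' @export
age_from_height <- function(height_cm, sex, curve = growth_curve()) {
  stopifnot(inherits(curve, "growth_curve"))
  sex <- rep_len(as.character(sex), length(height_cm))
  hi <- unname(curve$h_inf[sex])
  rejected <- !is.finite(height_cm) | height_cm <= curve$h0 / 2
  # adult band: height at or above H_inf * (1 - eps) of the gap closed
  band <- hi - curve$eps * (hi - curve$h0)
  censored <- !rejected & height_cm >= band
  gap <- ifelse(is.finite(height_cm), hi - height_cm, NA_real_)
  age <- -log(pmax(gap, .Machine$double.eps) / (hi - curve$h0)) / curve$k
  age <- pmax(age, 0)
  age[censored] <- curve$adult_cap
  age[rejected] <- NA_real_
  tibble(
    height_cm = height_cm, sex = sex, age_months = age,
    censored = censored, rejected = rejected
  )
}

#' Assign a field age class from an age in months
#'
#' Calves are animals under 1 year, sub-adults 1-3 years, adults 4 years and
#' older (48 months and up).
#'
#' @param age_months Ages in months (>= 0).
#' @return Factor with levels `calf`, `subadult`, `adult`.
#' @examples
#' assign_age_class(c(11, 12, 47, 48))
#' @export
assign_age_class <- function(age_months) {
  stopifnot(all(age_months >= 0, na.rm = TRUE))
  cut(age_months,
    breaks = c(-Inf, 12, 48, Inf), right = FALSE,
    labels = c("calf", "subadult", "adult")
  )
}
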