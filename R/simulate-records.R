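#' Simulate per-calf dispersal records from known multinomial-logit
#' coefficients
#'
#' Draws sex, a community label, covariates, and a four-level dispersal
#' class from a multinomial logit with `none` as the reference. Used for
#' parameter-recovery validation of the statistical stage at arbitrary n
#' without simulating a full society; covariates are drawn independently
#' per record so that the fitted standard errors are calibrated against
#' the generator.
#'
#' @param n Number of records.
#' @param coefs Named list with elements `social`, `spatial`, `both`;
#'   each a named coefficient vector over any of `(Intercept)`, `sexM`,
#'   `forage`, `dist_town`, `dist_boma`, `density`.
#' @param n_communities Number of community labels to draw.
#' @param seed Integer seed.
#' @return Tibble: `id`, `sex`, `community`, the four covariates,
#'   `dispersal_class` (factor none/social/spatial/both).
#' @examples
#' simulate_dispersal_records(5, list(
#'   social = c(`(Intercept)` = -2.6, sexM = 2.0),
#'   spatial = c(`(Intercept)` = -3.1, dist_town = 0.11),
#'   both = c(`(Intercept)` = -3.0, sexM = 2.6, dist_town = 0.07)
#' ), seed = 1)
#' @export
simulate_dispersal_records <- function(n, coefs, n_communities = 12,
                                       seed = 1L) {
  stopifnot(all(c("social", "spatial", "both") %in% names(coefs)))
  set.seed(seed)
  d <- tibble(
    id = sprintf("R%05d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    community = sample.int(n_communities, n, replace = TRUE),
    forage = runif(n, 0.1, 0.6),
    dist_town = runif(n, 2, 30),
    dist_boma = runif(n, 0.5, 10),
    density = runif(n, 0.5, 2)
  )
  X <- cbind(
    `(Intercept)` = 1, sexM = as.numeric(d$sex == "M"),
    forage = d$forage, dist_town = d$dist_town,
    dist_boma = d$dist_boma, density = d$density
  )
  eta <- vapply(c("social", "spatial", "both"), function(f) {
    b <- coefs[[f]]
    as.vector(X[, names(b), drop = FALSE] %*% b)
  }, numeric(n))
  P <- cbind(none = 1, exp(eta))
  P <- P / rowSums(P)
  lv <- c("none", "social", "spatial", "both")
  d$dispersal_class <- factor(
    vapply(seq_len(n), function(i) sample(lv, 1L, prob = P[i, lv]),
           character(1)),
    levels = lv
  )
  d
}

#' Simulate binary dispersal outcomes with a community random effect
#'
#' Generates records `y ~ Bernoulli(plogis(b0 + b_sex * 1[M] + u_c))`
#' with community intercepts `u_c ~ N(0, re_sd^2)`. Used to validate the
#' mixed logistic fit (including its reduction to a plain logistic when
#' `re_sd = 0`).
#'
#' @param n Number of records.
#' @param beta0 Intercept (log-odds for females).
#' @param beta_sex Male log-odds ratio.
#' @param re_sd Among-community SD of the random intercept.
#' @param n_communities Number of communities.
#' @param seed Integer seed.
#' @return Tibble: `sex`, `community`, `y`.
#' @export
simulate_binary_records <- function(n, beta0 = -1, beta_sex = 1.85,
                                    re_sd = 0, n_communities = 12,
                                    seed = 1L) {
  set.seed(seed)
  comm <- sample.int(n_communities, n, replace = TRUE)
  u <- rnorm(n_communities, 0, re_sd)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  eta <- beta0 + beta_sex * (sex == "M") + u[comm]
  tibble(sex = sex, community = comm,
         y = rbinom(n, 1, stats::plogis(eta)))
}
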