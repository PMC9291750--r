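#' Inclusion filter for potential dispersers
#'
#' Selects calves usable for dispersal classification: individuals first
#' sighted as calves in the birth-year window, and detected at least once
#' in every rolling interval of `interval_years` consecutive calendar
#' years spanning the study (so that each has resight coverage for at
#' least five years after first sighting under the defaults).
#'
#' @param detections Detection tibble with `id`, `occasion`, `year`,
#'   `age_class`.
#' @param birth_years Calendar years in which first sighting as a calf
#'   qualifies (default 2012-2013).
#' @param interval_years Length of each rolling detection interval.
#' @return Character vector of qualifying calf ids (empty with a warning
#'   if none qualify).
#' @export
select_potential_dispersers <- function(detections,
                                        birth_years = c(2012, 2013),
                                        interval_years = 3) {
  d <- as_tibble(detections)
  stopifnot(all(c("id", "year", "age_class") %in% names(d)))
  firsts <- d |>
    arrange(.data$occasion) |>
    group_by(.data$id) |>
    slice(1L) |>
    ungroup()
  calves <- firsts$id[firsts$age_class == "calf" &
                        firsts$year %in% birth_years]
  yrs <- sort(unique(d$year))
  starts <- seq(min(yrs), max(yrs) - interval_years + 1L)
  keep <- vapply(calves, function(i) {
    iy <- unique(d$year[d$id == i])
    all(vapply(starts, function(s) {
      any(iy >= s & iy <= s + interval_years - 1L)
    }, logical(1)))
  }, logical(1))
  out <- calves[keep]
  if (length(out) == 0L) warn("No calves pass the potential-disperser filter.")
  out
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2 * logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Random-intercept logistic regression (community random effect)
#'
#' Fits a binomial GLMM with a random intercept by adaptive Gauss-Hermite
#' quadrature (lme4, fixed node count). When the fit shows signs of
#' complete separation (diverging coefficients or standard errors), a
#' Jeffreys-prior-penalized (Firth) fixed-effects logistic fit is
#' substituted and flagged.
#'
#' @param data Data frame with the response, predictors, and grouping
#'   column.
#' @param response Name of the binary (0/1) response column.
#' @param predictors Character vector of fixed-effect terms (may include
#'   interactions like `"sex:dist_town"`).
#' @param random Name of the grouping column for the random intercept.
#' @param nagq Number of adaptive quadrature nodes.
#' @return An object of class `disp_fit` (see [tidy()] / [glance()]).
#' @export
fit_logistic_random_intercept <- function(data, response, predictors,
                                          random = "community", nagq = 8) {
  data <- as.data.frame(data)
  y <- data[[response]]
  if (length(unique(na.omit(y))) < 2L) {
    abort(sprintf("Response `%s` has no variation.", response))
  }
  if (length(unique(data[[random]])) < 2L) {
    abort("Need at least 2 groups for a random intercept.")
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, random))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = data, family = binomial(), nAGQ = nagq)
  ))
  fe <- lme4::fixef(fit)
  se <- suppressWarnings(sqrt(diag(as.matrix(vcov(fit)))))
  separated <- any(abs(fe) > 15) || any(se > 50)
  if (separated) {
    firth <- firth_logistic(data, response, predictors)
    return(new_disp_fit(
      fit = fit, kind = "logistic_mixed", data = data,
      coefs = firth$coefs, loglik = firth$loglik,
      k = nrow(firth$coefs), n = nrow(data),
      re_sd = NA_real_, separation = TRUE, fallback = firth
    ))
  }
  ll <- as.numeric(logLik(fit))
  k <- length(fe) + 1L # + random-intercept variance
  z <- fe / se
  coefs <- tibble(
    term = names(fe), estimate = unname(fe), std_error = unname(se),
    statistic = unname(z), p_value = 2 * pnorm(-abs(unname(z))),
    conf_low = unname(fe - 1.96 * se), conf_high = unname(fe + 1.96 * se)
  )
  re_sd <- sqrt(unname(unlist(lme4::VarCorr(fit)[[random]])))[1]
  new_disp_fit(fit = fit, kind = "logistic_mixed", data = data,
               coefs = coefs, loglik = ll, k = k, n = nrow(data),
               re_sd = re_sd, separation = FALSE)
}

## Jeffreys-penalized (Firth) logistic regression by IRLS with
## hat-diagonal score adjustment; used as the separation fallback.
firth_logistic <- function(data, response, predictors, max_iter = 100,
                           tol = 1e-8) {
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  X <- stats::model.matrix(as.formula(paste("~", rhs)), data = data)
  y <- data[[response]]
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    XtWX <- crossprod(X, XW)
    h <- rowSums((X %*% solve(XtWX)) * XW) # hat-matrix diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- solve(XtWX, U)
    beta <- beta + as.vector(delta)
    if (max(abs(delta)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  V <- solve(crossprod(X, X * (mu * (1 - mu))))
  se <- sqrt(diag(V))
  z <- beta / se
  list(
    coefs = tibble(
      term = colnames(X), estimate = beta, std_error = se, statistic = z,
      p_value = 2 * pnorm(-abs(z)),
      conf_low = beta - 1.96 * se, conf_high = beta + 1.96 * se
    ),
    loglik = ll
  )
}

#' Multinomial logistic model for the four dispersal types
#'
#' Maximum-likelihood multinomial logit with `none` as the reference
#' level, fitted via nnet. Numeric covariates are standardized internally
#' for optimization stability and coefficients are reported on the
#' original scale. Relative risk ratios are the exponentiated
#' coefficients. Empty outcome categories are dropped with a
#' structural-zero warning.
#'
#' @param data Data frame containing the response and predictors.
#' @param response Name of the 4-level response column (factor or
#'   character with levels none/social/spatial/both, or any set of
#'   levels whose first is the reference).
#' @param predictors Character vector of predictor terms.
#' @param reference Reference level (default `"none"`).
#' @return An object of class `disp_fit` with per-outcome coefficient
#'   rows (column `outcome`) and `rrr = exp(estimate)`.
#' @export
fit_multinomial <- function(data, response, predictors, reference = "none") {
  data <- as.data.frame(data)
  y <- data[[response]]
  if (!is.factor(y)) y <- factor(y)
  if (!reference %in% levels(y)) abort("Reference level absent from response.")
  empty <- levels(y)[table(y) == 0L]
  if (length(empty)) {
    warn(sprintf("Empty outcome categories dropped (structural zeros): %s",
                 paste(empty, collapse = ", ")))
    y <- droplevels(y)
  }
  y <- stats::relevel(y, ref = reference)
  data$.y <- y

  num <- predictors[vapply(predictors, function(p) {
    p %in% names(data) && is.numeric(data[[p]])
  }, logical(1))]
  centers <- vapply(num, function(p) mean(data[[p]]), numeric(1))
  scales <- vapply(num, function(p) {
    s <- sd(data[[p]]); if (s == 0) 1 else s
  }, numeric(1))
  data_orig <- data
  for (p in num) data[[p]] <- (data[[p]] - centers[[p]]) / scales[[p]]

  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- as.formula(paste(".y ~", rhs))
  fit <- nnet::multinom(fml, data = data, trace = FALSE, maxit = 500,
                        Hess = TRUE)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(y)[2], names(cf)))

  # exact linear map from standardized- to original-scale coefficients:
  # X_std = X_orig C  =>  beta_orig = C beta_std, V_orig = A V A' with
  # A = I_outcomes (x) C (delta method, exact for a linear reparametrization)
  rhs_fml <- as.formula(paste("~", rhs))
  Xo <- stats::model.matrix(rhs_fml, data = data_orig)
  Xs <- stats::model.matrix(rhs_fml, data = data)
  C <- solve(crossprod(Xo), crossprod(Xo, Xs))
  cf_orig <- cf %*% t(C)
  dimnames(cf_orig) <- dimnames(cf)
  se <- tryCatch({
    V <- solve(fit$Hessian)
    A <- kronecker(diag(nrow(cf)), C)
    Vo <- A %*% V %*% t(A)
    matrix(sqrt(pmax(diag(Vo), 0)), nrow = nrow(cf), byrow = TRUE,
           dimnames = dimnames(cf))
  }, error = function(e) cf * NA)
  cf <- cf_orig

  coefs <- as_tibble(as.data.frame.table(cf, stringsAsFactors = FALSE)) |>
    rename(outcome = "Var1", term = "Var2", estimate = "Freq") |>
    left_join(
      as_tibble(as.data.frame.table(se, stringsAsFactors = FALSE)) |>
        rename(outcome = "Var1", term = "Var2", std_error = "Freq"),
      by = c("outcome", "term")
    ) |>
    mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pnorm(-abs(.data$statistic)),
      rrr = exp(.data$estimate)
    )
  ll <- -fit$value # nnet stores the negative log-likelihood in $value
  k <- length(cf)
  new_disp_fit(fit = fit, kind = "multinomial", data = data,
               coefs = coefs, loglik = ll, k = k, n = nrow(data),
               reference = reference,
               standardization = list(centers = centers, scales = scales))
}

#' Gaussian linear model for dispersal distance or age
#'
#' Ordinary least-squares fit packaged with the same `disp_fit` interface
#' (AICc bookkeeping counts the residual variance as a parameter).
#'
#' @inheritParams fit_multinomial
#' @param response Name of the numeric response column.
#' @return A `disp_fit`.
#' @export
fit_linear <- function(data, response, predictors) {
  data <- as.data.frame(data)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fit <- stats::lm(as.formula(paste(response, "~", rhs)), data = data)
  sm <- summary(fit)
  cf <- sm$coefficients
  coefs <- tibble(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4],
    conf_low = cf[, 1] - 1.96 * cf[, 2], conf_high = cf[, 1] + 1.96 * cf[, 2]
  )
  new_disp_fit(fit = fit, kind = "linear", data = data, coefs = coefs,
               loglik = as.numeric(logLik(fit)),
               k = length(coef(fit)) + 1L, n = nrow(data),
               adj_r_squared = sm$adj.r.squared)
}

new_disp_fit <- function(fit, kind, data, coefs, loglik, k, n, ...) {
  structure(
    c(list(fit = fit, kind = kind, data = data, coefs = coefs,
           loglik = loglik, k = k, n = n,
           aicc = aicc(loglik, k, n)), list(...)),
    class = "disp_fit"
  )
}

#' @export
print.disp_fit <- function(x, ...) {
  cat(sprintf("<disp_fit: %s> n = %d, k = %d, logLik = %.2f, AICc = %.2f\n",
              x$kind, x$n, x$k, x$loglik, x$aicc))
  print(x$coefs, n = 20)
  invisible(x)
}

#' Rank a candidate model set by AICc
#'
#' All models must be fitted to the same rows. Returns the set sorted by
#' AICc with differences and Akaike weights.
#'
#' @param fits Named list of `disp_fit` objects.
#' @return Tibble: `model`, `k`, `loglik`, `aicc`, `delta_aicc`,
#'   `weight`, sorted by AICc.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    abort("All models must be fitted to the same number of rows.")
  }
  nm <- names(fits) %||% paste0("model_", seq_along(fits))
  tab <- tibble(
    model = nm,
    k = unname(vapply(fits, function(f) f$k, numeric(1))),
    loglik = unname(vapply(fits, function(f) f$loglik, numeric(1))),
    aicc = unname(vapply(fits, function(f) f$aicc, numeric(1)))
  ) |>
    arrange(.data$aicc) |>
    mutate(
      delta_aicc = .data$aicc - min(.data$aicc),
      weight = exp(-0.5 * .data$delta_aicc) / sum(exp(-0.5 * .data$delta_aicc))
    )
  tab
}

#' Sex-specific predicted probabilities by observed-value averaging
#'
#' For each value of the focal covariate on a grid, that value is imposed
#' on every observation, the fitted multinomial predicts a probability for
#' each outcome per observation, and the probabilities are averaged within
#' sex. Probabilities sum to one at every grid point. Grid values outside
#' the observed covariate range trigger an extrapolation warning.
#'
#' @param fit A multinomial `disp_fit`.
#' @param focal Name of the focal (numeric) covariate.
#' @param grid Numeric grid for the focal covariate; defaults to 25 points
#'   over its observed range.
#' @param by Grouping column for the averages (default `"sex"`; `NULL`
#'   averages over everyone).
#' @return Tibble of class `predicted_probabilities`: `by`-columns,
#'   `focal` value, `outcome`, `probability`.
#' @export
predicted_probabilities <- function(fit, focal, grid = NULL, by = "sex") {
  stopifnot(inherits(fit, "disp_fit"), fit$kind == "multinomial")
  data <- fit$data
  std <- fit$standardization
  # fit$data holds standardized covariates; recover the original scale
  orig <- data[[focal]]
  if (focal %in% names(std$centers)) {
    orig <- orig * std$scales[[focal]] + std$centers[[focal]]
  }
  grid <- grid %||% seq(min(orig), max(orig), length.out = 25)
  if (any(grid < min(orig) - 1e-9 | grid > max(orig) + 1e-9)) {
    warn("Grid extends beyond the observed covariate range; extrapolating.")
  }
  out <- map(grid, function(v) {
    nd <- data
    vv <- v
    if (focal %in% names(std$centers)) {
      vv <- (v - std$centers[[focal]]) / std$scales[[focal]]
    }
    nd[[focal]] <- vv
    P <- predict(fit$fit, newdata = nd, type = "probs")
    if (is.null(dim(P))) P <- cbind(`1` = 1 - P, `2` = P) # 2-level fallback
    df <- as_tibble(P)
    if (!is.null(by)) df[[by]] <- nd[[by]]
    df$.focal <- v
    df
  }) |>
    list_rbind() |>
    tidyr::pivot_longer(
      cols = -dplyr::any_of(c(by, ".focal")),
      names_to = "outcome", values_to = "probability"
    ) |>
    group_by(across(dplyr::any_of(c(by, ".focal", "outcome")))) |>
    summarise(probability = mean(.data$probability), .groups = "drop") |>
    rename(!!focal := ".focal")
  class(out) <- c("predicted_probabilities", class(out))
  attr(out, "focal") <- focal
  attr(out, "by") <- by
  out
}

#' Two-sample comparison (Welch t or Wilcoxon rank-sum)
#'
#' Welch's unequal-variance t test with Satterthwaite degrees of freedom,
#' or the Wilcoxon rank-sum test with tie-corrected normal approximation
#' and continuity correction.
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @param method `"welch_t"` or `"wilcoxon"`.
#' @return Tibble: `method`, `statistic`, `df` (`NA` for Wilcoxon),
#'   `p_value`, `estimate` (difference in means, or `NA`).
#' @export
compare_groups <- function(x, y, method = c("welch_t", "wilcoxon")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) abort("Need >= 2 values per group.")
  if (sd(x) == 0 && sd(y) == 0 && method == "welch_t") {
    abort("Zero variance in both groups: the test statistic is degenerate.")
  }
  if (method == "welch_t") {
    tt <- t.test(x, y, var.equal = FALSE)
    tibble(method = method, statistic = unname(tt$statistic),
           df = unname(tt$parameter), p_value = tt$p.value,
           estimate = unname(diff(rev(tt$estimate))))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    tibble(method = method, statistic = unname(wt$statistic),
           df = NA_real_, p_value = wt$p.value, estimate = NA_real_)
  }
}

#' Summary of dispersal classes by sex
#'
#' Per sex and dispersal class: counts, within-sex proportions, mean final
#' and maximum distances; plus derived per-sex summaries (number and
#' proportion dispersing, and each class's share among dispersers).
#'
#' @param records Tibble with `sex`, `dispersal_class`, and optionally
#'   `final_km`, `max_km` (e.g. [combine_outcomes()] output, or plain
#'   counts expanded to rows).
#' @return A list of class `dispersal_summary` with tibbles `by_class`
#'   (sex x class) and `by_sex`.
#' @export
summarize_types <- function(records) {
  r <- as_tibble(records) |>
    filter(!is.na(.data$dispersal_class)) |>
    mutate(dispersal_class = factor(.data$dispersal_class,
                                    levels = c("none", "social", "spatial",
                                               "both")))
  if (!"final_km" %in% names(r)) r$final_km <- NA_real_
  if (!"max_km" %in% names(r)) r$max_km <- NA_real_
  by_class <- r |>
    group_by(.data$sex, .data$dispersal_class, .drop = FALSE) |>
    summarise(
      n = dplyr::n(),
      mean_final_km = mean(.data$final_km),
      mean_max_km = mean(.data$max_km),
      .groups = "drop"
    ) |>
    group_by(.data$sex) |>
    mutate(
      prop_within_sex = .data$n / pmax(sum(.data$n), 1L),
      n_dispersers = sum(.data$n[.data$dispersal_class != "none"]),
      share_among_dispersers = dplyr::case_when(
        .data$dispersal_class == "none" ~ NA_real_,
        .data$n_dispersers == 0 ~ 0,
        TRUE ~ .data$n / .data$n_dispersers
      )
    ) |>
    ungroup()
  by_sex <- by_class |>
    group_by(.data$sex) |>
    summarise(
      n_total = sum(.data$n),
      n_dispersed = .data$n_dispersers[1],
      prop_dispersed = if_else(.data$n_total > 0,
                               .data$n_dispersed / .data$n_total, 0),
      .groups = "drop"
    )
  structure(list(by_class = by_class, by_sex = by_sex),
            class = "dispersal_summary")
}

#' @export
print.dispersal_summary <- function(x, ...) {
  cat("<dispersal_summary>\n")
  print(x$by_class)
  print(x$by_sex)
  invisible(x)
}

#' Expand class counts into one-row-per-individual records
#'
#' Convenience for feeding printed summary counts (e.g. a published
#' contingency table) into [summarize_types()] or the model stage.
#'
#' @param counts Tibble with `sex`, `dispersal_class`, `n` and optional
#'   extra columns carried through.
#' @return Tibble with one row per individual.
#' @export
expand_class_counts <- function(counts) {
  counts <- as_tibble(counts)
  counts[rep(seq_len(nrow(counts)), counts$n), setdiff(names(counts), "n")]
}

#' Build the a-priori candidate model specifications
#'
#' Reconstructs a 20-model candidate set over sex and the four community
#' covariates: a null model, each term alone, sex plus each covariate,
#' sex-interaction models, and additive pairs of covariates whose
#' correlation does not exceed `max_cor` in the supplied data (highly
#' correlated covariates never co-occur).
#'
#' @param data Data frame holding the covariates (used for the correlation
#'   screen).
#' @param covariates Covariate names.
#' @param max_cor Maximum absolute pairwise correlation allowed within one
#'   model.
#' @return Named list of character vectors of predictor terms (the null
#'   model is `character(0)`).
#' @export
candidate_models <- function(data,
                             covariates = c("forage", "dist_town",
                                            "dist_boma", "density"),
                             max_cor = 0.5) {
  specs <- list(null = character(0), sex = "sex")
  for (cv in covariates) {
    specs[[cv]] <- cv
    specs[[paste0("sex_", cv)]] <- c("sex", cv)
  }
  specs[["sex_x_dist_town"]] <- c("sex", "dist_town", "sex:dist_town")
  specs[["sex_x_density"]] <- c("sex", "density", "sex:density")
  cm <- stats::cor(as.data.frame(data)[, covariates])
  pairs <- utils::combn(covariates, 2, simplify = FALSE)
  for (pr in pairs) {
    if (abs(cm[pr[1], pr[2]]) <= max_cor) {
      specs[[paste(pr, collapse = "_")]] <- pr
      specs[[paste0("sex_", paste(pr, collapse = "_"))]] <- c("sex", pr)
    }
    if (length(specs) >= 20L) break
  }
  specs[seq_len(min(length(specs), 20L))]
}
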