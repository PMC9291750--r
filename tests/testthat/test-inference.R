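test_that("the potential-disperser filter enforces every rolling interval", {
  mkdet <- function(id, years) {
    tibble::tibble(
      id = id, occasion = (years - 2012L) * 6L + 1L, year = years,
      age_class = c("calf", rep("subadult", length(years) - 1L))
    )
  }
  det <- dplyr::bind_rows(
    mkdet("every_year", 2012:2018),
    mkdet("gap_15_17", c(2012, 2013, 2014, 2018)), # misses 2015-2017
    mkdet("late_born", c(2014, 2015, 2016, 2017, 2018)),
    mkdet("sparse_ok", c(2012, 2014, 2015, 2017, 2018))
  )
  sel <- select_potential_dispersers(det)
  expect_true("every_year" %in% sel)
  expect_true("sparse_ok" %in% sel)
  expect_false("gap_15_17" %in% sel) # absent from the 2015-2017 window
  expect_false("late_born" %in% sel) # not a calf in the birth-year window
})

test_that("the filter matches a brute-force interval check on simulated calendars", {
  soc <- small_society()
  det <- soc$detections
  sel <- select_potential_dispersers(det)
  # independent re-implementation: explicit loops over ids and windows
  firsts <- det[order(det$occasion), ]
  firsts <- firsts[!duplicated(firsts$id), ]
  calves <- firsts$id[firsts$age_class == "calf" & firsts$year %in% 2012:2013]
  brute <- character(0)
  for (i in calves) {
    yrs <- unique(det$year[det$id == i])
    ok <- TRUE
    for (s in 2012:2016) {
      if (!any(yrs %in% s:(s + 2))) ok <- FALSE
    }
    if (ok) brute <- c(brute, i)
  }
  expect_setequal(sel, brute)
  expect_gt(length(sel), 0)
})

test_that("AICc applies the closed-form small-sample correction", {
  # k = 3, n = 137: correction term 2k(k+1)/(n-k-1) = 24/133
  expect_equal(aicc(-10, 3, 137) - (20 + 6), 24 / 133, tolerance = 1e-12)
  expect_equal(round(aicc(0, 3, 137) - aicc(0, 3, 1e9), 3), 0.180)
  expect_equal(aicc(0, 5, 6), Inf) # undefined when n <= k + 1
})

test_that("model ranking weights behave like Akaike weights", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  d <- data.frame(y = 2 * x + rnorm(n), x = x, z = rnorm(n))
  f_true <- fit_linear(d, "y", "x")
  f_null <- fit_linear(d, "y", character(0))
  f_noise <- fit_linear(d, "y", "z")
  tab <- rank_models(list(true = f_true, null = f_null, noise = f_noise))
  expect_equal(tab$model[1], "true")
  expect_gt(tab$weight[1], 0.9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  # identical models share the weight equally
  tab2 <- rank_models(list(a = f_true, b = f_true))
  expect_equal(tab2$weight, c(0.5, 0.5))
  expect_error(rank_models(list(a = f_true,
                                b = fit_linear(d[1:100, ], "y", "x"))),
               "same number of rows")
})

test_that("two-sample comparisons match their reference behaviour", {
  x <- c(1.5, 2.5, 3.5, 4.5)
  expect_equal(compare_groups(x, x, "welch_t")$statistic, 0)
  set.seed(2)
  a <- rnorm(200)
  expect_lt(compare_groups(a, a + 1, "welch_t")$p_value, 1e-3)
  expect_error(compare_groups(rep(1, 5), rep(1, 5), "welch_t"), "Zero variance")

  # tie-corrected normal approximation vs exhaustive permutation
  px <- c(1.25, 1.68, 2.95, 3.28, 3.85, 5.78, 6.02, 6.04, 6.31, 8.08)
  py <- c(3.11, 4.80, 7.05, 7.12, 7.34, 7.57, 9.04, 10.30, 10.68, 10.97)
  pooled <- c(px, py)
  r <- rank(pooled)
  n <- length(px)
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  EW <- n * length(py) / 2
  W_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  p_perm <- mean(abs(stats - EW) >= abs(W_obs - EW))
  res <- compare_groups(px, py, "wilcoxon")
  expect_lt(abs(res$p_value - p_perm), 0.01)
})

test_that("the mixed logistic reduces to a plain logistic without group variance", {
  d <- simulate_binary_records(600, beta0 = -1, beta_sex = 1.5, re_sd = 0,
                               seed = 14)
  fit_mix <- fit_logistic_random_intercept(d, "y", "sex")
  fit_glm <- glm(y ~ sex, data = d, family = binomial())
  b_mix <- tidy(fit_mix)$estimate[tidy(fit_mix)$term == "sexM"]
  se_mix <- tidy(fit_mix)$std_error[tidy(fit_mix)$term == "sexM"]
  expect_lt(abs(b_mix - coef(fit_glm)[["sexM"]]), 2 * se_mix)
  expect_lt(glance(fit_mix)$re_sd, 0.25)
  expect_error(fit_logistic_random_intercept(
    within(d, y <- 0L), "y", "sex"), "no variation")
})

test_that("the mixed logistic recovers a planted sex effect", {
  d <- simulate_binary_records(500, beta0 = -1, beta_sex = 1.85, re_sd = 0.3,
                               seed = 15)
  fit <- fit_logistic_random_intercept(d, "y", "sex")
  co <- tidy(fit)
  b <- co$estimate[co$term == "sexM"]
  se <- co$std_error[co$term == "sexM"]
  expect_lt(abs(b - 1.85), 2 * se)
})

test_that("complete separation triggers the penalized fallback", {
  d <- data.frame(
    y = rep(c(0L, 1L), each = 20),
    sex = rep(c("F", "M"), each = 20),
    community = rep(1:4, 10)
  )
  fit <- fit_logistic_random_intercept(d, "y", "sex")
  expect_true(glance(fit)$separation)
  expect_true(all(is.finite(tidy(fit)$estimate)))
  expect_lt(abs(tidy(fit)$estimate[2]), 10) # penalization keeps it finite
})

test_that("a two-category multinomial coincides with plain logistic", {
  set.seed(33)
  n <- 400
  d <- data.frame(sex = sample(c("F", "M"), n, TRUE))
  d$cls <- ifelse(runif(n) < plogis(-1 + 1.2 * (d$sex == "M")),
                  "social", "none")
  suppressWarnings(fit_m <- fit_multinomial(d, "cls", "sex"))
  fit_g <- glm(I(cls == "social") ~ sex, data = d, family = binomial())
  co <- tidy(fit_m)
  expect_equal(co$estimate[co$term == "sexM"],
               coef(fit_g)[["sexM"]], tolerance = 1e-3)
  expect_equal(co$estimate[co$term == "(Intercept)"],
               coef(fit_g)[["(Intercept)"]], tolerance = 1e-3)
})

test_that("multinomial coefficients are recovered within 2 SE at n = 2000", {
  coefs <- list(
    social = c(`(Intercept)` = -2.62, sexM = 2.01, dist_town = 0.01),
    spatial = c(`(Intercept)` = -3.06, sexM = 0.74, dist_town = 0.11),
    both = c(`(Intercept)` = -3.01, sexM = 2.56, dist_town = 0.07)
  )
  # calibration over replicates: each run yields 9 coefficient checks
  # whose 2-SE coverage should sit near the nominal 95%
  zs <- unlist(lapply(1:8, function(s) {
    d <- simulate_dispersal_records(2000, coefs, seed = 100 + s)
    fit <- fit_multinomial(d, "dispersal_class", c("sex", "dist_town"))
    co <- tidy(fit)
    vapply(names(coefs), function(oc) {
      vapply(names(coefs[[oc]]), function(tm) {
        row <- co[co$outcome == oc & co$term == tm, ]
        (row$estimate - coefs[[oc]][[tm]]) / row$std_error
      }, numeric(1))
    }, numeric(3))
  }))
  expect_gte(mean(abs(zs) < 2), 0.88)
  expect_lt(abs(median(zs)), 0.5) # no systematic bias
  # relative risk ratios are the exponentiated coefficients
  d <- simulate_dispersal_records(2000, coefs, seed = 7)
  co <- tidy(fit_multinomial(d, "dispersal_class", c("sex", "dist_town")))
  expect_equal(co$rrr, exp(co$estimate))
  # empty category handling
  d2 <- d[d$dispersal_class != "both", ]
  d2$dispersal_class <- factor(d2$dispersal_class,
                               levels = c("none", "social", "spatial", "both"))
  expect_warning(fit2 <- fit_multinomial(d2, "dispersal_class", "sex"),
                 "structural zeros")
  expect_false("both" %in% tidy(fit2)$outcome)
})

test_that("AICc ranks the generating multinomial model first under strong signal", {
  coefs <- list(
    social = c(`(Intercept)` = -2.0, sexM = 2.0),
    spatial = c(`(Intercept)` = -3.0, dist_town = 0.12),
    both = c(`(Intercept)` = -3.0, sexM = 2.2, dist_town = 0.10)
  )
  d <- simulate_dispersal_records(800, coefs, seed = 8)
  fits <- list(
    null = fit_multinomial(d, "dispersal_class", character(0)),
    forage = fit_multinomial(d, "dispersal_class", "forage"),
    sex_dist_town = fit_multinomial(d, "dispersal_class",
                                    c("sex", "dist_town"))
  )
  tab <- rank_models(fits)
  expect_equal(tab$model[1], "sex_dist_town")
  expect_gt(tab$weight[1], 0.9)
})

test_that("predicted probabilities average over observed covariates", {
  coefs <- list(
    social = c(`(Intercept)` = -2.0, sexM = 2.0),
    spatial = c(`(Intercept)` = -3.5, dist_town = 0.15),
    both = c(`(Intercept)` = -3.5, sexM = 2.0, dist_town = 0.12)
  )
  d <- simulate_dispersal_records(1200, coefs, seed = 9)
  fit <- fit_multinomial(d, "dispersal_class", c("sex", "dist_town"))
  pp <- predicted_probabilities(fit, "dist_town")
  sums <- pp |>
    dplyr::group_by(sex, dist_town) |>
    dplyr::summarise(s = sum(probability), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-8))
  # a planted positive town-distance effect gives rising spatial curves
  sp <- pp[pp$outcome == "spatial" & pp$sex == "F", ]
  sp <- sp[order(sp$dist_town), ]
  expect_gt(sp$probability[nrow(sp)], sp$probability[1])
  expect_true(all(diff(sp$probability) > -1e-6))

  # the null model yields flat curves at the category frequencies
  fit0 <- fit_multinomial(d, "dispersal_class", character(0))
  # add the covariate back for the grid (constant prediction regardless)
  fit0$data$dist_town <- d$dist_town
  fit0$data$sex <- d$sex
  pp0 <- predicted_probabilities(fit0, "dist_town")
  freqs <- prop.table(table(d$dispersal_class))
  for (oc in names(freqs)) {
    vals <- pp0$probability[pp0$outcome == oc]
    expect_equal(vals, rep(freqs[[oc]], length(vals)), tolerance = 1e-3)
  }
})

test_that("class summaries reproduce count-table arithmetic", {
  counts <- tibble::tibble(
    sex = rep(c("F", "M"), each = 4),
    dispersal_class = rep(c("none", "social", "spatial", "both"), 2),
    n = c(52, 4, 9, 5, 21, 12, 8, 26)
  )
  sm <- summarize_types(expand_class_counts(counts))
  bs <- sm$by_sex
  expect_equal(bs$n_dispersed[bs$sex == "M"], 46)
  expect_equal(round(100 * bs$prop_dispersed[bs$sex == "M"]), 69)
  expect_equal(round(100 * bs$prop_dispersed[bs$sex == "F"]), 26)
  bc <- sm$by_class
  f_soc <- bc[bc$sex == "F" & bc$dispersal_class == "social", ]
  expect_equal(round(100 * f_soc$share_among_dispersers), 22)
  # an empty class keeps a zero row
  few <- tibble::tibble(sex = "F", dispersal_class = c("none", "social"),
                        n = c(3, 1))
  sm2 <- summarize_types(expand_class_counts(few))
  spat <- sm2$by_class[sm2$by_class$sex == "F" &
                         sm2$by_class$dispersal_class == "spatial", ]
  expect_equal(spat$n, 0L)
  expect_equal(spat$prop_within_sex, 0)
})

test_that("the candidate set respects the correlation screen", {
  set.seed(10)
  n <- 100
  d <- data.frame(forage = rnorm(n), dist_boma = rnorm(n),
                  density = rnorm(n))
  d$dist_town <- d$forage * 2 + rnorm(n, sd = 0.1) # strongly correlated
  specs <- candidate_models(d)
  expect_lte(length(specs), 20L)
  expect_true("null" %in% names(specs))
  has_both <- vapply(specs, function(s) {
    all(c("forage", "dist_town") %in% s)
  }, logical(1))
  expect_false(any(has_both))
})

test_that("planted town-distance effects are recovered with the right sign", {
  coefs <- list(
    social = c(`(Intercept)` = -2.6, sexM = 2.0),
    spatial = c(`(Intercept)` = -3.1, dist_town = 0.11),
    both = c(`(Intercept)` = -3.0, sexM = 2.6, dist_town = 0.07)
  )
  signs <- vapply(1:50, function(r) {
    d <- simulate_dispersal_records(400, coefs, seed = 1000 + r)
    fit <- tryCatch(
      fit_multinomial(d, "dispersal_class", c("sex", "dist_town")),
      warning = function(w) suppressWarnings(
        fit_multinomial(d, "dispersal_class", c("sex", "dist_town"))
      )
    )
    co <- tidy(fit)
    all(co$estimate[co$term == "dist_town" &
                      co$outcome %in% c("spatial", "both")] > 0)
  }, logical(1))
  expect_gte(mean(signs), 0.9)
})
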