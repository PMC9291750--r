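timeline <- function(communities, ages = NULL) {
  n <- length(communities)
  tibble::tibble(
    id = "calf1",
    occasion = seq_len(n),
    age_months = ages %||% seq(2, by = 4, length.out = n),
    community = as.integer(communities),
    support = ifelse(is.na(communities), NA_real_, 1)
  )
}

test_that("group community assignment is a majority vote with tie -> unassigned", {
  expect_equal(assign_detection_community(c(2L, 2L, 2L))$community, 2L)
  expect_equal(assign_detection_community(c(1L, 1L, 2L))$support, 2 / 3)
  expect_true(is.na(assign_detection_community(c(1L, 1L, 2L, 2L))$community))
  expect_true(is.na(assign_detection_community(integer(0))$community))
  # unanimous rule only assigns single-community groups
  expect_true(is.na(assign_detection_community(c(1L, 1L, 2L),
                                               method = "unanimous")$community))
  expect_equal(assign_detection_community(c(3L, 3L),
                                          method = "unanimous")$community, 3L)
})

test_that("natal community is the pre-weaning mode with earliest-tie-break", {
  tl <- timeline(c(5L, 5L, 5L, 7L), ages = c(3, 6, 9, 30))
  expect_equal(natal_community(tl)$natal_community, 5L)
  tl2 <- timeline(c(3L, 3L, 7L), ages = c(3, 9, 15))
  expect_equal(natal_community(tl2)$natal_community, 3L)
  tl3 <- timeline(c(7L, 3L, 3L, 7L, 3L), ages = c(2, 5, 8, 11, 14))
  expect_equal(natal_community(tl3)$natal_community, 3L) # mode beats earliest
  tl4 <- timeline(c(7L, 3L), ages = c(2, 6))
  expect_equal(natal_community(tl4)$natal_community, 7L) # tie -> earliest
  # no assigned pre-weaning detection -> unusable
  tl5 <- timeline(c(NA, 4L, 4L), ages = c(6, 30, 36))
  expect_true(is.na(natal_community(tl5)$natal_community))
})

test_that("the three temporal rules classify hand-traced timelines", {
  # (a) always natal
  out_a <- classify_social(timeline(c(1L, 1L, 1L, 1L)))
  expect_equal(out_a$social_flag, 0L)
  expect_equal(out_a$n_exploratory_visits, 0L)

  # (b) away and back: exploratory visit, no dispersal
  out_b <- classify_social(timeline(c(1L, 1L, 2L, 2L, 1L, 1L)))
  expect_equal(out_b$social_flag, 0L)
  expect_equal(out_b$n_exploratory_visits, 1L)

  # (c) permanent switch after weaning at age 45
  out_c <- classify_social(
    timeline(c(1L, 1L, 1L, 2L, 2L, 2L), ages = c(5, 15, 30, 45, 50, 55))
  )
  expect_equal(out_c$social_flag, 1L)
  expect_equal(out_c$social_age_months, 45)
  expect_equal(out_c$destinations[[1]], 2L)
  expect_false(out_c$single_terminal)
})

test_that("edge timelines are flagged instead of force-classified", {
  # single terminal non-natal detection: counted social but flagged
  out <- classify_social(
    timeline(c(1L, 1L, 1L, 2L), ages = c(5, 20, 35, 50))
  )
  expect_equal(out$social_flag, 1L)
  expect_true(out$single_terminal)

  # switch before weaning does not count as the calf's own dispersal
  out2 <- classify_social(
    timeline(c(1L, 2L, 2L, 2L), ages = c(3, 10, 14, 17))
  )
  expect_equal(out2$social_flag, 0L)

  # fewer than two assigned detections -> undetermined
  out3 <- classify_social(timeline(c(1L, NA, NA), ages = c(3, 10, 20)))
  expect_true(out3$undetermined)
})

test_that("unassigned detections never change the classification", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    comms <- sample(c(1L, 1L, 1L, 2L, 3L), n, replace = TRUE)
    ages <- sort(runif(n, 2, 70))
    base <- classify_social(timeline(comms, ages))
    # splice unassigned detections at random ages
    k <- sample(1:4, 1)
    ext_ages <- c(ages, runif(k, 2, 70))
    ext_comms <- c(comms, rep(NA_integer_, k))
    o <- order(ext_ages)
    with_na <- classify_social(timeline(ext_comms[o], ext_ages[o]))
    expect_equal(with_na$social_flag, base$social_flag)
    expect_equal(with_na$n_exploratory_visits, base$n_exploratory_visits)
  }
})

test_that("bachelor herds require a strict male majority", {
  det <- manual_detections(list(
    list(occasion = 1L, ids = c("m1", "m2", "m3", "f1"),
         sexes = c("M", "M", "M", "F"), ages = c(30, 40, 50, 60)),
    list(occasion = 2L, ids = c("m1", "m4", "f1", "f2"),
         sexes = c("M", "M", "F", "F"), ages = c(34, 34, 64, 64)),
    list(occasion = 3L, ids = "f3", sexes = "F", ages = 20)
  ))
  out <- bachelor_herd_ages(det)
  expect_equal(out$first_bachelor_age_months[out$id == "m1"], 30)
  expect_equal(out$first_bachelor_age_months[out$id == "f1"], 60)
  # 2M/2F is not a bachelor herd; f3 never in one
  expect_true(is.na(out$first_bachelor_age_months[out$id == "m4"]))
  expect_true(is.na(out$first_bachelor_age_months[out$id == "f3"]))
})

test_that("natal communities recover the planted birth communities", {
  soc <- small_society()
  an <- cached_analysis_small()
  truth <- soc$truth
  nat <- an$natal
  # community labels must correspond: map detected labels to true ones
  part <- an$partition$membership
  map <- tapply(soc$adults$community[match(part$id, soc$adults$id)],
                part$community, function(x) as.integer(names(which.max(table(x)))))
  nat$natal_true_label <- map[as.character(nat$natal_community)]
  cmp <- merge(nat, truth[, c("id", "birth_community")], by = "id")
  expect_gte(mean(cmp$natal_true_label == cmp$birth_community, na.rm = TRUE),
             0.95)
})

test_that("spatial-only fates are never socially classified without mixing", {
  cfg <- sim_config(
    n_communities = 4, members_per_community = c(12, 14), n_calves = 25,
    group_mixing = 0,
    fate_probs = list(F = c(none = 0.5, social = 0, spatial = 0.5, both = 0),
                      M = c(none = 0.5, social = 0, spatial = 0.5, both = 0)),
    seed = 13
  )
  soc <- cached_society("spatialonly", cfg)
  an <- run_dispersal_analysis(soc$detections, seed = 1)
  m <- merge(an$records, soc$truth, by = "id")
  sp <- m[m$fate == "spatial", ]
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$social_flag == 0L, na.rm = TRUE))
})
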