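test_that("coordinate projection is planar-identity and geodesic-accurate", {
  d <- tibble::tibble(id = "a", x_km = c(0, 3), y_km = c(0, 4))
  expect_identical(project_coordinates(d), d)

  # two points 0.01 deg of longitude apart at 4S: geodesic distance 1.1105 km
  g <- tibble::tibble(id = "a", lon = c(36.00, 36.01), lat = c(-4, -4))
  p <- project_coordinates(g)
  d_proj <- sqrt(diff(p$x_km)^2 + diff(p$y_km)^2)
  # spherical projection vs WGS84 geodesic: agreement to ~1 m
  expect_equal(d_proj, 1.110501, tolerance = 2e-3)
  expect_equal(round(d_proj, 2), 1.11)

  # the same point twice projects to zero separation
  same <- project_coordinates(tibble::tibble(id = "a", lon = c(36, 36),
                                             lat = c(-4, -4)))
  expect_equal(sqrt(diff(same$x_km)^2 + diff(same$y_km)^2), 0)

  # incomplete coordinate sets are rejected
  expect_error(project_coordinates(tibble::tibble(id = "a", lon = 36,
                                                  lat = NA_real_)),
               "Mixed or incomplete")
})

test_that("projection round-trips below one metre at study scale", {
  set.seed(8)
  lon <- 36 + runif(100, -0.5, 0.5)
  lat <- -4 + runif(100, -0.5, 0.5)
  xy <- dispersoc:::tm_forward(lon, lat, 36, -4)
  back <- dispersoc:::tm_inverse(xy$x, xy$y, 36, -4)
  # 1e-5 degrees is about one metre
  expect_lt(max(abs(back$lon - lon)), 1e-8)
  expect_lt(max(abs(back$lat - lat)), 1e-8)
})

test_that("net displacement is measured from the first detection", {
  d <- tibble::tibble(
    id = "c1", occasion = 1:3, age_months = c(10, 20, 30),
    x_km = c(0, 3, 0), y_km = c(0, 4, 0),
    age_class = c("calf", "subadult", "subadult")
  )
  s <- displacement_series(d, ids = "c1")
  expect_equal(s$distance_km, c(0, 5, 0))
  # isometry invariance: rotate by 31 degrees and translate
  th <- 31 * pi / 180
  d2 <- d
  d2$x_km <- cos(th) * d$x_km - sin(th) * d$y_km + 100
  d2$y_km <- sin(th) * d$x_km + cos(th) * d$y_km - 50
  expect_equal(displacement_series(d2, ids = "c1")$distance_km,
               s$distance_km, tolerance = 1e-12)
  # singleton individuals are dropped with a message
  d3 <- dplyr::bind_rows(d, tibble::tibble(
    id = "c2", occasion = 1L, age_months = 5, x_km = 0, y_km = 0,
    age_class = "calf"
  ))
  expect_message(s3 <- displacement_series(d3, ids = c("c1", "c2")),
                 "fewer than 2")
  expect_false("c2" %in% s3$id)
})

test_that("the kernel isopleth area matches the bivariate-normal closed form", {
  set.seed(123)
  n <- 2000
  x <- rnorm(n, sd = 2)
  y <- rnorm(n, sd = 2)
  est <- kernel_isopleth_area(x, y)
  truth <- qchisq(0.95, 2) * pi * 4 # 5.991 * pi * sigma^2 = 75.30 km^2
  expect_lt(abs(est$area_km2 - truth) / truth, 0.07)
  # duplicating every point must not change the area
  est2 <- kernel_isopleth_area(c(x, x), c(y, y), bw = est$bandwidth)
  expect_equal(est2$area_km2, est$area_km2, tolerance = 1e-6)
  # degenerate cloud is an explicit error
  expect_error(kernel_isopleth_area(rep(1, 20), rep(2, 20)), "degenerate")
})

test_that("sparse individuals are excluded from home-range estimation", {
  set.seed(5)
  d <- dplyr::bind_rows(
    tibble::tibble(id = "rich", occasion = 1:30,
                   x_km = rnorm(30, sd = 2), y_km = rnorm(30, sd = 2)),
    tibble::tibble(id = "sparse", occasion = 1:5,
                   x_km = rnorm(5), y_km = rnorm(5))
  )
  hr <- kernel_home_ranges(d, min_locs = 10)
  expect_true(hr$usable[hr$id == "rich"])
  expect_false(hr$usable[hr$id == "sparse"])
  expect_true(is.na(hr$area_km2[hr$id == "sparse"]))
})

test_that("threshold radii convert mean areas to circle radii", {
  hr <- tibble::tibble(id = c("a", "b", "c"),
                       area_km2 = c(115, 115, 115), usable = TRUE)
  mem <- tibble::tibble(id = c("a", "b", "c"), community = c(1L, 1L, 2L))
  thr <- threshold_radii(hr, mem)
  expect_equal(thr$threshold_km, rep(sqrt(115 / pi), 2), tolerance = 1e-12)
  expect_equal(round(thr$threshold_km[1], 2), 6.05)
  # a community with no usable member gets the global mean, with a warning
  hr2 <- hr
  hr2$usable[3] <- FALSE
  expect_warning(thr2 <- threshold_radii(hr2, mem), "no usable")
  expect_true(thr2$imputed[thr2$community == 2])
  expect_equal(thr2$threshold_km[thr2$community == 2], sqrt(115 / pi))
})

test_that("threshold radius estimates converge for circular-uniform truth", {
  set.seed(99)
  r_true <- 5
  n <- 4000
  u <- sqrt(runif(n)) * r_true
  a <- runif(n, 0, 2 * pi)
  est <- kernel_isopleth_area(u * cos(a), u * sin(a))
  # 95% isopleth of a uniform disk covers ~95% of the disk area
  r_est <- circular_radius(est$area_km2)
  expect_lt(abs(r_est - r_true * sqrt(0.95)) / r_true, 0.08)
})

test_that("smoothed-crossing confirmation separates dispersal from sorties", {
  mk <- function(dist, ages = NULL) {
    tibble::tibble(id = "c", occasion = seq_along(dist),
                   age_months = ages %||% seq(2, by = 4,
                                              length.out = length(dist)),
                   distance_km = dist)
  }
  # monotone crossing, everything beyond afterwards -> disperser
  out <- classify_spatial(mk(c(0, 1, 2, 4, 7, 9, 10, 11)), threshold = 6)
  expect_equal(out$spatial_flag, 1L)
  expect_equal(out$post_crossing_fraction, 1)
  expect_equal(out$spatial_age_months, out$crossing_age_months)

  # single mid-series exceedance with return -> sortie, not dispersal
  out2 <- classify_spatial(mk(c(0, 1, 8, 1, 2, 1)), threshold = 6)
  expect_equal(out2$spatial_flag, 0L)
  expect_equal(length(out2$sortie_ages[[1]]), 1L)

  # sawtooth: final beyond but only 2 of 6 post-crossing detections beyond
  age <- c(2, 6, 10, 14, 18, 22, 26, 30, 34, 38, 42, 46, 50, 54, 58, 62)
  dist <- c(0, 0.5, 1, 0.8, 1.2, 2, 3, 5, 7.5, 9, 4, 5, 9.5, 4.5, 5, 7.2)
  out3 <- classify_spatial(mk(dist, age), threshold = 6)
  expect_equal(out3$spatial_flag, 0L)
  expect_equal(out3$crossing_age_months, 42)
  expect_equal(out3$post_crossing_fraction, 1 / 3, tolerance = 1e-9)
  expect_equal(out3$sortie_ages[[1]], age[dist > 6])

  # short series fall back to the final-distance rule, flagged
  out4 <- classify_spatial(mk(c(0, 8, 9)), threshold = 6)
  expect_equal(out4$spatial_flag, 1L)
  expect_true(out4$low_confidence)
})

test_that("sorties with the mother are excluded from first-sortie age", {
  s <- tibble::tibble(id = "c", occasion = 1:6,
                      age_months = c(2, 5, 12, 20, 28, 36),
                      distance_km = c(0, 8, 1, 9, 1, 2))
  out <- classify_spatial(s, threshold = 6)
  expect_equal(sort(out$sortie_ages[[1]]), c(5, 20))
  expect_equal(out$first_sortie_age_months, 20)
  out2 <- classify_spatial(s, threshold = 6, exclude_mother_sorties = FALSE)
  expect_equal(out2$first_sortie_age_months, 5)
})

test_that("raising the threshold never creates a disperser", {
  # checked over the realistic threshold range (around the home-range
  # radius); far below it the strict >1/2 post-crossing rule can interact
  # discontinuously with the crossing location
  an <- cached_analysis_small()
  for (thr in list(c(5, 6), c(6, 8), c(8, 10), c(5, 8))) {
    lo <- classify_spatial(an$series, thr[1])
    hi <- classify_spatial(an$series, thr[2])
    expect_false(any(lo$spatial_flag == 0L & hi$spatial_flag == 1L))
  }
})

test_that("the four-level classification is exhaustive and exclusive", {
  an <- cached_analysis_small()
  rec <- an$records
  det <- rec[!rec$undetermined, ]
  expect_false(any(is.na(det$dispersal_class)))
  expect_setequal(levels(det$dispersal_class),
                  c("none", "social", "spatial", "both"))
  # cross of the flags reproduces the class
  expect_equal(as.character(det$dispersal_class),
               dplyr::case_when(
                 det$social_flag == 1 & det$spatial_flag == 1 ~ "both",
                 det$social_flag == 1 ~ "social",
                 det$spatial_flag == 1 ~ "spatial",
                 TRUE ~ "none"
               ))
  # first sortie precedes spatial dispersal whenever both exist
  both_known <- det[!is.na(det$first_sortie_age_months) &
                      !is.na(det$spatial_age_months), ]
  if (nrow(both_known)) {
    expect_true(all(both_known$first_sortie_age_months <=
                      both_known$spatial_age_months))
  }
})
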