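test_that("cover, frequency and IVI follow the point-intercept formulas", {
  ds <- two_species_dataset()
  prof <- compute_profile(ds, "P1", "V1")
  sp <- prof$species[order(prof$species$species_code), ]
  expect_equal(sp$cover_pct, c(202, 101) / 1010 * 100)
  expect_equal(sp$frequency, c(10L, 5L))
  expect_equal(sp$rel_cover_pct, c(200 / 3, 100 / 3))
  expect_equal(sp$rel_freq_pct, c(200 / 3, 100 / 3))
  expect_equal(sp$ivi, c(400 / 3, 200 / 3))
  expect_equal(sum(prof$species$ivi), 200)

  rec <- species_records("P1", "V1", "SOLO", "Shrub", 101L, 10L)
  solo <- compute_profile(
    survey_dataset(rec, toy_visits("P1", "V1", "2012-05-01")), "P1", "V1")
  expect_equal(solo$species$cover_pct, 10)
  expect_equal(solo$species$ivi, 200)
})

test_that("a species layered at one point counts that point once", {
  rec <- species_records("P1", "V1", "SPA", "Shrub", 10L, 1L)
  rec <- dplyr::bind_rows(rec, rec[1, ])  # duplicate hit, second stratum
  ds <- survey_dataset(rec, toy_visits("P1", "V1", "2012-05-01"))
  prof <- compute_profile(ds, "P1", "V1")
  expect_equal(prof$species$pi_count, 10L)
})

test_that("ground-cover fractions partition the 1010 points", {
  rec <- dplyr::bind_rows(
    species_records("P1", "V1", "SPA", "Shrub", 101L, 1L),
    tibble::tibble(plot_id = "P1", visit_id = "V1", transect = 2L,
                   point = 0:100, hit_kind = "bare_soil",
                   species_code = "", growth_form = ""),
    tibble::tibble(plot_id = "P1", visit_id = "V1", transect = 3L,
                   point = 0:9, hit_kind = "non_vascular_other",
                   species_code = "", growth_form = ""))
  ds <- survey_dataset(rec, toy_visits("P1", "V1", "2012-05-01"))
  prof <- compute_profile(ds, "P1", "V1")
  expect_equal(prof$vegetated_pct, 101 / 1010 * 100)
  expect_equal(prof$non_vascular_pct, 10 / 1010 * 100)
  expect_equal(prof$vegetated_pct + prof$bare_pct + prof$non_vascular_pct, 100)
})

test_that("diversity indices match closed forms", {
  even4 <- manual_profile(c(a = 25, b = 25, c = 25, d = 25))
  d4 <- diversity_summary(even4, basis = "cover")
  expect_equal(d4$H, log(4))
  expect_equal(d4$D, 0.75)
  expect_equal(d4$E, 1)

  solo <- manual_profile(c(a = 100))
  d1 <- diversity_summary(solo, basis = "cover")
  expect_equal(d1$S, 1L)
  expect_equal(d1$H, 0)
  expect_equal(d1$D, 0)
  expect_true(is.na(d1$E))

  skew <- manual_profile(c(a = 50, b = 30, c = 20))
  d3 <- diversity_summary(skew, basis = "cover")
  expect_equal(d3$H, -sum(c(.5, .3, .2) * log(c(.5, .3, .2))))
  expect_equal(round(d3$H, 5), 1.02965)
  expect_equal(d3$D, 0.62)
})

test_that("Sorensen distance matches hand values and metric axioms", {
  p <- manual_profile(c(x = 60, y = 40))
  q <- manual_profile(c(x = 40, z = 60))
  expect_equal(sorensen_distance(p, q), 0.6)
  expect_equal(sorensen_distance(p, p), 0)
  expect_equal(sorensen_distance(q, p), sorensen_distance(p, q))
  disjoint <- manual_profile(c(u = 10, v = 90))
  expect_equal(sorensen_distance(p, disjoint), 1)
})

test_that("Simpson beta discounts richness differences", {
  same <- manual_profile(c(a = 1, b = 1, c = 1))
  expect_equal(simpson_beta(same, manual_profile(c(a = 9, b = 5, c = 2))), 0)
  nested <- manual_profile(c(a = 1, b = 1, c = 1, d = 1, e = 1))
  expect_equal(simpson_beta(same, nested), 0)
  p <- manual_profile(setNames(rep(1, 7), c("s1", "s2", "s3", "s4", "s5", "u1", "u2")))
  q <- manual_profile(setNames(rep(1, 8), c("s1", "s2", "s3", "s4", "s5", "v1", "v2", "v3")))
  expect_equal(simpson_beta(p, q), 2 / 7)
})

test_that("Simpson beta agrees with the independent community-matrix form", {
  for (seed in 1:10) {
    sets <- withr::with_seed(seed, {
      pool <- paste0("S", 1:20)
      list(a = sample(pool, sample(3:12, 1)), b = sample(pool, sample(3:12, 1)))
    })
    p <- manual_profile(setNames(rep(1, length(sets$a)), sets$a))
    q <- manual_profile(setNames(rep(1, length(sets$b)), sets$b))
    pool <- union(sets$a, sets$b)
    m <- rbind(as.integer(pool %in% sets$a), as.integer(pool %in% sets$b))
    expect_equal(simpson_beta(p, q), as.numeric(vegan::betadiver(m, "sim")))
  }
})

test_that("Whittaker beta and half-changes follow their definitions", {
  a <- manual_profile(setNames(rep(1, 5), paste0("S", 1:5)))
  expect_equal(whittaker_beta(list(a, a, a)), 1)
  b <- manual_profile(setNames(rep(1, 5), paste0("T", 1:5)))
  expect_equal(whittaker_beta(list(a, b)), 2)
  c4 <- manual_profile(setNames(rep(1, 4), c("S1", "S2", "X1", "X2")))
  c6 <- manual_profile(setNames(rep(1, 6), c("S1", "S2", "Y1", "Y2", "Y3", "Y4")))
  expect_equal(whittaker_beta(list(c4, c6)), 1.6)

  expect_equal(half_changes(1), 0)
  expect_equal(half_changes(0.5), 1)
  expect_equal(half_changes(0.25), 2)
  expect_true(is.na(half_changes(0)))
})

test_that("profiles are invariant to record order and IVI always sums to 200", {
  sim <- generate_dataset(small_sim_config(seed = 31, n_plots = 1L,
                                           visit_schedule = c(0, 4)))
  ds <- sim$dataset
  profs <- profile_all_visits(ds)
  for (p in profs) {
    expect_equal(sum(p$species$ivi), 200, tolerance = 1e-9)
    expect_equal(sum(p$species$rel_cover_pct), 100, tolerance = 1e-9)
    expect_equal(sum(p$species$rel_freq_pct), 100, tolerance = 1e-9)
    expect_equal(p$vegetated_pct + p$bare_pct + p$non_vascular_pct, 100)
  }
  shuffled <- withr::with_seed(5, survey_dataset(
    ds$records[sample(nrow(ds$records)), ], ds$visits))
  v <- ds$visits[1, ]
  expect_equal(compute_profile(shuffled, v$plot_id, v$visit_id),
               compute_profile(ds, v$plot_id, v$visit_id))
})
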