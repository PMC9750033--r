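test_that("raw growth-form labels merge into the eight groups", {
  expect_equal(merge_growth_form("Tree Mallee"), "Trees")
  expect_equal(merge_growth_form("Fern"), "Others")
  expect_equal(merge_growth_form("Hummock grass"), "HummockGrass")
  expect_equal(merge_growth_form("HUMMOCK GRASS"), "HummockGrass")
  expect_equal(merge_growth_form(c("Acacia Shrub", "Chenopod", "Sedge")),
               c("Shrubs", "Chenopods", "Sedges"))
  expect_error(merge_growth_form("Cactus"), "Cactus",
               class = "vegshift_mapping_error")
})

test_that("growth-form IVI follows the relative species + relative PI formula", {
  rec <- dplyr::bind_rows(
    species_records("P1", "V1", "TUS1", "Tussock grass", 20L, 2L),
    species_records("P1", "V1", "TUS2", "Tussock grass", 10L, 1L,
                    point_offset = 30L),
    species_records("P1", "V1", "SHR1", "Shrub", 70L, 7L, point_offset = 50L))
  ds <- survey_dataset(rec, toy_visits("P1", "V1", "2012-05-01"))
  gp <- growth_form_profile(ds, "P1", "V1")
  tus <- gp$forms[gp$forms$form == "TussockGrass", ]
  shr <- gp$forms[gp$forms$form == "Shrubs", ]
  expect_equal(tus$n_species, 2L)
  expect_equal(tus$pi_count, 30L)
  expect_equal(tus$gf_ivi, 2 / 3 * 100 + 30)
  expect_equal(shr$gf_ivi, 1 / 3 * 100 + 70)
  expect_equal(sum(gp$forms$gf_ivi), 200)

  solo <- survey_dataset(species_records("P1", "V1", "ONE", "Tree", 11L, 1L),
                         toy_visits("P1", "V1", "2012-05-01"))
  gp1 <- growth_form_profile(solo, "P1", "V1")
  expect_equal(gp1$forms$gf_ivi[gp1$forms$form == "Trees"], 200)

  sym <- survey_dataset(dplyr::bind_rows(
    species_records("P1", "V1", "T1", "Tree", 40L, 4L),
    species_records("P1", "V1", "S1", "Shrub", 40L, 4L, point_offset = 50L)),
    toy_visits("P1", "V1", "2012-05-01"))
  gps <- growth_form_profile(sym, "P1", "V1")
  expect_equal(gps$forms$gf_ivi[gps$forms$form %in% c("Trees", "Shrubs")],
               c(100, 100))
})

test_that("structure distance obeys metric axioms on growth-form spectra", {
  mk <- function(...) {
    rec <- dplyr::bind_rows(...)
    ds <- survey_dataset(rec, toy_visits("P1", unique(rec$visit_id),
                                         rep("2012-05-01", 1)))
    growth_form_profile(ds, "P1", unique(rec$visit_id))
  }
  a <- mk(species_records("P1", "V1", "T1", "Tree", 40L, 4L))
  b <- mk(species_records("P1", "V1", "S1", "Shrub", 40L, 4L))
  expect_equal(structure_distance(a, a), 0)
  expect_equal(structure_distance(a, b), 1)
  expect_equal(structure_distance(a, b), structure_distance(b, a))
})

test_that("component cover shifts classify against raw point counts", {
  v1 <- dplyr::bind_rows(
    species_records("P1", "V1", "T1", "Tree", 303L, 10L),
    species_records("P1", "V1", "G1", "Tussock grass", 101L, 5L,
                    point_offset = 60L))
  v2 <- dplyr::bind_rows(
    species_records("P1", "V2", "T1", "Tree", 253L, 10L),
    species_records("P1", "V2", "G1", "Tussock grass", 101L, 5L,
                    point_offset = 60L))
  ds <- survey_dataset(dplyr::bind_rows(v1, v2),
                       toy_visits("P1", c("V1", "V2"),
                                  c("2012-05-01", "2017-06-01")))
  expect_equal(component_cover(ds, "P1", "V1", "wooded"), 303 / 1010 * 100)
  expect_equal(component_cover(ds, "P1", "V1", "herbaceous"), 101 / 1010 * 100)
  # double-computation oracle: bare = 100 - vegetated, from the profile
  prof <- compute_profile(ds, "P1", "V1")
  expect_equal(component_cover(ds, "P1", "V1", "bare"), prof$bare_pct)

  wooded <- classify_cover_shift(ds, "P1", "V1", "V2", "wooded")
  expect_equal(wooded$direction, "decreased")
  expect_equal(wooded$value_first_pct, 30)
  expect_equal(wooded$value_last_pct, 25.04950495049505)
  herb <- classify_cover_shift(ds, "P1", "V1", "V2", "herbaceous")
  expect_equal(herb$direction, "unchanged")
  expect_equal(herb$interval_years,
               as.numeric(as.Date("2017-06-01") - as.Date("2012-05-01")) / 365.25)
})

test_that("cover-shift tallies partition every qualifying plot", {
  sim <- generate_dataset(small_sim_config(seed = 61, n_plots = 2L,
                                           visit_schedule = c(0, 6)))
  tal <- tally_cover_shifts(sim$dataset, min_interval_years = 4)
  expect_true(nrow(tal) > 0)
  expect_equal(tal$increased_n + tal$decreased_n + tal$unchanged_n,
               tal$total_plots)
  expect_equal(tal$increased_pct + tal$decreased_pct + tal$unchanged_pct,
               rep(100, nrow(tal)))
  expect_setequal(unique(tal$group),
                  c("Hummock & Tussock Grasslands", "Acacia & Other Shrublands",
                    "Eucalypt & Mallee Woodlands"))

  # brute-force oracle for one cell
  pairs <- pair_revisits(sim$dataset, "first_to_last")
  pairs <- pairs[pairs$interval_years > 4, ]
  mvg <- sim$dataset$visits$mvg_label[
    match(paste(pairs$plot_id, pairs$baseline_visit),
          paste(sim$dataset$visits$plot_id, sim$dataset$visits$visit_id))]
  wood <- pairs[assign_groups(mvg)$streamlined_group == "Woodlands", ]
  dirs <- vapply(seq_len(nrow(wood)), function(i) {
    classify_cover_shift(sim$dataset, wood$plot_id[i], wood$baseline_visit[i],
                         wood$revisit[i], "bare")$direction
  }, "")
  cell <- tal[tal$group == "Eucalypt & Mallee Woodlands" &
                tal$component == "bare", ]
  expect_equal(cell$increased_n, sum(dirs == "increased"))
  expect_equal(cell$total_plots, nrow(wood))

  none <- tally_cover_shifts(sim$dataset, min_interval_years = 50)
  expect_equal(nrow(none), 0)
})

test_that("vegetated-area trajectories recover exact and constant trends", {
  mkvisit <- function(visit, n_pts) {
    species_records("P1", visit, "SPA", "Shrub", n_pts, 10L)
  }
  dates <- as.Date("2012-01-01") + c(0, 730, 1460)
  ds <- survey_dataset(
    dplyr::bind_rows(mkvisit("V1", 101L), mkvisit("V2", 202L),
                     mkvisit("V3", 303L)),
    toy_visits("P1", c("V1", "V2", "V3"), dates))
  traj <- vegetated_area_trajectory(ds, group_by = "mvg_label")
  # vegetated cover gains exactly 10 percentage points per 730 days
  expect_equal(traj$fits$slope, (101 / 1010 * 100) / (730 / 365.25))
  expect_equal(traj$fits$r_squared, 1)

  flat <- survey_dataset(
    dplyr::bind_rows(mkvisit("V1", 150L), mkvisit("V2", 150L)),
    toy_visits("P1", c("V1", "V2"), c("2012-01-01", "2015-01-01")))
  expect_equal(vegetated_area_trajectory(flat)$fits$slope, 0)
})
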