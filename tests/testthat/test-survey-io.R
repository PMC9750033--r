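test_that("a minimal two-row survey reads into one visit with two records", {
  tmp <- withr::local_tempdir()
  rec_path <- file.path(tmp, "records.csv")
  meta_path <- file.path(tmp, "visits.csv")
  writeLines(c(
    "plot_id,visit_id,visit_date,transect,point,hit_kind,species_code,growth_form",
    "P1,V1,2013-06-01,1,0,species,SPX,Shrub",
    "P1,V1,2013-06-01,1,0,bare_soil,,"), rec_path)
  writeLines(c("plot_id,visit_id,visit_date,mvg_label,notes",
               "P1,V1,2013-06-01,Acacia Shrublands,"), meta_path)
  ds <- read_survey_table(rec_path, meta_path)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$visits), 1)
  expect_equal(nrow(ds$records), 2)
  expect_equal(ds$visits$visit_date, as.Date("2013-06-01"))
})

test_that("missing columns and out-of-range indices are rejected with names", {
  tmp <- withr::local_tempdir()
  rec_path <- file.path(tmp, "records.csv")
  meta_path <- file.path(tmp, "visits.csv")
  writeLines(c("plot_id,visit_id,visit_date,transect,point,hit_kind,species_code",
               "P1,V1,2013-06-01,1,0,species,SPX"), rec_path)
  writeLines(c("plot_id,visit_id,visit_date,mvg_label,notes",
               "P1,V1,2013-06-01,Acacia Shrublands,"), meta_path)
  expect_error(read_survey_table(rec_path, meta_path), "growth_form",
               class = "vegshift_format_error")

  rec <- species_records("P1", "V1", "SPX", "Shrub", 5L, 1L)
  rec$transect[1] <- 11L
  expect_error(survey_dataset(rec, toy_visits("P1", "V1", "2013-06-01")),
               "transect out of range", class = "vegshift_integrity_error")
})

test_that("validate_dataset reports violations as data with coordinates", {
  ok <- two_species_dataset()
  expect_equal(nrow(validate_dataset(ok)), 0)

  rec <- species_records("P1", "V1", "SPX", "Shrub", 3L, 1L)
  rec$point[1] <- 101L
  bad <- survey_dataset(rec, toy_visits("P1", "V1", "2013-06-01"),
                        strict = FALSE)
  rep1 <- validate_dataset(bad)
  expect_equal(rep1$rule, "point_index out of range")
  expect_equal(rep1$plot_id, "P1")

  rec2 <- tibble::tibble(
    plot_id = "P1", visit_id = "V1", transect = 1L, point = c(0L, 0L),
    hit_kind = "bare_soil", species_code = "", growth_form = "")
  bad2 <- survey_dataset(rec2, toy_visits("P1", "V1", "2013-06-01"),
                         strict = FALSE)
  rep2 <- validate_dataset(bad2)
  expect_equal(rep2$rule, "duplicate substrate hit")

  rec3 <- species_records("P1", "V9", "SPX", "Shrub", 3L, 1L)
  bad3 <- survey_dataset(rec3, toy_visits("P1", "V1", "2013-06-01"),
                         strict = FALSE)
  expect_true("record references unknown visit" %in% validate_dataset(bad3)$rule)
})

test_that("write then read is the identity on a generated dataset", {
  sim <- generate_dataset(small_sim_config(seed = 11, n_plots = 1L,
                                           visit_schedule = c(0, 2)))
  tmp <- withr::local_tempdir()
  write_survey_table(sim$dataset, file.path(tmp, "r.csv"),
                     file.path(tmp, "v.csv"))
  back <- read_survey_table(file.path(tmp, "r.csv"), file.path(tmp, "v.csv"))
  expect_equal(back$records, sim$dataset$records)
  expect_equal(back$visits, sim$dataset$visits)
  expect_equal(back$points_per_plot, sim$dataset$points_per_plot)
})

test_that("writing an empty dataset yields header-only files that read back", {
  empty <- survey_dataset(
    tibble::tibble(plot_id = character(), visit_id = character(),
                   transect = integer(), point = integer(),
                   hit_kind = character(), species_code = character(),
                   growth_form = character()),
    toy_visits(character(), character(), as.Date(character())))
  tmp <- withr::local_tempdir()
  write_survey_table(empty, file.path(tmp, "r.csv"), file.path(tmp, "v.csv"))
  expect_equal(length(readLines(file.path(tmp, "r.csv"))), 1)
  back <- read_survey_table(file.path(tmp, "r.csv"), file.path(tmp, "v.csv"))
  expect_equal(nrow(back$records), 0)
})

test_that("revisit pairing computes fractional-year intervals per mode", {
  rec <- dplyr::bind_rows(
    species_records("P1", "V1", "SPA", "Shrub", 5L, 1L),
    species_records("P1", "V2", "SPA", "Shrub", 5L, 1L),
    species_records("P1", "V3", "SPA", "Shrub", 5L, 1L))
  vis <- toy_visits("P1", c("V1", "V2", "V3"),
                    c("2012-05-01", "2015-05-01", "2017-05-01"))
  ds <- survey_dataset(rec, vis)

  pairs <- pair_revisits(ds, "baseline_to_each")
  expect_equal(nrow(pairs), 2)
  expect_equal(unique(pairs$baseline_visit), "V1")
  expect_equal(pairs$interval_years[pairs$revisit == "V3"], 1826 / 365.25)

  fl <- pair_revisits(ds, "first_to_last")
  expect_equal(nrow(fl), 1)
  expect_equal(fl$revisit, "V3")
  expect_equal(fl$interval_years, 1826 / 365.25)
})

test_that("pair counts follow visit counts and row order does not matter", {
  sim <- generate_dataset(small_sim_config(seed = 3, n_plots = 2L))
  ds <- sim$dataset
  nv <- table(ds$visits$plot_id)
  expect_equal(nrow(pair_revisits(ds, "baseline_to_each")), sum(nv - 1))
  expect_equal(nrow(pair_revisits(ds, "first_to_last")), sum(nv >= 2))

  shuffled <- withr::with_seed(1, {
    survey_dataset(ds$records[sample(nrow(ds$records)), ],
                   ds$visits[sample(nrow(ds$visits)), ])
  })
  expect_equal(pair_revisits(shuffled), pair_revisits(ds))
  expect_equal(shuffled$records, ds$records)
})
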