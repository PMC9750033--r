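#' Run the full repeat-visit change analysis and write a report bundle
#'
#' End-to-end orchestration: obtain a survey dataset (either read from the
#' two-file CSV form or simulated from a [simulation_config()]), then
#' compute and write every analysis table as CSV — per-visit community and
#' diversity summaries, baseline dissimilarity records per metric,
#' dissimilarity-versus-interval fits per streamlined group / physiognomy /
#' MVG, annualised-shift ANOVAs (wooded vs herbaceous, global MVG, all
#' pairwise uncorrected), the dominance-shift summary, structural
#' growth-form profiles and cover-shift tallies, and vegetated-area fits —
#' plus a machine-readable JSON manifest recording the configuration, seed,
#' package version, design decisions in force, and per-table row counts.
#'
#' The bundle is deterministic: the same inputs (or the same simulation
#' seed) produce byte-identical files. Tables are staged in a temporary
#' directory and moved into `out_dir` only on success, so a failed run
#' leaves no partial bundle.
#'
#' @param out_dir Output directory (created if needed).
#' @param input,metadata Paths to the intercept and visit-metadata CSVs;
#'   give these *or* `sim_config`, not both.
#' @param sim_config A [simulation_config()] for a simulated campaign.
#' @param basis Abundance basis for all dissimilarities (`"ivi"` default).
#' @param min_interval_years Strict interval filter for annualised shifts
#'   and cover tallies (default 4).
#' @param dominance_tol Unchanged band on delta sigma (default 0).
#' @param cover_tol Unchanged band on component cover, percentage points
#'   (default 0).
#' @param metrics Dissimilarity metrics to tabulate (default sorensen +
#'   simpson_beta; growth_form_sorensen is always computed for the
#'   structural fits).
#' @param verbose Log per-stage progress to standard error.
#' @return Invisibly, a list with the dataset, every table, and the
#'   manifest.
#' @export
run_report <- function(out_dir, input = NULL, metadata = NULL,
                       sim_config = NULL, basis = c("ivi", "cover"),
                       min_interval_years = 4, dominance_tol = 0,
                       cover_tol = 0,
                       metrics = c("sorensen", "simpson_beta"),
                       verbose = FALSE) {
  basis <- match.arg(basis)
  metrics <- match.arg(metrics, c("sorensen", "simpson_beta",
                                  "growth_form_sorensen"), several.ok = TRUE)
  has_files <- !is.null(input) || !is.null(metadata)
  if (has_files == !is.null(sim_config)) {
    abort("give either input+metadata paths or a sim_config, not both",
          class = "vegshift_config_error")
  }
  say <- function(...) if (verbose) message("[vegshift] ", ...)

  stage_dir <- tempfile("vegshift_report_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  tables <- list()
  notes <- character()
  emit <- function(name, tbl) {
    tables[[name]] <<- tbl
    readr::write_csv(tbl, file.path(stage_dir, paste0(name, ".csv")),
                     progress = FALSE)
  }

  if (has_files) {
    say("reading ", input)
    dataset <- read_survey_table(input, metadata)
    ground_truth <- NULL
  } else {
    say("simulating with seed ", sim_config$seed)
    sim <- generate_dataset(sim_config)
    dataset <- sim$dataset
    ground_truth <- sim$ground_truth
    emit("ground_truth", ground_truth)
  }
  write_survey_table(dataset, file.path(stage_dir, "records.csv"),
                     file.path(stage_dir, "visits.csv"))

  say("profiling ", nrow(dataset$visits), " visits")
  profiles <- profile_all_visits(dataset)
  emit("community_profiles", profiles_to_table(profiles))
  emit("diversity_summary",
       dplyr::bind_rows(lapply(profiles, diversity_summary, basis = basis)))

  for (metric in metrics) {
    say("dissimilarities: ", metric)
    emit(paste0("dissimilarity_", metric),
         baseline_dissimilarities(dataset, metric, basis))
  }
  diss <- tables[[paste0("dissimilarity_", metrics[1])]]

  say("trajectory fits")
  empty_fits <- tibble::tibble(grouping = character(), group = character(),
                               n = integer(), slope = numeric(),
                               intercept = numeric(), r_squared = numeric())
  if (nrow(diss) == 0) {
    notes <- c(notes, "no repeat visits: trajectory fits are empty")
    emit("trajectory_fits", empty_fits)
  } else {
    fits <- dplyr::bind_rows(
      dplyr::mutate(fit_trajectory(diss, "streamlined_group"),
                    grouping = "streamlined_group"),
      dplyr::mutate(fit_trajectory(diss, "physiognomy"),
                    grouping = "physiognomy"),
      dplyr::mutate(fit_trajectory(diss, "mvg_label"), grouping = "mvg_label"))
    emit("trajectory_fits", fits[c("grouping", "group", "n", "slope",
                                   "intercept", "r_squared")])
  }

  say("annualised shifts (interval > ", min_interval_years, " yr)")
  ann <- annualized_shifts(diss, min_interval_years)
  emit("annualized_shifts", ann)
  anova_rows <- list()
  if (nrow(ann) == 0) {
    notes <- c(notes, paste0("no revisit exceeds ", min_interval_years,
                             " years: annualised-shift ANOVAs and cover",
                             " tallies are empty"))
  } else {
    for (grouping in c("physiognomy", "mvg_label")) {
      ok <- ann |>
        dplyr::count(.data[[grouping]]) |>
        dplyr::filter(.data$n >= 2)
      usable <- ann[ann[[grouping]] %in% ok[[grouping]], ]
      if (nrow(ok) >= 2) {
        res <- oneway_anova(usable, "rate", grouping)
        anova_rows[[grouping]] <- tibble::tibble(
          grouping = grouping, f = res$f, df1 = res$df_between,
          df2 = res$df_within, p_value = res$p_value)
      } else {
        notes <- c(notes, paste0("annualised-shift ANOVA by ", grouping,
                                 " skipped: fewer than 2 groups with >= 2",
                                 " qualifying revisits"))
      }
    }
  }
  an_tbl <- dplyr::bind_rows(anova_rows)
  if (nrow(an_tbl) == 0) {
    an_tbl <- tibble::tibble(grouping = character(), f = numeric(),
                             df1 = integer(), df2 = integer(),
                             p_value = numeric())
  }
  emit("annualized_anova", an_tbl)
  emit("annualized_anova_pairwise", pairwise_anova(ann, "rate", "mvg_label"))

  say("dominance shifts")
  shifts <- dominance_shifts(dataset, basis, dominance_tol)
  emit("dominance_shifts", shifts)
  emit("dominance_summary",
       if (nrow(shifts) > 0) summarize_dominance(shifts, "mvg_label")
       else tibble::tibble(group = character(), n_increased = integer(),
                           n_decreased = integer(), n_unchanged = integer()))

  say("structure")
  gf_tables <- lapply(seq_len(nrow(dataset$visits)), function(i) {
    p <- growth_form_profile(dataset, dataset$visits$plot_id[i],
                             dataset$visits$visit_id[i])
    dplyr::mutate(p$forms, plot_id = p$plot_id, visit_id = p$visit_id,
                  vegetated_pct = p$vegetated_pct, .before = 1)
  })
  emit("growth_form_profiles", dplyr::bind_rows(gf_tables))
  emit("structure_tally",
       tally_cover_shifts(dataset, min_interval_years, cover_tol))
  gf_diss <- baseline_dissimilarities(dataset, "growth_form_sorensen")
  emit("dissimilarity_growth_form_sorensen", gf_diss)
  if (nrow(gf_diss) == 0) {
    emit("structure_fits", empty_fits)
    emit("vegetated_area_records",
         tibble::tibble(plot_id = character(), visit_id = character(),
                        interval_years = numeric(),
                        delta_vegetated_pct = numeric()))
    emit("vegetated_area_fits", empty_fits[-1])
  } else {
    emit("structure_fits",
         dplyr::mutate(fit_trajectory(gf_diss, "streamlined_group"),
                       grouping = "streamlined_group"))
    veg <- vegetated_area_trajectory(dataset, "mvg_label")
    emit("vegetated_area_records", veg$records)
    emit("vegetated_area_fits", veg$fits)
  }

  manifest <- list(
    package = "vegshift",
    version = as.character(utils::packageVersion("vegshift")),
    input = if (has_files) list(records = input, metadata = metadata)
      else "simulated",
    seed = if (is.null(sim_config)) NA else sim_config$seed,
    basis = basis,
    min_interval_years = min_interval_years,
    dominance_tol = dominance_tol,
    cover_tol = cover_tol,
    metrics = metrics,
    decisions = c(
      "abundance basis for dissimilarities defaults to species IVI",
      "intervals in fractional years (days / 365.25)",
      "annualised-shift filter: interval strictly greater than min_interval_years",
      "Simpson beta = min(b,c)/(min(b,c)+a) (richness-difference insensitive)",
      "Whittaker beta = gamma / mean alpha; half-changes = ln(mean similarity)/ln(0.5)",
      "lognormal SAD sigma = ML standard deviation of log abundances of observed species (no veil-line correction)",
      "dominance summary means are of |delta sigma| within each direction class",
      "pairwise ANOVAs are uncorrected for multiplicity",
      "wooded component = Trees + Shrubs; herbaceous = Hummock + Tussock grasses; chenopods, sedges, forbs and others excluded from the dichotomy",
      "unrecorded point slots count as bare ground"),
    notes = notes,
    row_counts = lapply(tables, nrow))
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage_dir)) {
    file.copy(file.path(stage_dir, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  say("report written to ", out_dir)
  invisible(c(list(dataset = dataset, ground_truth = ground_truth,
                   manifest = manifest), tables))
}
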