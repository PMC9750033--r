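# Fixture builders: everything is constructed in code, no files on disk.

# Records for one species covering `n_points` distinct points spread over
# the first `n_transects` transects (filling transects in order).
species_records <- function(plot_id, visit_id, species_code, growth_form,
                            n_points, n_transects,
                            point_offset = 0L) {
  stopifnot(n_points <= n_transects * 101, point_offset + ceiling(n_points / n_transects) <= 101)
  per <- ceiling(n_points / n_transects)
  transect <- rep(seq_len(n_transects), each = per)[seq_len(n_points)]
  point <- (rep(seq_len(per) - 1L, times = n_transects)[seq_len(n_points)]) +
    point_offset
  tibble::tibble(plot_id = plot_id, visit_id = visit_id,
                 transect = as.integer(transect), point = as.integer(point),
                 hit_kind = "species", species_code = species_code,
                 growth_form = growth_form)
}

toy_visits <- function(plot_id, visit_ids, dates,
                       mvg_label = "Acacia Shrublands") {
  tibble::tibble(plot_id = plot_id, visit_id = visit_ids,
                 visit_date = as.Date(dates), mvg_label = mvg_label,
                 notes = "")
}

# The canonical worked example: species A covers 20% (202 points, all 10
# transects), species B 10% (101 points, 5 transects). Relative cover and
# frequency both split 2:1, so the IVIs are 133.33 / 66.67.
two_species_dataset <- function() {
  rec <- dplyr::bind_rows(
    species_records("P1", "V1", "SPA", "Shrub", 202L, 10L),
    species_records("P1", "V1", "SPB", "Forb", 101L, 5L, point_offset = 50L))
  survey_dataset(rec, toy_visits("P1", "V1", "2012-05-01"))
}

# A hand-made community profile from abundance values (bypasses the survey
# layer; used to test metrics on exactly chosen numbers).
manual_profile <- function(abundances, plot_id = "P", visit_id = "V",
                           growth_form = "Shrub") {
  sp <- tibble::tibble(
    species_code = names(abundances), growth_form = growth_form,
    pi_count = NA_integer_, cover_pct = unname(abundances),
    frequency = NA_integer_,
    rel_cover_pct = unname(abundances) / sum(abundances) * 100,
    rel_freq_pct = unname(abundances) / sum(abundances) * 100,
    ivi = unname(abundances))
  structure(list(plot_id = plot_id, visit_id = visit_id, species = sp,
                 vegetated_pct = NA_real_, bare_pct = NA_real_,
                 non_vascular_pct = NA_real_, points_per_plot = 1010L),
            class = "community_profile")
}

# Small simulated campaign for integration-style tests.
small_sim_config <- function(seed = 42, n_plots = 2L,
                             visit_schedule = c(0, 3, 6)) {
  groups <- default_sim_groups()
  groups$n_plots <- n_plots
  simulation_config(groups = groups, visit_schedule = visit_schedule,
                    seed = seed)
}
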