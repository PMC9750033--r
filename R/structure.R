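MERGED_FORMS <- c("Trees", "Shrubs", "Sedges", "HummockGrass", "TussockGrass",
                  "Chenopods", "ForbsHerbs", "Others")

#' Default mapping from raw field growth-form labels to the eight merged forms
#'
#' Trees (tree, tree mallee, tree-palm and similar), Shrubs (shrub, heath
#' shrub, shrub mallee, acacia shrub), Sedges, Hummock Grass, Tussock
#' Grass, Chenopods, Forbs and Herbs, and Others for groups of minute
#' abundance (epiphytes, ferns, rushes, vines). Keys are matched
#' case-insensitively after whitespace normalisation.
#'
#' @return A named character vector: raw label (lower case) -> merged form.
#' @export
default_growth_form_map <- function() {
  c("tree" = "Trees", "tree mallee" = "Trees", "tree-palm" = "Trees",
    "tree palm" = "Trees", "palm" = "Trees",
    "shrub" = "Shrubs", "heath shrub" = "Shrubs", "heath-shrub" = "Shrubs",
    "shrub mallee" = "Shrubs", "mallee shrub" = "Shrubs",
    "acacia shrub" = "Shrubs",
    "sedge" = "Sedges",
    "hummock grass" = "HummockGrass",
    "tussock grass" = "TussockGrass",
    "chenopod" = "Chenopods", "chenopod shrub" = "Chenopods",
    "forb" = "ForbsHerbs", "herb" = "ForbsHerbs", "forb/herb" = "ForbsHerbs",
    "epiphyte" = "Others", "fern" = "Others", "rush" = "Others",
    "vine" = "Others", "vines" = "Others")
}

#' Merge raw growth-form labels into the eight structural groups
#'
#' @param raw_label Character vector of raw field labels.
#' @param map Named mapping (lower-case raw label -> merged form); defaults
#'   to [default_growth_form_map()].
#' @return Character vector of merged forms (one of Trees, Shrubs, Sedges,
#'   HummockGrass, TussockGrass, Chenopods, ForbsHerbs, Others). Unmapped
#'   labels are an error, never silently folded into Others.
#' @export
merge_growth_form <- function(raw_label, map = default_growth_form_map()) {
  key <- tolower(gsub("\\s+", " ", trimws(as.character(raw_label))))
  merged <- unname(map[key])
  if (anyNA(merged)) {
    abort(paste0("unmapped growth form label(s): ",
                 paste(unique(raw_label[is.na(merged)]), collapse = ", ")),
          class = "vegshift_mapping_error")
  }
  merged
}

#' Growth-form structural profile of a visit
#'
#' The structural analogue of [compute_profile()]: species hits are pooled
#' into the eight merged growth forms, and each form receives a growth-form
#' IVI = relative species count (%) + relative point-intercept count (%),
#' summing to 200 over the forms of a vegetated visit. `pi_count` is the
#' number of distinct points intercepting any species of the form (a point
#' carrying both a tree and a grass counts toward both forms).
#'
#' @param dataset A [survey_dataset()].
#' @param plot_id,visit_id The visit.
#' @param gf_map Raw-to-merged mapping, see [merge_growth_form()].
#' @return An object of class `growth_form_profile`: a `forms` tibble with
#'   one row per merged form (zero rows filled in) and columns `n_species`,
#'   `pi_count`, `rel_species_pct`, `rel_pi_pct`, `gf_ivi`, plus
#'   `vegetated_pct` and identifiers. An unvegetated visit yields an
#'   all-zero profile.
#' @export
growth_form_profile <- function(dataset, plot_id, visit_id,
                                gf_map = default_growth_form_map()) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!any(dataset$visits$plot_id == plot_id &
             dataset$visits$visit_id == visit_id)) {
    abort(paste0("unknown visit: ", plot_id, "/", visit_id))
  }
  n_pts <- dataset$points_per_plot
  rec <- dataset$records[dataset$records$plot_id == plot_id &
                           dataset$records$visit_id == visit_id &
                           dataset$records$hit_kind == "species", ]
  empty <- tibble::tibble(form = MERGED_FORMS, n_species = 0L, pi_count = 0L,
                          rel_species_pct = 0, rel_pi_pct = 0, gf_ivi = 0)
  if (nrow(rec) == 0) {
    return(structure(list(plot_id = plot_id, visit_id = visit_id,
                          forms = empty, vegetated_pct = 0,
                          points_per_plot = n_pts),
                     class = "growth_form_profile"))
  }
  rec$form <- merge_growth_form(rec$growth_form, gf_map)
  by_form <- rec |>
    dplyr::group_by(.data$form) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species_code),
      pi_count = dplyr::n_distinct(paste(.data$transect, .data$point)),
      .groups = "drop")
  forms <- empty |>
    dplyr::select("form") |>
    dplyr::left_join(by_form, by = "form") |>
    dplyr::mutate(dplyr::across(c("n_species", "pi_count"),
                                ~ ifelse(is.na(.x), 0L, .x))) |>
    dplyr::mutate(
      rel_species_pct = .data$n_species / sum(.data$n_species) * 100,
      rel_pi_pct = .data$pi_count / sum(.data$pi_count) * 100,
      gf_ivi = .data$rel_species_pct + .data$rel_pi_pct)
  vegetated_pct <- dplyr::n_distinct(paste(rec$transect, rec$point)) /
    n_pts * 100
  structure(list(plot_id = plot_id, visit_id = visit_id, forms = forms,
                 vegetated_pct = vegetated_pct, points_per_plot = n_pts),
            class = "growth_form_profile")
}

#' @export
print.growth_form_profile <- function(x, ...) {
  cat("<growth_form_profile> ", x$plot_id, "/", x$visit_id, ": vegetated ",
      sprintf("%.1f", x$vegetated_pct), "%\n", sep = "")
  print(x$forms)
  invisible(x)
}

#' Structural (growth-form) Sorensen distance between two visits
#'
#' Bray-Curtis dissimilarity on the growth-form IVI vectors over the eight
#' merged forms — the structural counterpart of [sorensen_distance()].
#'
#' @param p,q `growth_form_profile` objects.
#' @return A number in [0, 1]; `NA` when both visits are unvegetated.
#' @export
structure_distance <- function(p, q) {
  stopifnot(inherits(p, "growth_form_profile"),
            inherits(q, "growth_form_profile"))
  a <- setNames(p$forms$gf_ivi, p$forms$form)[MERGED_FORMS]
  b <- setNames(q$forms$gf_ivi, q$forms$form)[MERGED_FORMS]
  if (sum(a) == 0 && sum(b) == 0) return(NA_real_)
  if (sum(a) == 0 || sum(b) == 0) return(1)
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Percentage of points intercepting a structural component
#'
#' `"wooded"` counts points hit by any Trees or Shrubs species,
#' `"herbaceous"` points hit by hummock or tussock grasses, and `"bare"`
#' the bare-ground percentage of the visit profile (points with no living
#' vascular cover and no other recorded substrate).
#'
#' @param dataset A [survey_dataset()].
#' @param plot_id,visit_id The visit.
#' @param component `"wooded"`, `"herbaceous"` or `"bare"`.
#' @param gf_map Growth-form mapping.
#' @return A percentage of the 1010 point slots.
#' @export
component_cover <- function(dataset, plot_id, visit_id,
                            component = c("wooded", "herbaceous", "bare"),
                            gf_map = default_growth_form_map()) {
  component <- match.arg(component)
  if (component == "bare") {
    return(compute_profile(dataset, plot_id, visit_id)$bare_pct)
  }
  forms <- if (component == "wooded") c("Trees", "Shrubs")
    else c("HummockGrass", "TussockGrass")
  rec <- dataset$records[dataset$records$plot_id == plot_id &
                           dataset$records$visit_id == visit_id &
                           dataset$records$hit_kind == "species", ]
  if (nrow(rec) == 0) return(0)
  rec$form <- merge_growth_form(rec$growth_form, gf_map)
  hit <- rec[rec$form %in% forms, ]
  dplyr::n_distinct(paste(hit$transect, hit$point)) /
    dataset$points_per_plot * 100
}

#' Classify the cover shift of one structural component of a plot
#'
#' Compares the component's percentage cover at two visits: increased if
#' the change exceeds `tol_pct`, decreased if below `-tol_pct`, else
#' unchanged. The default tolerance 0 treats only exact ties (possible
#' because covers are ratios of integer point counts) as unchanged.
#'
#' @param dataset A [survey_dataset()].
#' @param plot_id Plot identifier.
#' @param first_visit,last_visit Visit identifiers, `first_visit` earlier.
#' @param component `"wooded"`, `"herbaceous"` or `"bare"`.
#' @param tol_pct Unchanged band in percentage points.
#' @param gf_map Growth-form mapping.
#' @return A one-row tibble: `plot_id`, `component`, `value_first_pct`,
#'   `value_last_pct`, `direction`, `interval_years`.
#' @export
classify_cover_shift <- function(dataset, plot_id, first_visit, last_visit,
                                 component = c("wooded", "herbaceous", "bare"),
                                 tol_pct = 0,
                                 gf_map = default_growth_form_map()) {
  component <- match.arg(component)
  vis <- dataset$visits
  d1 <- vis$visit_date[vis$plot_id == plot_id & vis$visit_id == first_visit]
  d2 <- vis$visit_date[vis$plot_id == plot_id & vis$visit_id == last_visit]
  if (length(d1) != 1 || length(d2) != 1) {
    abort(paste0("missing visit for plot ", plot_id))
  }
  v1 <- component_cover(dataset, plot_id, first_visit, component, gf_map)
  v2 <- component_cover(dataset, plot_id, last_visit, component, gf_map)
  delta <- v2 - v1
  direction <- if (delta > tol_pct) "increased"
    else if (delta < -tol_pct) "decreased" else "unchanged"
  tibble::tibble(plot_id = plot_id, component = component,
                 value_first_pct = v1, value_last_pct = v2,
                 direction = direction,
                 interval_years = as.numeric(d2 - d1) / DAYS_PER_YEAR)
}

#' Tally structural cover shifts per merged vegetation group
#'
#' For every plot whose first and last visits are more than
#' `min_interval_years` apart, classifies the wooded, herbaceous and bare
#' cover shifts and tallies increased / decreased / unchanged counts (with
#' percentages of the group total) within three merged groups: Hummock &
#' Tussock Grasslands, Acacia & Other Shrublands, and Eucalypt & Mallee
#' Woodlands.
#'
#' @param dataset A [survey_dataset()].
#' @param min_interval_years Strict lower bound on the first-to-last
#'   interval (default 4).
#' @param tol_pct Unchanged band in percentage points (default 0).
#' @param gf_map Growth-form mapping.
#' @return A tibble: `group`, `component`, `increased_n`, `increased_pct`,
#'   `decreased_n`, `decreased_pct`, `unchanged_n`, `unchanged_pct`,
#'   `total_plots`. Zero rows when no plot qualifies.
#' @export
tally_cover_shifts <- function(dataset, min_interval_years = 4, tol_pct = 0,
                               gf_map = default_growth_form_map()) {
  stopifnot(inherits(dataset, "survey_dataset"))
  pairs <- pair_revisits(dataset, "first_to_last")
  pairs <- pairs[pairs$interval_years > min_interval_years, ]
  empty <- tibble::tibble(group = character(), component = character(),
                          increased_n = integer(), increased_pct = numeric(),
                          decreased_n = integer(), decreased_pct = numeric(),
                          unchanged_n = integer(), unchanged_pct = numeric(),
                          total_plots = integer())
  if (nrow(pairs) == 0) return(empty)
  vis <- dataset$visits
  mvg <- vis$mvg_label[match(paste(pairs$plot_id, pairs$baseline_visit),
                             paste(vis$plot_id, vis$visit_id))]
  streamlined <- assign_groups(mvg)$streamlined_group
  merged_group <- dplyr::case_match(streamlined,
    "Grasslands" ~ "Hummock & Tussock Grasslands",
    "Shrublands" ~ "Acacia & Other Shrublands",
    "Woodlands" ~ "Eucalypt & Mallee Woodlands")
  shifts <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    dplyr::bind_rows(lapply(c("wooded", "herbaceous", "bare"), function(comp) {
      classify_cover_shift(dataset, pairs$plot_id[i], pairs$baseline_visit[i],
                           pairs$revisit[i], comp, tol_pct, gf_map)
    })) |>
      dplyr::mutate(group = merged_group[i])
  }))
  shifts |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(
      increased_n = sum(.data$direction == "increased"),
      decreased_n = sum(.data$direction == "decreased"),
      unchanged_n = sum(.data$direction == "unchanged"),
      total_plots = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      increased_pct = .data$increased_n / .data$total_plots * 100,
      decreased_pct = .data$decreased_n / .data$total_plots * 100,
      unchanged_pct = .data$unchanged_n / .data$total_plots * 100) |>
    dplyr::select("group", "component", "increased_n", "increased_pct",
                  "decreased_n", "decreased_pct", "unchanged_n",
                  "unchanged_pct", "total_plots") |>
    dplyr::arrange(.data$group, .data$component)
}

#' Vegetated-area change trajectories per vegetation group
#'
#' For every revisit, computes the change in vegetated cover (%) relative
#' to the plot's baseline visit; each plot also contributes its baseline as
#' a zero point at interval 0. The changes are regressed on interval
#' (years) per group with [fit_trajectory()]; the slope sign says whether a
#' group is gaining or losing vegetated area.
#'
#' @param dataset A [survey_dataset()].
#' @param group_by Grouping column: `"mvg_label"` (default),
#'   `"streamlined_group"` or `"physiognomy"`.
#' @return A list with `records` (tibble of per-revisit changes, including
#'   the baseline zero points) and `fits` (tibble from [fit_trajectory()]
#'   with `delta_vegetated_pct` as the response).
#' @export
vegetated_area_trajectory <- function(dataset, group_by = "mvg_label") {
  stopifnot(inherits(dataset, "survey_dataset"))
  pairs <- pair_revisits(dataset, "baseline_to_each")
  if (nrow(pairs) == 0) {
    abort("no repeat visits: cannot fit vegetated-area trajectories")
  }
  veg <- function(p, v) compute_profile(dataset, p, v)$vegetated_pct
  base <- pairs |> dplyr::distinct(.data$plot_id, .data$baseline_visit)
  base_veg <- setNames(
    vapply(seq_len(nrow(base)),
           function(i) veg(base$plot_id[i], base$baseline_visit[i]), 0.0),
    base$plot_id)
  records <- dplyr::bind_rows(
    tibble::tibble(plot_id = base$plot_id, visit_id = base$baseline_visit,
                   interval_years = 0, delta_vegetated_pct = 0),
    tibble::tibble(
      plot_id = pairs$plot_id, visit_id = pairs$revisit,
      interval_years = pairs$interval_years,
      delta_vegetated_pct = vapply(seq_len(nrow(pairs)), function(i) {
        veg(pairs$plot_id[i], pairs$revisit[i]) - base_veg[[pairs$plot_id[i]]]
      }, 0.0)))
  vis <- dataset$visits
  mvg <- vis$mvg_label[match(paste(records$plot_id, records$visit_id),
                             paste(vis$plot_id, vis$visit_id))]
  groups <- assign_groups(mvg)
  records$mvg_label <- groups$mvg_label
  records$streamlined_group <- groups$streamlined_group
  records$physiognomy <- groups$physiognomy
  fits <- fit_trajectory(records, group_by = group_by,
                         x = "interval_years", y = "delta_vegetated_pct")
  list(records = records, fits = fits)
}
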