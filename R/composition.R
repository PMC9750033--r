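#' Per-visit community profile: cover, frequency and importance value index
#'
#' Summarises one plot visit into the standard point-intercept community
#' table. For each species: `pi_count` is the number of distinct points
#' (out of 1010) at which it was intercepted (a species touched in several
#' canopy strata at one point counts once, so cover cannot exceed 100%);
#' `cover_pct = pi_count / 1010 * 100`; `frequency` is the number of the 10
#' transects on which it was recorded (1-10). Relative cover and relative
#' frequency are each species' share of the respective column sums (in %),
#' and their sum is the importance value index (IVI), which totals 200 over
#' the species of a visit.
#'
#' Ground-cover accounting classifies every one of the 1010 point slots:
#' vegetated (at least one species hit), non-vascular/other (a
#' `non_vascular_other` hit and no species hit), or bare (everything else —
#' a `bare_soil` hit, or no recorded hit at all, the point-intercept
#' convention for bare ground). The three percentages sum to 100.
#'
#' @param dataset A [survey_dataset()].
#' @param plot_id,visit_id The visit to profile (must exist in the
#'   metadata).
#' @return An object of class `community_profile`: `species` (tibble with
#'   columns `species_code`, `growth_form`, `pi_count`, `cover_pct`,
#'   `frequency`, `rel_cover_pct`, `rel_freq_pct`, `ivi`, sorted by
#'   descending IVI), plus `vegetated_pct`, `bare_pct`,
#'   `non_vascular_pct` and the identifiers. A visit with no species hits
#'   yields an empty species table, not an error.
#' @export
compute_profile <- function(dataset, plot_id, visit_id) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!any(dataset$visits$plot_id == plot_id &
             dataset$visits$visit_id == visit_id)) {
    abort(paste0("unknown visit: ", plot_id, "/", visit_id))
  }
  n_pts <- dataset$points_per_plot
  rec <- dataset$records[dataset$records$plot_id == plot_id &
                           dataset$records$visit_id == visit_id, ]

  sp_hits <- rec[rec$hit_kind == "species", ]
  if (nrow(sp_hits) > 0) {
    sp <- sp_hits |>
      dplyr::distinct(.data$species_code, .data$growth_form, .data$transect,
                      .data$point) |>
      dplyr::group_by(.data$species_code) |>
      dplyr::summarise(
        growth_form = .data$growth_form[1],
        pi_count = dplyr::n_distinct(paste(.data$transect, .data$point)),
        frequency = dplyr::n_distinct(.data$transect),
        .groups = "drop") |>
      dplyr::mutate(
        cover_pct = .data$pi_count / n_pts * 100,
        rel_cover_pct = .data$cover_pct / sum(.data$cover_pct) * 100,
        rel_freq_pct = .data$frequency / sum(.data$frequency) * 100,
        ivi = .data$rel_cover_pct + .data$rel_freq_pct) |>
      dplyr::select("species_code", "growth_form", "pi_count", "cover_pct",
                    "frequency", "rel_cover_pct", "rel_freq_pct", "ivi") |>
      dplyr::arrange(dplyr::desc(.data$ivi), .data$species_code)
  } else {
    sp <- tibble::tibble(species_code = character(), growth_form = character(),
                         pi_count = integer(), cover_pct = numeric(),
                         frequency = integer(), rel_cover_pct = numeric(),
                         rel_freq_pct = numeric(), ivi = numeric())
  }

  pt_key <- function(d) unique(paste(d$transect, d$point))
  veg_pts <- pt_key(sp_hits)
  nv_pts <- setdiff(pt_key(rec[rec$hit_kind == "non_vascular_other", ]), veg_pts)
  vegetated_pct <- length(veg_pts) / n_pts * 100
  non_vascular_pct <- length(nv_pts) / n_pts * 100
  bare_pct <- 100 - vegetated_pct - non_vascular_pct

  structure(list(plot_id = plot_id, visit_id = visit_id, species = sp,
                 vegetated_pct = vegetated_pct, bare_pct = bare_pct,
                 non_vascular_pct = non_vascular_pct,
                 points_per_plot = n_pts),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> ", x$plot_id, "/", x$visit_id, ": ",
      nrow(x$species), " species, vegetated ",
      sprintf("%.1f", x$vegetated_pct), "%, bare ",
      sprintf("%.1f", x$bare_pct), "%\n", sep = "")
  invisible(x)
}

profile_abundance <- function(profile, basis = c("ivi", "cover")) {
  basis <- match.arg(basis)
  col <- if (basis == "ivi") "ivi" else "cover_pct"
  setNames(profile$species[[col]], profile$species$species_code)
}

#' Diversity summary of a community profile
#'
#' Richness S, Shannon H' (natural log), Simpson D = 1 - sum(p^2), Pielou
#' evenness E = H'/ln(S) (reported as `NA` for S = 1, where it is
#' undefined), and the maximum species IVI (200 indicates monodominance).
#'
#' @param profile A `community_profile` with at least one species.
#' @param basis Abundance basis for the proportions: `"ivi"` (default) or
#'   `"cover"`.
#' @return A one-row tibble: `plot_id`, `visit_id`, `S`, `H`, `D`, `E`,
#'   `max_ivi`, `vegetated_pct`, `bare_pct`. An empty profile yields S = 0
#'   and `NA` indices.
#' @export
diversity_summary <- function(profile, basis = c("ivi", "cover")) {
  stopifnot(inherits(profile, "community_profile"))
  ab <- profile_abundance(profile, basis)
  S <- length(ab)
  if (S == 0) {
    return(tibble::tibble(plot_id = profile$plot_id,
                          visit_id = profile$visit_id, S = 0L, H = NA_real_,
                          D = NA_real_, E = NA_real_, max_ivi = NA_real_,
                          vegetated_pct = profile$vegetated_pct,
                          bare_pct = profile$bare_pct))
  }
  p <- ab / sum(ab)
  H <- as.numeric(vegan::diversity(p, index = "shannon"))
  D <- 1 - sum(p^2)
  E <- if (S == 1) NA_real_ else H / log(S)
  tibble::tibble(plot_id = profile$plot_id, visit_id = profile$visit_id,
                 S = S, H = H, D = D, E = E,
                 max_ivi = max(profile$species$ivi),
                 vegetated_pct = profile$vegetated_pct,
                 bare_pct = profile$bare_pct)
}

union_matrix <- function(a, b) {
  species <- sort(union(names(a), names(b)))
  m <- rbind(ifelse(species %in% names(a), a[species], 0),
             ifelse(species %in% names(b), b[species], 0))
  colnames(m) <- species
  m
}

#' Sorensen (Bray-Curtis) dissimilarity between two visits
#'
#' Abundance-based dissimilarity 1 - 2 sum(min(a_i, b_i)) / (sum a + sum b)
#' over the union of the two species lists (absent species contribute 0).
#' The default abundance basis is the species IVI, the basis on which all
#' floristic and structural comparisons in this package rest; percentage
#' cover is available for sensitivity analyses.
#'
#' @param p,q `community_profile` objects.
#' @param basis `"ivi"` (default) or `"cover"`.
#' @return A number in [0, 1]; 0 for identical profiles, 1 for disjoint
#'   species sets. `NA` when both profiles are empty.
#' @export
sorensen_distance <- function(p, q, basis = c("ivi", "cover")) {
  basis <- match.arg(basis)
  a <- profile_abundance(p, basis)
  b <- profile_abundance(q, basis)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  if (length(a) == 0 || length(b) == 0) return(1)
  m <- union_matrix(a, b)
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Simpson beta dissimilarity between two visits
#'
#' Presence-absence dissimilarity min(b, c) / (min(b, c) + a), where a is
#' the number of shared species and b, c the numbers unique to each visit.
#' By taking the smaller unique count it discounts pure richness
#' differences: nested species sets score 0.
#'
#' @param p,q `community_profile` objects (at least one non-empty).
#' @return A number in [0, 1]; `NA` when both profiles are empty.
#' @export
simpson_beta <- function(p, q) {
  sa <- p$species$species_code
  sb <- q$species$species_code
  if (length(sa) == 0 && length(sb) == 0) return(NA_real_)
  a <- length(intersect(sa, sb))
  b <- length(setdiff(sa, sb))
  cc <- length(setdiff(sb, sa))
  m <- min(b, cc)
  if (m + a == 0) return(NA_real_)
  m / (m + a)
}

#' Whittaker beta diversity of a set of profiles
#'
#' beta_W = gamma / mean(alpha): pooled species richness over the profiles
#' divided by their mean richness. 1 when all profiles share the same
#' species list; the number of profiles when all lists are disjoint.
#'
#' @param profiles A list of `community_profile` objects.
#' @return A number >= 1, or `NA` if all profiles are empty.
#' @export
whittaker_beta <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  richness <- vapply(profiles, function(p) nrow(p$species), 0L)
  if (all(richness == 0)) return(NA_real_)
  gamma <- length(unique(unlist(lapply(profiles,
                                       function(p) p$species$species_code))))
  gamma / mean(richness)
}

#' Compositional turnover expressed as half-changes
#'
#' Converts a mean Sorensen similarity (1 - mean Sorensen distance) among a
#' set of profiles into the number of compositional half-changes:
#' HC = ln(similarity) / ln(0.5). One half-change means similarity has
#' fallen to 50%.
#'
#' @param mean_similarity Mean similarity in (0, 1].
#' @return A number >= 0; `NA` for similarity <= 0 (complete turnover).
#' @export
half_changes <- function(mean_similarity) {
  if (is.na(mean_similarity) || mean_similarity <= 0) return(NA_real_)
  stopifnot(mean_similarity <= 1)
  log(mean_similarity) / log(0.5)
}

#' Profile every visit in a dataset
#'
#' @param dataset A [survey_dataset()].
#' @return A named list of `community_profile` objects, keyed
#'   `"plot_id/visit_id"`, in canonical visit order.
#' @export
profile_all_visits <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  vis <- dataset$visits
  out <- vector("list", nrow(vis))
  names(out) <- paste(vis$plot_id, vis$visit_id, sep = "/")
  for (i in seq_len(nrow(vis))) {
    out[[i]] <- compute_profile(dataset, vis$plot_id[i], vis$visit_id[i])
  }
  out
}

#' Flatten a list of profiles into one species table
#'
#' @param profiles A list of `community_profile` objects (e.g. from
#'   [profile_all_visits()]).
#' @return A tibble with one row per (visit, species).
#' @export
profiles_to_table <- function(profiles) {
  dplyr::bind_rows(lapply(profiles, function(p) {
    if (nrow(p$species) == 0) return(NULL)
    dplyr::mutate(p$species, plot_id = p$plot_id, visit_id = p$visit_id,
                  .before = 1)
  }))
}
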