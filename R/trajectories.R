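#' Map a Major Vegetation Group label to its streamlined group and physiognomy
#'
#' Grassland MVGs (Hummock, Tussock) form the herbaceous streamlined group
#' "Grasslands"; shrubland MVGs (Acacia, Chenopod and other shrublands) and
#' woodland MVGs (Eucalypt, Mallee) are wooded, streamlined to "Shrublands"
#' and "Woodlands". Matching is on the trailing word of the label, so
#' "Other Shrublands" resolves too; anything else is a mapping error.
#'
#' @param mvg_label Character vector of MVG names.
#' @return A tibble with columns `mvg_label`, `streamlined_group`
#'   (Grasslands/Shrublands/Woodlands) and `physiognomy`
#'   (herbaceous/wooded), one row per input element.
#' @export
assign_groups <- function(mvg_label) {
  lab <- as.character(mvg_label)
  tail_word <- tolower(sub("^.*\\s", "", trimws(lab)))
  streamlined <- dplyr::case_when(
    tail_word == "grasslands" ~ "Grasslands",
    tail_word == "shrublands" ~ "Shrublands",
    tail_word == "woodlands" ~ "Woodlands",
    TRUE ~ NA_character_)
  if (anyNA(streamlined)) {
    abort(paste0("unrecognised MVG label(s): ",
                 paste(unique(lab[is.na(streamlined)]), collapse = ", "),
                 "; labels must end in Grasslands, Shrublands or Woodlands"),
          class = "vegshift_mapping_error")
  }
  tibble::tibble(mvg_label = lab, streamlined_group = streamlined,
                 physiognomy = ifelse(streamlined == "Grasslands",
                                      "herbaceous", "wooded"))
}

#' Dissimilarity of every revisit to its plot's baseline survey
#'
#' Pairs each revisit with its baseline ([pair_revisits()]), computes the
#' chosen dissimilarity between the two visits' community (or growth-form)
#' profiles, and attaches the vegetation-group labels of the baseline visit.
#' These records are the raw material for the dissimilarity-versus-interval
#' regressions and the annualised turnover statistics.
#'
#' @param dataset A [survey_dataset()].
#' @param metric `"sorensen"` (abundance-based Bray-Curtis, default),
#'   `"simpson_beta"` (presence-absence, richness-difference-insensitive),
#'   or `"growth_form_sorensen"` (Bray-Curtis on growth-form IVI spectra).
#' @param basis Abundance basis for Sorensen metrics: `"ivi"` or `"cover"`.
#' @param mode Revisit pairing mode, see [pair_revisits()].
#' @return A tibble: `plot_id`, `baseline_visit`, `revisit`,
#'   `interval_years`, `metric`, `distance`, `mvg_label`,
#'   `streamlined_group`, `physiognomy`.
#' @export
baseline_dissimilarities <- function(dataset,
                                     metric = c("sorensen", "simpson_beta",
                                                "growth_form_sorensen"),
                                     basis = c("ivi", "cover"),
                                     mode = c("baseline_to_each",
                                              "first_to_last")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  metric <- match.arg(metric)
  basis <- match.arg(basis)
  mode <- match.arg(mode)
  pairs <- pair_revisits(dataset, mode)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(plot_id = character(), baseline_visit = character(),
                          revisit = character(), interval_years = numeric(),
                          metric = character(), distance = numeric(),
                          mvg_label = character(),
                          streamlined_group = character(),
                          physiognomy = character()))
  }
  needed <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(plot_id = pairs$plot_id, visit_id = pairs$baseline_visit),
    tibble::tibble(plot_id = pairs$plot_id, visit_id = pairs$revisit)))
  profiler <- if (metric == "growth_form_sorensen") growth_form_profile else compute_profile
  prof <- lapply(seq_len(nrow(needed)), function(i) {
    profiler(dataset, needed$plot_id[i], needed$visit_id[i])
  })
  key <- function(p, v) match(paste(p, v, sep = "\r"),
                              paste(needed$plot_id, needed$visit_id, sep = "\r"))
  dist_fun <- switch(metric,
    sorensen = function(a, b) sorensen_distance(a, b, basis),
    simpson_beta = function(a, b) simpson_beta(a, b),
    growth_form_sorensen = function(a, b) structure_distance(a, b))
  distance <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- prof[[key(pairs$plot_id[i], pairs$baseline_visit[i])]]
    b <- prof[[key(pairs$plot_id[i], pairs$revisit[i])]]
    dist_fun(a, b)
  }, 0.0)

  baseline_mvg <- dataset$visits$mvg_label[
    match(paste(pairs$plot_id, pairs$baseline_visit),
          paste(dataset$visits$plot_id, dataset$visits$visit_id))]
  groups <- assign_groups(baseline_mvg)
  tibble::tibble(
    plot_id = pairs$plot_id, baseline_visit = pairs$baseline_visit,
    revisit = pairs$revisit, interval_years = pairs$interval_years,
    metric = metric, distance = distance, mvg_label = groups$mvg_label,
    streamlined_group = groups$streamlined_group,
    physiognomy = groups$physiognomy)
}

#' Regress dissimilarity on survey interval, per vegetation group
#'
#' Ordinary least squares of `distance` on `interval_years`, fitted
#' separately within each level of a grouping column. Each revisit record is
#' one observation. The slope is the per-year rate at which composition
#' moves away from baseline; R-squared measures how linear that trajectory
#' is.
#'
#' @param records A tibble of dissimilarity records (e.g. from
#'   [baseline_dissimilarities()]).
#' @param group_by Name of the grouping column (`"streamlined_group"`,
#'   `"physiognomy"`, `"mvg_label"`, ...). Use `NULL` for a single pooled
#'   fit.
#' @param x,y Names of the predictor and response columns (defaults
#'   `interval_years`, `distance`).
#' @return A tibble: `group`, `n`, `slope`, `intercept`, `r_squared`.
#'   A group with fewer than 2 records or without 2 distinct predictor
#'   values is a degenerate design and raises an error naming the group.
#' @export
fit_trajectory <- function(records, group_by = "streamlined_group",
                           x = "interval_years", y = "distance") {
  records <- tibble::as_tibble(records)
  grp <- if (is.null(group_by)) rep("all", nrow(records)) else records[[group_by]]
  out <- lapply(unique(grp), function(g) {
    d <- records[grp == g, ]
    xs <- d[[x]]
    ys <- d[[y]]
    if (length(xs) < 2 || length(unique(xs)) < 2) {
      abort(paste0("degenerate regression design for group '", g,
                   "': need >= 2 records with >= 2 distinct ", x, " values"),
            class = "vegshift_fit_error")
    }
    fit <- lm(ys ~ xs)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((ys - mean(ys))^2)
    tibble::tibble(group = g, n = length(xs),
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$group)
}

#' Annualised compositional shift rates
#'
#' Divides each baseline-to-revisit dissimilarity by its interval in years,
#' keeping only revisits separated from baseline by more than
#' `min_interval_years` (default 4 — the lapse regarded as long enough for
#' shifts to become evident; the inequality is strict on fractional years).
#'
#' @param records A tibble from [baseline_dissimilarities()].
#' @param min_interval_years Strict lower bound on the interval (set 0 to
#'   keep everything).
#' @return The qualifying records with an added `rate = distance /
#'   interval_years` column (per year).
#' @export
annualized_shifts <- function(records, min_interval_years = 4) {
  records <- tibble::as_tibble(records)
  records |>
    dplyr::filter(.data$interval_years > min_interval_years) |>
    dplyr::mutate(rate = .data$distance / .data$interval_years)
}

#' One-way analysis of variance with per-group summaries
#'
#' Standard fixed-effects one-way ANOVA (F = MS_between / MS_within, with
#' k - 1 and N - k degrees of freedom) of a numeric response across the
#' levels of a grouping column, plus per-group n, mean and standard error
#' (SD / sqrt(n)).
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return An object of class `vegshift_anova`: a list with `grouping`,
#'   `k`, `f`, `df_between`, `df_within`, `p_value` and a `groups` tibble
#'   (`group`, `n`, `mean`, `se`). Requires >= 2 groups, each with >= 2
#'   values; otherwise an error naming the offending group.
#' @export
oneway_anova <- function(data, value = "rate", group = "mvg_label") {
  data <- tibble::as_tibble(data)
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  counts <- table(g)
  if (length(counts) < 2) {
    abort("one-way ANOVA needs at least 2 groups",
          class = "vegshift_anova_error")
  }
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(paste0("group(s) with fewer than 2 values: ",
                 paste(small, collapse = ", ")),
          class = "vegshift_anova_error")
  }
  tab <- anova(lm(v ~ factor(g)))
  stats_tbl <- tibble::tibble(group = names(counts)) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(g == .data$group),
                  mean = mean(v[g == .data$group]),
                  se = sd(v[g == .data$group]) / sqrt(.data$n)) |>
    dplyr::ungroup()
  structure(list(grouping = group, k = length(counts),
                 f = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1], groups = stats_tbl),
            class = "vegshift_anova")
}

#' @export
print.vegshift_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA by %s: F(%d,%d) = %.3f, P = %.4g\n",
              x$grouping, x$df_between, x$df_within, x$f, x$p_value))
  print(x$groups)
  invisible(x)
}

#' All pairwise one-way ANOVAs between group levels
#'
#' Runs [oneway_anova()] on every pair of group levels with at least 2
#' values each. No multiplicity correction is applied (the output is
#' labelled accordingly); treat the p-values as descriptive follow-ups to a
#' significant global test.
#'
#' @inheritParams oneway_anova
#' @return A tibble: `group_a`, `group_b`, `n_a`, `n_b`, `f`, `df1`, `df2`,
#'   `p_value`, `correction` (always `"uncorrected"`).
#' @export
pairwise_anova <- function(data, value = "rate", group = "mvg_label") {
  data <- tibble::as_tibble(data)
  g <- as.character(data[[group]])
  levels <- names(which(table(g) >= 2))
  if (length(levels) < 2) {
    return(tibble::tibble(group_a = character(), group_b = character(),
                          n_a = integer(), n_b = integer(), f = numeric(),
                          df1 = integer(), df2 = integer(),
                          p_value = numeric(), correction = character()))
  }
  combos <- utils::combn(sort(levels), 2)
  out <- lapply(seq_len(ncol(combos)), function(i) {
    pair <- combos[, i]
    res <- oneway_anova(data[g %in% pair, ], value, group)
    tibble::tibble(group_a = pair[1], group_b = pair[2],
                   n_a = res$groups$n[res$groups$group == pair[1]],
                   n_b = res$groups$n[res$groups$group == pair[2]],
                   f = res$f, df1 = res$df_between, df2 = res$df_within,
                   p_value = res$p_value, correction = "uncorrected")
  })
  dplyr::bind_rows(out)
}
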