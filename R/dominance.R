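#' Rank-abundance (Whittaker) curve of a visit
#'
#' Species sorted by decreasing abundance, rank 1 the most abundant. Ties
#' are broken by species code (lexicographic), so the curve is a
#' deterministic function of the profile regardless of input row order.
#'
#' @param profile A `community_profile` with at least one species.
#' @param basis `"ivi"` (default) or `"cover"`.
#' @return A tibble: `plot_id`, `visit_id`, `rank`, `species_code`,
#'   `abundance`.
#' @export
rank_abundance <- function(profile, basis = c("ivi", "cover")) {
  stopifnot(inherits(profile, "community_profile"))
  ab <- profile_abundance(profile, basis)
  if (length(ab) == 0) abort("cannot rank an empty profile")
  ord <- order(-ab, names(ab))
  tibble::tibble(plot_id = profile$plot_id, visit_id = profile$visit_id,
                 rank = seq_along(ab), species_code = names(ab)[ord],
                 abundance = unname(ab[ord]))
}

#' Fit a lognormal species abundance distribution
#'
#' Maximum-likelihood lognormal fit to the observed species abundances of a
#' visit: `mu` is the mean of the natural-log abundances and `sigma` their
#' ML standard deviation (divisor n). Sigma is the dominance shape
#' parameter: low sigma means abundance is concentrated in few species
#' (strong dominance), high sigma a more even spread of log-abundances.
#' Because sigma is a function of log-ratios it is identical whichever
#' abundance currency is used — IVI, percentage cover, relative cover or
#' raw intercept counts all give the same value (mu shifts by the log of
#' the scale factor).
#'
#' Only observed species enter the fit: no correction is attempted for rare
#' species hidden behind the sampling veil line.
#'
#' @param profile A `community_profile` with >= 2 species.
#' @param basis `"ivi"` (default) or `"cover"`.
#' @return An object of class `sad_fit`: `plot_id`, `visit_id`,
#'   `n_species`, `mu`, `sigma`, `basis`.
#' @export
fit_lognormal_sad <- function(profile, basis = c("ivi", "cover")) {
  stopifnot(inherits(profile, "community_profile"))
  basis <- match.arg(basis)
  ab <- profile_abundance(profile, basis)
  if (length(ab) < 2) {
    abort(paste0("lognormal SAD fit needs >= 2 species (",
                 profile$plot_id, "/", profile$visit_id, " has ",
                 length(ab), ")"), class = "vegshift_fit_error")
  }
  la <- log(ab)
  mu <- mean(la)
  sigma <- sqrt(mean((la - mu)^2))
  structure(list(plot_id = profile$plot_id, visit_id = profile$visit_id,
                 n_species = length(ab), mu = mu, sigma = sigma,
                 basis = basis),
            class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("<sad_fit> %s/%s: n = %d, mu = %.3f, sigma = %.3f (%s basis)\n",
              x$plot_id, x$visit_id, x$n_species, x$mu, x$sigma, x$basis))
  invisible(x)
}

#' Classify the dominance shift of a plot between two visits
#'
#' Compares the lognormal sigma of the first and last visit of a plot. A
#' lower sigma at the last visit means abundance became more concentrated —
#' increased dominance; a higher sigma means decreased dominance. A
#' tolerance band around zero (default 0) maps small changes to
#' `"unchanged"`.
#'
#' @param first,last `sad_fit` objects for the same plot, `first` from the
#'   earlier visit.
#' @param tol Non-negative half-width of the unchanged band on
#'   `delta_sigma`.
#' @return A one-row tibble: `plot_id`, `sigma_first`, `sigma_last`,
#'   `delta_sigma` (last - first), `direction`
#'   (increased_dominance/decreased_dominance/unchanged).
#' @export
classify_dominance_shift <- function(first, last, tol = 0) {
  stopifnot(inherits(first, "sad_fit"), inherits(last, "sad_fit"), tol >= 0)
  if (!identical(first$plot_id, last$plot_id)) {
    abort(paste0("sad fits are for different plots: ", first$plot_id,
                 " vs ", last$plot_id))
  }
  delta <- last$sigma - first$sigma
  direction <- if (delta < -tol) "increased_dominance"
    else if (delta > tol) "decreased_dominance" else "unchanged"
  tibble::tibble(plot_id = first$plot_id, sigma_first = first$sigma,
                 sigma_last = last$sigma, delta_sigma = delta,
                 direction = direction)
}

#' First-to-last dominance shifts for every repeat plot
#'
#' Fits the lognormal SAD at the earliest and latest visit of every plot
#' with >= 2 visits (skipping visits with < 2 species, which cannot be
#' fitted) and classifies the shift.
#'
#' @param dataset A [survey_dataset()].
#' @param basis `"ivi"` (default) or `"cover"`.
#' @param tol Unchanged band, see [classify_dominance_shift()].
#' @return A tibble with one row per classifiable repeat plot: shift columns
#'   plus `interval_years` and `mvg_label`.
#' @export
dominance_shifts <- function(dataset, basis = c("ivi", "cover"), tol = 0) {
  stopifnot(inherits(dataset, "survey_dataset"))
  basis <- match.arg(basis)
  pairs <- pair_revisits(dataset, "first_to_last")
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p1 <- compute_profile(dataset, pairs$plot_id[i], pairs$baseline_visit[i])
    p2 <- compute_profile(dataset, pairs$plot_id[i], pairs$revisit[i])
    if (nrow(p1$species) < 2 || nrow(p2$species) < 2) return(NULL)
    shift <- classify_dominance_shift(fit_lognormal_sad(p1, basis),
                                      fit_lognormal_sad(p2, basis), tol)
    shift$interval_years <- pairs$interval_years[i]
    shift
  })
  shifts <- dplyr::bind_rows(out)
  if (nrow(shifts) == 0) {
    return(tibble::tibble(plot_id = character(), sigma_first = numeric(),
                          sigma_last = numeric(), delta_sigma = numeric(),
                          direction = character(), interval_years = numeric(),
                          mvg_label = character()))
  }
  vis <- dataset$visits
  base_idx <- match(paste(pairs$plot_id, pairs$baseline_visit),
                    paste(vis$plot_id, vis$visit_id))
  mvg <- setNames(vis$mvg_label[base_idx], pairs$plot_id)
  shifts$mvg_label <- unname(mvg[shifts$plot_id])
  shifts
}

#' Summarise dominance shifts per vegetation group
#'
#' For each group: counts of plots with increased, decreased and unchanged
#' dominance; mean and standard error of |delta sigma| within each of the
#' two shifted classes; and, where both classes hold >= 2 plots, a one-way
#' ANOVA of |delta sigma| between them.
#'
#' @param shifts A tibble from [dominance_shifts()] (columns `delta_sigma`,
#'   `direction`, and the grouping column).
#' @param group_by Name of the grouping column (default `"mvg_label"`).
#' @return A tibble with one row per group: `n_increased`, `n_decreased`,
#'   `n_unchanged`, `mean_abs_delta_increased`, `se_increased`,
#'   `mean_abs_delta_decreased`, `se_decreased`, `anova_f`, `anova_p`
#'   (`NA` where the ANOVA is not estimable).
#' @export
summarize_dominance <- function(shifts, group_by = "mvg_label") {
  shifts <- tibble::as_tibble(shifts)
  grp_col <- shifts[[group_by]]
  out <- lapply(sort(unique(grp_col)), function(g) {
    d <- shifts[grp_col == g, ]
    inc <- abs(d$delta_sigma[d$direction == "increased_dominance"])
    dec <- abs(d$delta_sigma[d$direction == "decreased_dominance"])
    mean_se <- function(x) {
      if (length(x) == 0) return(c(NA_real_, NA_real_))
      c(mean(x), if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_)
    }
    mi <- mean_se(inc)
    md <- mean_se(dec)
    af <- ap <- NA_real_
    if (length(inc) >= 2 && length(dec) >= 2) {
      an <- oneway_anova(
        tibble::tibble(value = c(inc, dec),
                       class = rep(c("increased", "decreased"),
                                   c(length(inc), length(dec)))),
        value = "value", group = "class")
      af <- an$f
      ap <- an$p_value
    }
    tibble::tibble(group = g,
                   n_increased = length(inc), n_decreased = length(dec),
                   n_unchanged = sum(d$direction == "unchanged"),
                   mean_abs_delta_increased = mi[1], se_increased = mi[2],
                   mean_abs_delta_decreased = md[1], se_decreased = md[2],
                   anova_f = af, anova_p = ap)
  })
  dplyr::bind_rows(out)
}
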