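#' Configure a synthetic repeat-visit survey campaign
#'
#' Defines the study conditions for the simulator: how many plots of each
#' Major Vegetation Group (MVG) to lay out, the community structure of each
#' group (species richness, lognormal species-abundance shape `sad_sigma`,
#' bare-ground fraction), and the temporal dynamics (per-year species
#' turnover, abundance drift, optional monotone bare-fraction trend, visit
#' schedule). Defaults emulate an arid-to-Mediterranean rangeland campaign:
#' herbaceous groups (Hummock/Tussock Grasslands) turn over at 0.10/yr,
#' woody groups (Shrublands/Woodlands) at 0.05/yr — a two-fold contrast —
#' with visits at roughly 0, 3 and 6 years.
#'
#' @param groups A data frame with one row per vegetation group and columns
#'   `group`, `n_plots`, `richness`, `sad_sigma`, `bare_fraction`,
#'   `turnover_rate`, `bare_trend` (per-year additive change in bare
#'   fraction). Defaults to [default_sim_groups()].
#' @param drift_sd Lognormal abundance drift of surviving species, on the
#'   log scale per square-root year (default 0.10).
#' @param visit_schedule Strictly increasing visit offsets in years,
#'   starting at 0.
#' @param schedule_jitter_years Half-width of the uniform jitter applied to
#'   non-baseline offsets, emulating uneven revisit logistics (default 0.75).
#' @param pool_multiplier Regional pool size as a multiple of plot richness
#'   (default 3); the unused part of the pool supplies replacement species.
#' @param start_date Calendar date of the baseline visits.
#' @param seed Integer seed; the whole campaign is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(groups = default_sim_groups(),
                              drift_sd = 0.10,
                              visit_schedule = c(0, 3, 6),
                              schedule_jitter_years = 0.75,
                              pool_multiplier = 3,
                              start_date = as.Date("2012-04-01"),
                              seed = 1L) {
  groups <- tibble::as_tibble(groups)
  need <- c("group", "n_plots", "richness", "sad_sigma", "bare_fraction",
            "turnover_rate")
  miss <- setdiff(need, names(groups))
  if (length(miss) > 0) {
    abort(paste0("groups is missing column(s): ", paste(miss, collapse = ", ")),
          class = "vegshift_config_error")
  }
  if (!"bare_trend" %in% names(groups)) groups$bare_trend <- 0
  stopifnot(all(groups$n_plots >= 1), all(groups$richness >= 1),
            all(groups$sad_sigma >= 0),
            all(groups$bare_fraction >= 0 & groups$bare_fraction <= 1),
            all(groups$turnover_rate >= 0 & groups$turnover_rate <= 1),
            drift_sd >= 0, schedule_jitter_years >= 0, pool_multiplier >= 1)
  if (length(visit_schedule) < 1 || visit_schedule[1] != 0 ||
      is.unsorted(visit_schedule, strictly = TRUE)) {
    abort("visit_schedule must start at 0 and be strictly increasing",
          class = "vegshift_config_error")
  }
  structure(list(groups = groups, drift_sd = drift_sd,
                 visit_schedule = visit_schedule,
                 schedule_jitter_years = schedule_jitter_years,
                 pool_multiplier = pool_multiplier,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default vegetation-group parameters for the simulator
#'
#' Six Major Vegetation Groups spanning the herbaceous/woody contrast.
#' Richness, dominance concentration (`sad_sigma`), and bare-ground fraction
#' grade from sparse, strongly dominated hummock grasslands to richer, more
#' vegetated eucalypt woodlands; herbaceous groups turn over twice as fast
#' as woody ones.
#'
#' @return A tibble with one row per group.
#' @export
default_sim_groups <- function() {
  tibble::tribble(
    ~group,                ~n_plots, ~richness, ~sad_sigma, ~bare_fraction, ~turnover_rate,
    "Hummock Grasslands",        5L,       25L,        1.5,           0.55,           0.10,
    "Tussock Grasslands",        7L,       35L,        1.2,           0.45,           0.10,
    "Acacia Shrublands",        12L,       45L,        1.2,           0.40,           0.05,
    "Chenopod Shrublands",       8L,       35L,        1.1,           0.50,           0.05,
    "Eucalypt Woodlands",       28L,       60L,        1.2,           0.25,           0.05,
    "Mallee Woodlands",         13L,       50L,        1.2,           0.30,           0.05) |>
    dplyr::mutate(bare_trend = 0)
}

#' Default growth-form composition of each simulated vegetation group
#'
#' Raw field growth-form labels (as a surveyor would record them) with the
#' probability that a pool species belongs to each, per group.
#'
#' @param group A group name from [default_sim_groups()].
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_growth_form_mix <- function(group) {
  mixes <- list(
    "Hummock Grasslands" = c("Hummock grass" = 0.35, "Forb" = 0.35,
                             "Shrub" = 0.15, "Tussock grass" = 0.10,
                             "Chenopod" = 0.05),
    "Tussock Grasslands" = c("Tussock grass" = 0.40, "Forb" = 0.40,
                             "Shrub" = 0.10, "Sedge" = 0.05, "Rush" = 0.05),
    "Acacia Shrublands" = c("Acacia Shrub" = 0.30, "Shrub" = 0.15,
                            "Forb" = 0.25, "Tussock grass" = 0.15,
                            "Tree" = 0.05, "Chenopod" = 0.10),
    "Chenopod Shrublands" = c("Chenopod" = 0.45, "Forb" = 0.25,
                              "Shrub" = 0.15, "Tussock grass" = 0.10,
                              "Vine" = 0.05),
    "Eucalypt Woodlands" = c("Tree" = 0.15, "Shrub" = 0.35, "Forb" = 0.25,
                             "Tussock grass" = 0.10, "Sedge" = 0.10,
                             "Fern" = 0.05),
    "Mallee Woodlands" = c("Tree Mallee" = 0.20, "Shrub Mallee" = 0.20,
                           "Shrub" = 0.20, "Forb" = 0.20,
                           "Tussock grass" = 0.10, "Chenopod" = 0.10))
  if (!group %in% names(mixes)) {
    abort(paste0("no default growth-form mix for group '", group,
                 "'; known: ", paste(names(mixes), collapse = ", ")),
          class = "vegshift_config_error")
  }
  mixes[[group]]
}

#' Draw a community with lognormal species abundance structure
#'
#' Builds a regional species pool, assigns each pool species a growth form
#' multinomially, seats the first `richness` pool members in the community,
#' and draws their relative abundances as exp(N(0, sad_sigma^2)) normalised
#' to sum to 1 — the lognormal species abundance distribution whose shape
#' parameter sigma the dominance analyses later recover.
#'
#' Uses R's global RNG stream; seed it (or call via [generate_dataset()])
#' for reproducibility.
#'
#' @param richness Number of species present (>= 1).
#' @param sad_sigma Lognormal shape parameter (>= 0; 0 gives a perfectly
#'   even community).
#' @param growth_form_mix Named numeric vector of raw growth-form label
#'   proportions, summing to 1.
#' @param bare_fraction Probability that a point intercept hits bare ground.
#' @param pool_size Regional pool size (default 3x richness).
#' @param prefix Species-code prefix, used to keep pools of different plots
#'   distinct.
#' @return An object of class `community_state`: abundances (named, sum 1),
#'   `bare_fraction`, `growth_form` map over the pool, the ordered `pool`,
#'   and the generating `sad_sigma` (used when replacement species are drawn).
#' @export
generate_community <- function(richness, sad_sigma, growth_form_mix,
                               bare_fraction = 0.3,
                               pool_size = 3 * richness, prefix = "SP") {
  stopifnot(richness >= 1, sad_sigma >= 0, pool_size >= richness,
            bare_fraction >= 0, bare_fraction <= 1)
  if (abs(sum(growth_form_mix) - 1) > 1e-8) {
    abort("growth_form_mix proportions must sum to 1",
          class = "vegshift_config_error")
  }
  pool <- sprintf("%s%04d", prefix, seq_len(pool_size))
  gf <- setNames(sample(names(growth_form_mix), pool_size, replace = TRUE,
                        prob = growth_form_mix), pool)
  present <- pool[seq_len(richness)]
  biomass <- setNames(exp(rnorm(richness, 0, sad_sigma)), present)
  structure(list(abundance = biomass / sum(biomass), biomass = biomass,
                 bare_fraction = bare_fraction,
                 growth_form = gf, pool = pool, sad_sigma = sad_sigma),
            class = "community_state")
}

#' Advance a community through time
#'
#' Species turnover is modelled as geometric per-year replacement: over
#' `years` each species is independently swapped for an unused pool species
#' with probability 1 - (1 - turnover_rate)^years, the incomer receiving a
#' fresh lognormal abundance. Surviving species drift: abundances are
#' multiplied by exp(N(0, years * drift_sd^2)). Abundances are renormalised;
#' richness is stationary. The bare fraction changes only through
#' `bare_trend` (per-year additive, clamped to [0, 1]).
#'
#' @param state A `community_state`.
#' @param years Elapsed time (>= 0).
#' @param turnover_rate Per-year replacement probability in [0, 1].
#' @param drift_sd Log-scale drift per square-root year (>= 0).
#' @param bare_trend Per-year additive change in bare fraction (default 0).
#' @return The evolved `community_state`.
#' @export
evolve_community <- function(state, years, turnover_rate, drift_sd,
                             bare_trend = 0) {
  stopifnot(inherits(state, "community_state"), years >= 0,
            turnover_rate >= 0, turnover_rate <= 1, drift_sd >= 0)
  bm <- state$biomass
  if (years == 0 || (turnover_rate == 0 && drift_sd == 0 && bare_trend == 0)) {
    if (years > 0 && bare_trend != 0) {
      state$bare_fraction <- min(1, max(0, state$bare_fraction + years * bare_trend))
    }
    return(state)
  }
  p_replace <- 1 - (1 - turnover_rate)^years
  replaced <- runif(length(bm)) < p_replace
  if (any(replaced)) {
    unused <- setdiff(state$pool, names(bm))
    n_new <- min(sum(replaced), length(unused))
    incoming <- if (n_new > 0) sample(unused, n_new) else character()
    # if the pool is exhausted, the excess species simply persist
    drop_idx <- which(replaced)[seq_len(n_new)]
    survivors <- if (n_new > 0) bm[-drop_idx] else bm
    if (drift_sd > 0 && length(survivors) > 0) {
      survivors <- survivors * exp(rnorm(length(survivors), 0,
                                         sqrt(years) * drift_sd))
    }
    # incomers draw a fresh biomass from the same lognormal as the baseline
    # community, so they enter on the scale of a typical resident species
    new_bm <- exp(rnorm(n_new, 0, state$sad_sigma))
    bm <- c(survivors, setNames(new_bm, incoming))
  } else if (drift_sd > 0) {
    bm <- bm * exp(rnorm(length(bm), 0, sqrt(years) * drift_sd))
  }
  state$biomass <- bm
  state$abundance <- bm / sum(bm)
  state$bare_fraction <- min(1, max(0, state$bare_fraction + years * bare_trend))
  state
}

#' Simulate one point-intercept survey of a community
#'
#' Visits each of the 1010 point-intercept slots (10 transects x 101 metre
#' marks): with probability `bare_fraction` the point hits bare ground,
#' otherwise it hits one species drawn from the community's relative
#' abundances (one hit per point; no canopy layering).
#'
#' @param state A `community_state`.
#' @param plot_id,visit_id Identifiers stamped on the records.
#' @return A tibble of intercept records in the [survey_dataset()] layout.
#' @export
sample_visit <- function(state, plot_id, visit_id) {
  stopifnot(inherits(state, "community_state"))
  n <- POINTS_PER_PLOT
  transect <- rep(seq_len(N_TRANSECTS), each = POINTS_PER_TRANSECT)
  point <- rep(0:(POINTS_PER_TRANSECT - 1L), times = N_TRANSECTS)
  bare <- runif(n) < state$bare_fraction
  species <- character(n)
  gf <- character(n)
  if (any(!bare)) {
    species[!bare] <- sample(names(state$abundance), sum(!bare),
                             replace = TRUE, prob = state$abundance)
    gf[!bare] <- unname(state$growth_form[species[!bare]])
  }
  tibble::tibble(
    plot_id = plot_id, visit_id = visit_id,
    transect = as.integer(transect), point = as.integer(point),
    hit_kind = ifelse(bare, "bare_soil", "species"),
    species_code = species, growth_form = gf)
}

#' Generate a full repeat-visit survey campaign with known ground truth
#'
#' Lays out `n_plots` plots per vegetation group, draws each plot's baseline
#' community, evolves it along the (jittered) visit schedule, and samples a
#' 1010-point survey at every visit. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (a validated [survey_dataset()])
#'   and `ground_truth` (tibble of the generating parameters per plot:
#'   group, richness, sad_sigma, bare_fraction, turnover_rate, drift_sd,
#'   bare_trend, seed).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  rec_list <- list()
  vis_list <- list()
  gt_list <- list()
  plot_no <- 0L
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    mix <- default_growth_form_mix(grp$group)
    for (k in seq_len(grp$n_plots)) {
      plot_no <- plot_no + 1L
      plot_id <- sprintf("PLOT%03d", plot_no)
      offsets <- config$visit_schedule
      if (length(offsets) > 1 && config$schedule_jitter_years > 0) {
        jit <- runif(length(offsets) - 1, -config$schedule_jitter_years,
                     config$schedule_jitter_years)
        offsets[-1] <- pmax(offsets[-1] + jit, 0.1)
        offsets <- sort(offsets)
      }
      state <- generate_community(
        richness = grp$richness, sad_sigma = grp$sad_sigma,
        growth_form_mix = mix, bare_fraction = grp$bare_fraction,
        pool_size = ceiling(config$pool_multiplier * grp$richness),
        prefix = sprintf("P%03dS", plot_no))
      for (v in seq_along(offsets)) {
        if (v > 1) {
          state <- evolve_community(state, offsets[v] - offsets[v - 1],
                                    turnover_rate = grp$turnover_rate,
                                    drift_sd = config$drift_sd,
                                    bare_trend = grp$bare_trend)
        }
        visit_id <- sprintf("%s-V%d", plot_id, v)
        visit_date <- config$start_date + round(offsets[v] * DAYS_PER_YEAR)
        rec_list[[length(rec_list) + 1]] <-
          sample_visit(state, plot_id, visit_id)
        vis_list[[length(vis_list) + 1]] <- tibble::tibble(
          plot_id = plot_id, visit_id = visit_id, visit_date = visit_date,
          mvg_label = grp$group, notes = "")
      }
      gt_list[[length(gt_list) + 1]] <- tibble::tibble(
        plot_id = plot_id, group = grp$group, richness = grp$richness,
        sad_sigma = grp$sad_sigma, bare_fraction = grp$bare_fraction,
        turnover_rate = grp$turnover_rate, drift_sd = config$drift_sd,
        bare_trend = grp$bare_trend, seed = config$seed)
    }
  }
  dataset <- survey_dataset(dplyr::bind_rows(rec_list),
                            dplyr::bind_rows(vis_list))
  list(dataset = dataset, ground_truth = dplyr::bind_rows(gt_list))
}
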