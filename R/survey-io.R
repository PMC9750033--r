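#' Construct a repeat-visit point-intercept survey dataset
#'
#' Bundles the two tables that describe a point-intercept monitoring campaign:
#' one row per intercept hit (`records`) and one row per plot visit
#' (`visits`). Every downstream computation in the package starts from this
#' container.
#'
#' @param records A data frame with columns `plot_id`, `visit_id`,
#'   `transect` (integer 1-10), `point` (integer 0-100, the metre mark),
#'   `hit_kind` (`"species"`, `"bare_soil"` or `"non_vascular_other"`),
#'   `species_code` (non-empty iff `hit_kind == "species"`) and
#'   `growth_form` (raw field growth-form label, non-empty iff a species hit).
#' @param visits A data frame with columns `plot_id`, `visit_id`,
#'   `visit_date` (`Date` or ISO-8601 string), `mvg_label` (Major Vegetation
#'   Group name, e.g. `"Acacia Shrublands"`) and optionally `notes`.
#' @param points_per_plot Number of point-intercept slots per visit
#'   (default 1010 = 10 transects x 101 points).
#' @param strict If `TRUE` (default), abort when [validate_dataset()] finds
#'   violations; if `FALSE`, return the dataset and leave checking to the
#'   caller.
#'
#' @return An object of class `survey_dataset`: a list with tibbles `records`
#'   and `visits` (canonically sorted) and the scalar `points_per_plot`.
#' @seealso [read_survey_table()], [validate_dataset()], [pair_revisits()]
#' @export
survey_dataset <- function(records, visits, points_per_plot = POINTS_PER_PLOT,
                           strict = TRUE) {
  records <- tibble::as_tibble(records)
  visits <- tibble::as_tibble(visits)

  req_rec <- c("plot_id", "visit_id", "transect", "point", "hit_kind",
               "species_code", "growth_form")
  req_vis <- c("plot_id", "visit_id", "visit_date", "mvg_label")
  miss <- setdiff(req_rec, names(records))
  if (length(miss) > 0) {
    abort(paste0("records is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "vegshift_format_error")
  }
  miss <- setdiff(req_vis, names(visits))
  if (length(miss) > 0) {
    abort(paste0("visits is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "vegshift_format_error")
  }
  if (!"notes" %in% names(visits)) visits$notes <- ""

  visits$visit_date <- parse_visit_date(visits$visit_date)
  records$plot_id <- as.character(records$plot_id)
  records$visit_id <- as.character(records$visit_id)
  records$transect <- as.integer(records$transect)
  records$point <- as.integer(records$point)
  records$species_code <- ifelse(is.na(records$species_code), "",
                                 as.character(records$species_code))
  records$growth_form <- ifelse(is.na(records$growth_form), "",
                                as.character(records$growth_form))
  visits$plot_id <- as.character(visits$plot_id)
  visits$visit_id <- as.character(visits$visit_id)
  visits$mvg_label <- as.character(visits$mvg_label)
  visits$notes <- ifelse(is.na(visits$notes), "", as.character(visits$notes))

  x <- structure(
    list(records = canonical_record_order(records[req_rec]),
         visits = canonical_visit_order(visits[c(req_vis, "notes")]),
         points_per_plot = as.integer(points_per_plot)),
    class = "survey_dataset")

  if (strict) {
    report <- validate_dataset(x)
    if (nrow(report) > 0) {
      abort(paste0("invalid survey dataset; first violations:\n",
                   paste(utils::head(format_violations(report), 5),
                         collapse = "\n")),
            class = "vegshift_integrity_error")
    }
  }
  x
}

parse_visit_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out)) {
    abort(paste0("visit_date not parseable as ISO-8601 (YYYY-MM-DD): ",
                 paste(unique(as.character(x)[is.na(out)]), collapse = ", ")),
          class = "vegshift_format_error")
  }
  out
}

canonical_record_order <- function(records) {
  dplyr::arrange(records, .data$plot_id, .data$visit_id, .data$transect,
                 .data$point, .data$hit_kind, .data$species_code)
}

canonical_visit_order <- function(visits) {
  dplyr::arrange(visits, .data$plot_id, .data$visit_date, .data$visit_id)
}

format_violations <- function(report) {
  paste0(report$rule, " [plot=", report$plot_id, " visit=", report$visit_id,
         "]: ", report$detail)
}

#' @export
print.survey_dataset <- function(x, ...) {
  n_plots <- length(unique(x$visits$plot_id))
  nv <- dplyr::count(x$visits, .data$plot_id)
  cat("<survey_dataset> ", n_plots, " plot(s), ", nrow(x$visits),
      " visit(s), ", nrow(x$records), " intercept record(s)\n", sep = "")
  cat("  repeat plots: ", sum(nv$n >= 2), "; points per plot: ",
      x$points_per_plot, "\n", sep = "")
  invisible(x)
}

#' Validate a survey dataset against the point-intercept data model
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data rather than raising them, so that a field dataset can
#' be audited in full.
#'
#' Rules checked: transect index in 1-10; point index in 0-100; recognised
#' hit kind; `species_code`/`growth_form` present exactly for species hits;
#' at most one substrate (non-species) hit per point; at most 1010 distinct
#' points per visit; every record referencing a known visit; unique
#' (plot, visit) metadata rows; no same-day duplicate visits of a plot.
#'
#' @param dataset A `survey_dataset` (built with `strict = FALSE` if you
#'   expect violations).
#' @return A tibble with columns `rule`, `plot_id`, `visit_id`, `detail`;
#'   zero rows iff the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  vis <- dataset$visits
  out <- list()
  bad <- function(rule, plot_id, visit_id, detail) {
    tibble::tibble(rule = rule, plot_id = as.character(plot_id),
                   visit_id = as.character(visit_id),
                   detail = as.character(detail))
  }

  i <- which(is.na(rec$transect) | rec$transect < 1 | rec$transect > N_TRANSECTS)
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("transect out of range", rec$plot_id[i],
                                  rec$visit_id[i],
                                  paste0("transect=", rec$transect[i]))
  }
  i <- which(is.na(rec$point) | rec$point < 0 | rec$point > POINTS_PER_TRANSECT - 1L)
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("point_index out of range", rec$plot_id[i],
                                  rec$visit_id[i], paste0("point=", rec$point[i]))
  }
  i <- which(!rec$hit_kind %in% HIT_KINDS)
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("unknown hit_kind", rec$plot_id[i],
                                  rec$visit_id[i], rec$hit_kind[i])
  }
  i <- which(rec$hit_kind == "species" & rec$species_code == "")
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("species hit without species_code",
                                  rec$plot_id[i], rec$visit_id[i],
                                  paste0("transect=", rec$transect[i],
                                         " point=", rec$point[i]))
  }
  i <- which(rec$hit_kind == "species" & rec$growth_form == "")
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("species hit without growth_form",
                                  rec$plot_id[i], rec$visit_id[i],
                                  rec$species_code[i])
  }
  i <- which(rec$hit_kind != "species" & rec$species_code != "")
  if (length(i) > 0) {
    out[[length(out) + 1]] <- bad("species_code on substrate hit",
                                  rec$plot_id[i], rec$visit_id[i],
                                  rec$species_code[i])
  }

  dup <- rec |>
    dplyr::filter(.data$hit_kind != "species") |>
    dplyr::count(.data$plot_id, .data$visit_id, .data$transect, .data$point) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    out[[length(out) + 1]] <- bad("duplicate substrate hit", dup$plot_id,
                                  dup$visit_id,
                                  paste0("transect=", dup$transect,
                                         " point=", dup$point, " (n=", dup$n, ")"))
  }

  npts <- rec |>
    dplyr::distinct(.data$plot_id, .data$visit_id, .data$transect, .data$point) |>
    dplyr::count(.data$plot_id, .data$visit_id) |>
    dplyr::filter(.data$n > dataset$points_per_plot)
  if (nrow(npts) > 0) {
    out[[length(out) + 1]] <- bad("too many points in visit", npts$plot_id,
                                  npts$visit_id,
                                  paste0(npts$n, " > ", dataset$points_per_plot))
  }

  known <- paste(vis$plot_id, vis$visit_id, sep = "\r")
  seen <- unique(paste(rec$plot_id, rec$visit_id, sep = "\r"))
  orphan <- setdiff(seen, known)
  if (length(orphan) > 0) {
    parts <- strsplit(orphan, "\r", fixed = TRUE)
    out[[length(out) + 1]] <- bad("record references unknown visit",
                                  vapply(parts, `[`, "", 1),
                                  vapply(parts, `[`, "", 2), "no metadata row")
  }

  dupv <- vis |> dplyr::count(.data$plot_id, .data$visit_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dupv) > 0) {
    out[[length(out) + 1]] <- bad("duplicate visit metadata", dupv$plot_id,
                                  dupv$visit_id, paste0("n=", dupv$n))
  }
  dupd <- vis |> dplyr::count(.data$plot_id, .data$visit_date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dupd) > 0) {
    out[[length(out) + 1]] <- bad("duplicate visit date for plot", dupd$plot_id,
                                  "", as.character(dupd$visit_date))
  }

  if (length(out) == 0) {
    tibble::tibble(rule = character(), plot_id = character(),
                   visit_id = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a point-intercept survey from CSV files
#'
#' Reads the two-file on-disk form of a survey: an intercept table
#' (`plot_id, visit_id, visit_date, transect, point, hit_kind, species_code,
#' growth_form`) and a visit metadata table
#' (`plot_id, visit_id, visit_date, mvg_label, notes`). Both UTF-8,
#' comma-delimited, with header. Row order is irrelevant: records are
#' canonically sorted on ingest, so downstream results do not depend on how
#' the file was written.
#'
#' @param path Path to the intercept CSV.
#' @param metadata_path Path to the visit metadata CSV.
#' @inheritParams survey_dataset
#' @return A validated [survey_dataset()].
#' @export
read_survey_table <- function(path, metadata_path,
                              points_per_plot = POINTS_PER_PLOT,
                              strict = TRUE) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  need <- c("plot_id", "visit_id", "transect", "point", "hit_kind",
            "species_code", "growth_form")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  miss <- setdiff(need, header)
  if (length(miss) > 0) {
    abort(paste0("intercept CSV missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vegshift_format_error")
  }
  rec <- readr::read_csv(path, col_types = readr::cols(
    plot_id = readr::col_character(), visit_id = readr::col_character(),
    visit_date = readr::col_character(), transect = readr::col_integer(),
    point = readr::col_integer(), hit_kind = readr::col_character(),
    species_code = readr::col_character(), growth_form = readr::col_character()),
    progress = FALSE)
  vheader <- names(readr::read_csv(metadata_path, n_max = 0,
                                   show_col_types = FALSE, progress = FALSE))
  miss <- setdiff(c("plot_id", "visit_id", "visit_date", "mvg_label"), vheader)
  if (length(miss) > 0) {
    abort(paste0("metadata CSV missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vegshift_format_error")
  }
  vis <- readr::read_csv(metadata_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  survey_dataset(rec[need], vis, points_per_plot = points_per_plot,
                 strict = strict)
}

#' Write a survey dataset to its two-file CSV form
#'
#' Inverse of [read_survey_table()]: writes canonical-order CSVs such that
#' reading them back reproduces the dataset exactly.
#'
#' @param dataset A `survey_dataset`.
#' @param path Output path for the intercept CSV.
#' @param metadata_path Output path for the visit metadata CSV.
#' @return `dataset`, invisibly.
#' @export
write_survey_table <- function(dataset, path, metadata_path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records |>
    dplyr::left_join(dataset$visits[c("plot_id", "visit_id", "visit_date")],
                     by = c("plot_id", "visit_id")) |>
    dplyr::select("plot_id", "visit_id", "visit_date", "transect", "point",
                  "hit_kind", "species_code", "growth_form")
  readr::write_csv(rec, path, progress = FALSE)
  readr::write_csv(dataset$visits, metadata_path, progress = FALSE)
  invisible(dataset)
}

#' Pair each revisit of a plot with its baseline survey
#'
#' The earliest visit of every plot is its baseline. In `"baseline_to_each"`
#' mode each later visit is paired with that baseline (a plot with k visits
#' yields k-1 pairs); in `"first_to_last"` mode only the earliest and latest
#' visits are paired (one pair per repeat plot). Intervals are fractional
#' years (days / 365.25). Plots with a single visit contribute no pairs.
#'
#' @param dataset A `survey_dataset`.
#' @param mode `"baseline_to_each"` (default) or `"first_to_last"`.
#' @return A tibble with columns `plot_id`, `baseline_visit`, `revisit`,
#'   `baseline_date`, `revisit_date`, `interval_years`.
#' @export
pair_revisits <- function(dataset, mode = c("baseline_to_each", "first_to_last")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  mode <- match.arg(mode)
  vis <- canonical_visit_order(dataset$visits)
  empty <- tibble::tibble(plot_id = character(), baseline_visit = character(),
                          revisit = character(),
                          baseline_date = as.Date(character()),
                          revisit_date = as.Date(character()),
                          interval_years = numeric())
  pairs <- vis |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      baseline_visit = .data$visit_id[1],
      baseline_date = .data$visit_date[1],
      revisit = list(.data$visit_id[-1]),
      revisit_date = list(.data$visit_date[-1]),
      .groups = "drop") |>
    tidyr::unnest(c("revisit", "revisit_date"))
  if (nrow(pairs) == 0) return(empty)
  if (mode == "first_to_last" && nrow(pairs) > 0) {
    pairs <- pairs |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::slice_max(.data$revisit_date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  pairs |>
    dplyr::mutate(interval_years = as.numeric(.data$revisit_date -
                                                .data$baseline_date) / DAYS_PER_YEAR) |>
    dplyr::select("plot_id", "baseline_visit", "revisit", "baseline_date",
                  "revisit_date", "interval_years") |>
    dplyr::arrange(.data$plot_id, .data$revisit_date)
}
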