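#' Run the full validation pipeline
#'
#' Orchestrates every analysis stage on one dataset: match tabulation with
#' paired tests of proportions (overall, by meal type, by food group; with
#' and without beverages), per-meal energy totals with percent error and
#' bounds concordance, the stratified energy summaries, elevation of mean
#' estimated over mean weighed energy, Bland-Altman agreement and
#' calibration regression for every mode x beverage cell, and survey
#' scores. Everything is computed on the item table as given; no
#' randomness is involved, so reruns on the same inputs are identical.
#'
#' @param ds A [study_dataset()], or a path to an `items.csv` file.
#' @param surveys A survey response tibble (see [read_surveys()]), a path
#'   to a `surveys.csv` file, or `NULL` to skip survey scoring.
#' @param bounds Symmetric percent bounds for concordance flags.
#' @param test_method Paired-test flavour passed to [mcnemar_paired()].
#' @param loa_multiplier Limits-of-agreement multiplier.
#' @return An object of class `pipeline_report`: a list with elements
#'   `match_tables`, `paired_tests`, `energy_meals`, `energy_summaries`,
#'   `elevation`, `agreement`, `survey_scores`, `provenance`.
#' @export
run_pipeline <- function(ds, surveys = NULL, bounds = c(10, 25),
                         test_method = c("exact", "chisq", "auto"),
                         loa_multiplier = 1.96) {
  test_method <- match.arg(test_method)
  if (is.character(ds)) ds <- read_food_log(ds, quiet = TRUE)
  stopifnot(inherits(ds, "study_dataset"))
  if (is.character(surveys)) surveys <- read_surveys(surveys)

  violations <- validate_dataset(ds)
  if (nrow(violations) > 0) {
    stop("dataset fails validation; see validate_dataset(): ",
         nrow(violations), " violation(s), first: ",
         violations$message[1], " (row ", violations$row[1], ")",
         call. = FALSE)
  }

  grid <- expand.grid(
    by = c("overall", "meal_type", "food_group"),
    beverages = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  match_tables <- purrr::pmap(grid, function(by, beverages) {
    dplyr::bind_rows(
      tabulate_matches(ds, "automated", by, include_beverages = beverages),
      tabulate_matches(ds, "semiautomated", by, include_beverages = beverages)
    ) |>
      dplyr::mutate(stratifier = by, beverages_included = beverages,
                    .before = 1)
  }) |> dplyr::bind_rows()

  paired_grid <- expand.grid(
    by = c("overall", "meal_type", "food_group"),
    beverages = c(TRUE, FALSE),
    category = c("exact", "far", "intrusion"),
    stringsAsFactors = FALSE
  )
  paired_tests <- purrr::pmap(paired_grid, function(by, beverages, category) {
    paired_proportions_test(ds, category, by, include_beverages = beverages,
                            method = test_method) |>
      dplyr::mutate(stratifier = by, beverages_included = beverages,
                    .before = 1)
  }) |> dplyr::bind_rows()

  meals_with <- meal_totals(ds, include_beverages = TRUE, bounds = bounds)
  meals_without <- meal_totals(ds, include_beverages = FALSE, bounds = bounds)
  energy_meals <- dplyr::bind_rows(
    dplyr::mutate(meals_with, beverages_included = TRUE, .before = 1),
    dplyr::mutate(meals_without, beverages_included = FALSE, .before = 1)
  )

  energy_summaries <- dplyr::bind_rows(
    summarize_by_menu_type(meals_with) |>
      dplyr::mutate(stratifier = "meal_type", beverages_included = TRUE, .before = 1),
    summarize_by_menu_type(meals_without) |>
      dplyr::mutate(stratifier = "meal_type", beverages_included = FALSE, .before = 1),
    summarize_by_food_group(ds, include_beverages = TRUE, bounds = bounds) |>
      dplyr::mutate(stratifier = "food_group", beverages_included = TRUE, .before = 1),
    summarize_by_food_group(ds, include_beverages = FALSE, bounds = bounds) |>
      dplyr::mutate(stratifier = "food_group", beverages_included = FALSE, .before = 1)
  )

  elevation <- tidyr::expand_grid(
    mode = c("automated", "semiautomated"),
    beverages_included = c(TRUE, FALSE)
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      elevation_pct = elevation_of_means(
        if (.data$beverages_included) meals_with else meals_without, .data$mode
      ),
      mean_diff_kcal = {
        m <- if (.data$beverages_included) meals_with else meals_without
        est <- if (.data$mode == "automated") m$auto_kcal_total else m$semi_kcal_total
        mean(est - m$weighed_kcal_total)
      }
    ) |>
    dplyr::ungroup()

  agreement <- agreement_suite(ds, loa_multiplier = loa_multiplier)

  survey_scores <- if (is.null(surveys)) {
    tibble::tibble(instrument = character(), item_label = character(),
                   n = integer(), mean = double(), sd = double())
  } else {
    dplyr::bind_rows(score_csuq(surveys), score_uss(surveys))
  }

  items <- ds$items
  provenance <- list(
    n_items = nrow(items),
    n_meals = nrow(dplyr::distinct(items, .data$participant_id, .data$meal_id)),
    n_participants = nrow(ds$participants),
    n_omitted = sum(omitted_items(items)),
    beverage_list = attr(ds, "beverages", exact = TRUE),
    bounds = bounds,
    test_method = test_method,
    loa_multiplier = loa_multiplier,
    input_hash = rlang::hash(list(items, surveys)),
    package_version = as.character(utils::packageVersion("dietvalidr"))
  )

  report <- structure(
    list(
      match_tables = match_tables,
      paired_tests = paired_tests,
      energy_meals = energy_meals,
      energy_summaries = energy_summaries,
      elevation = elevation,
      agreement = agreement,
      survey_scores = survey_scores,
      provenance = provenance
    ),
    class = "pipeline_report"
  )
  check_report_consistency(report)
  report
}

# overall counts must equal the sum of per-meal-type counts, per mode and
# beverage setting; run on every report
check_report_consistency <- function(report) {
  mt <- report$match_tables
  for (bev in unique(mt$beverages_included)) {
    for (mode in unique(mt$mode)) {
      ov <- mt[mt$stratifier == "overall" & mt$mode == mode &
                 mt$beverages_included == bev, ]
      by_meal <- mt[mt$stratifier == "meal_type" & mt$mode == mode &
                      mt$beverages_included == bev, ]
      for (col in c("n_exact", "n_far", "n_intrusion", "n_classified")) {
        if (sum(by_meal[[col]]) != ov[[col]]) {
          stop("internal consistency failure: per-meal-type ", col,
               " do not sum to the overall count", call. = FALSE)
        }
      }
    }
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<pipeline_report> %d items, %d meals, %d participants (%d omission-affected)\n",
    p$n_items, p$n_meals, p$n_participants, p$n_omitted
  ))
  ov <- x$match_tables[x$match_tables$stratifier == "overall" &
                         x$match_tables$beverages_included, ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %s: exact %d (%.0f%%), far %d (%.0f%%), intrusion %d (%.0f%%) of %d\n",
                ov$mode[i], ov$n_exact[i], round_half_up(ov$pct_exact[i]),
                ov$n_far[i], round_half_up(ov$pct_far[i]),
                ov$n_intrusion[i], round_half_up(ov$pct_intrusion[i]),
                ov$n_classified[i]))
  }
  el <- x$elevation
  for (i in seq_len(nrow(el))) {
    cat(sprintf("  energy elevation (%s, beverages %s): %.0f%%\n",
                el$mode[i],
                ifelse(el$beverages_included[i], "included", "excluded"),
                round_half_up(el$elevation_pct[i])))
  }
  invisible(x)
}

ba_as_list <- function(x) unclass(x)

#' Render a pipeline report to files
#'
#' `csv_bundle` writes six files into `dir`: `match_tables.csv` (counts,
#' raw and display-rounded percentages, and the automated-vs-semiautomated
#' paired-test p-value per category), `energy_meals.csv`,
#' `energy_summary.csv`, `survey_scores.csv`, `agreement.json`, and
#' `provenance.json`.
#' `json` writes the entire report as a single `report.json` at full
#' precision. Output is byte-stable for identical reports.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param format `"csv_bundle"` or `"json"`.
#' @param digits Display rounding (decimal places) for the rounded
#'   percentage columns in the CSV bundle.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("csv_bundle", "json"),
                          digits = 0) {
  stopifnot(inherits(report, "pipeline_report"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(name) {
    written <<- c(written, file.path(dir, name))
    file.path(dir, name)
  }
  if (format == "json") {
    out <- report
    out$agreement <- lapply(report$agreement, function(cell) {
      list(bland_altman = ba_as_list(cell$bland_altman),
           calibration = ba_as_list(cell$calibration))
    })
    jsonlite::write_json(unclass(out), put("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    return(invisible(written))
  }
  mt <- report$match_tables
  for (col in c("pct_exact", "pct_far", "pct_intrusion")) {
    mt[[paste0(col, "_display")]] <- round_half_up(mt[[col]], digits)
  }
  pv <- report$paired_tests |>
    dplyr::select("stratifier", "beverages_included", "stratum", "category",
                  "p_value") |>
    tidyr::pivot_wider(names_from = "category", values_from = "p_value",
                       names_prefix = "p_auto_vs_semi_")
  mt <- dplyr::left_join(mt, pv,
                         by = c("stratifier", "beverages_included", "stratum"))
  readr::write_csv(mt, put("match_tables.csv"), progress = FALSE, na = "")
  readr::write_csv(report$energy_meals, put("energy_meals.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(report$energy_summaries, put("energy_summary.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(report$survey_scores, put("survey_scores.csv"),
                   progress = FALSE, na = "")
  agreement <- lapply(report$agreement, function(cell) {
    list(bland_altman = ba_as_list(cell$bland_altman),
         calibration = ba_as_list(cell$calibration))
  })
  jsonlite::write_json(agreement, put("agreement.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(c(report$provenance, list(elevation = report$elevation)),
                       put("provenance.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(written)
}

#' Reload a JSON report
#'
#' Inverse of `render_report(format = "json")` for the numeric content:
#' tables come back as tibbles with the same values (the S3 classes on the
#' agreement objects are not reconstructed).
#'
#' @param path Path to a `report.json`.
#' @return A list mirroring the report structure.
#' @export
read_report_json <- function(path) {
  out <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("match_tables", "paired_tests", "energy_meals",
               "energy_summaries", "elevation", "survey_scores")) {
    if (!is.null(out[[nm]])) out[[nm]] <- tibble::as_tibble(out[[nm]])
  }
  out
}
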