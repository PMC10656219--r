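#' Signed percent error of an energy estimate
#'
#' `100 * (estimated - weighed) / weighed`: overestimation is positive.
#' A zero weighed value makes the error undefined; such entries return
#' `NaN` with a warning and are excluded from downstream means.
#'
#' @param estimated,weighed Numeric kcal vectors (recycled).
#' @return Numeric vector of percent errors.
#' @examples
#' percent_error(150, 100) # 50
#' percent_error(75, 100)  # -25
#' @export
percent_error <- function(estimated, weighed) {
  out <- 100 * (estimated - weighed) / weighed
  zero <- !is.na(weighed) & weighed == 0
  if (any(zero)) {
    warning(sum(zero), " item(s) with weighed kcal = 0; percent error undefined",
            call. = FALSE)
    out[zero] <- NaN
  }
  out
}

#' Per-meal energy totals, percent error and bounds concordance
#'
#' Sums weighed, automated, and semiautomated kcal over each meal's
#' included items and computes per-meal percent errors and within-bounds
#' flags for both modes. An item omitted in *either* mode is excluded from
#' all three totals, so the totals always cover an identical item set and
#' the modes stay comparable. Bounds are closed: `|error| <= b` counts as
#' within.
#'
#' @param ds A [study_dataset()].
#' @param include_beverages Drop beverages first if `FALSE`.
#' @param bounds Numeric vector of symmetric percent bounds (default 10, 25).
#' @return A tibble with one row per meal: keys, `n_items`,
#'   `weighed_kcal_total`, `auto_kcal_total`, `semi_kcal_total`,
#'   `pct_error_auto`, `pct_error_semi`, and logical columns
#'   `within_<b>_auto` / `within_<b>_semi` per bound.
#' @export
meal_totals <- function(ds, include_beverages = TRUE, bounds = c(10, 25)) {
  stopifnot(inherits(ds, "study_dataset"), all(bounds > 0))
  if (!include_beverages) ds <- exclude_beverages(ds)
  items <- ds$items[!omitted_items(ds$items), ]
  empty <- dplyr::anti_join(
    dplyr::distinct(ds$items, .data$participant_id, .data$meal_id),
    items, by = c("participant_id", "meal_id")
  )
  if (nrow(empty) > 0) {
    warning(nrow(empty), " meal(s) had no included items and were dropped",
            call. = FALSE)
  }
  meals <- items |>
    dplyr::group_by(.data$participant_id, .data$meal_id, .data$menu_type,
                    .data$menu_variant_kcal) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      weighed_kcal_total = sum(.data$weighed_kcal),
      auto_kcal_total = sum(.data$auto_kcal),
      semi_kcal_total = sum(.data$semi_kcal),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_error_auto = percent_error(.data$auto_kcal_total, .data$weighed_kcal_total),
      pct_error_semi = percent_error(.data$semi_kcal_total, .data$weighed_kcal_total)
    )
  for (b in bounds) {
    meals[[sprintf("within_%g_auto", b)]] <- abs(meals$pct_error_auto) <= b
    meals[[sprintf("within_%g_semi", b)]] <- abs(meals$pct_error_semi) <= b
  }
  meals
}

#' Elevation of mean estimated energy over mean weighed energy
#'
#' The headline error figure: `100 * (mean(estimated totals) -
#' mean(weighed totals)) / mean(weighed totals)`. This is a ratio of means
#' (equivalently, of sums), distinct from the mean of per-meal percent
#' errors reported in the stratified summaries; both conventions appear in
#' validation reports, so both are exposed.
#'
#' @param meals Tibble from [meal_totals()].
#' @param mode `"automated"` or `"semiautomated"`.
#' @return Percent elevation (scalar).
#' @export
elevation_of_means <- function(meals, mode = c("automated", "semiautomated")) {
  mode <- match.arg(mode)
  stopifnot(nrow(meals) > 0)
  est <- if (mode == "automated") meals$auto_kcal_total else meals$semi_kcal_total
  100 * (mean(est) - mean(meals$weighed_kcal_total)) / mean(meals$weighed_kcal_total)
}

# shared mean/SD/bounds summary over a grouped error table
summarise_energy <- function(df) {
  bounds_cols <- grep("^within_", names(df), value = TRUE)
  out <- df |>
    dplyr::summarise(
      n = dplyr::n(),
      weighed_mean = mean(.data$weighed), weighed_sd = stats::sd(.data$weighed),
      auto_mean = mean(.data$auto), auto_sd = stats::sd(.data$auto),
      semi_mean = mean(.data$semi), semi_sd = stats::sd(.data$semi),
      pct_error_auto_mean = mean(.data$err_auto, na.rm = TRUE),
      pct_error_auto_sd = stats::sd(.data$err_auto, na.rm = TRUE),
      pct_error_semi_mean = mean(.data$err_semi, na.rm = TRUE),
      pct_error_semi_sd = stats::sd(.data$err_semi, na.rm = TRUE),
      dplyr::across(dplyr::all_of(bounds_cols), list(n = ~sum(.x, na.rm = TRUE))),
      .groups = "drop"
    )
  for (b in bounds_cols) {
    out[[sprintf("%s_pct", b)]] <- 100 * out[[sprintf("%s_n", b)]] / out$n
  }
  out
}

#' Energy summary by menu type
#'
#' Meal-level analogue of the report's per-menu comparison: per menu type,
#' mean and SD (n - 1 denominator) of the weighed, automated, and
#' semiautomated totals, mean and SD of the per-meal percent errors
#' (mean-of-ratios), and within-bounds counts and percentages. A
#' single-meal stratum has `NA` SDs.
#'
#' @param meals Tibble from [meal_totals()].
#' @return A tibble with one row per menu type.
#' @export
summarize_by_menu_type <- function(meals) {
  bounds_cols <- grep("^within_", names(meals), value = TRUE)
  meals |>
    dplyr::transmute(
      stratum = .data$menu_type,
      weighed = .data$weighed_kcal_total,
      auto = .data$auto_kcal_total,
      semi = .data$semi_kcal_total,
      err_auto = .data$pct_error_auto,
      err_semi = .data$pct_error_semi,
      dplyr::across(dplyr::all_of(bounds_cols))
    ) |>
    dplyr::group_by(.data$stratum) |>
    summarise_energy()
}

#' Energy summary by FNDDS food group
#'
#' Item-level analogue of [summarize_by_menu_type()], stratified by the
#' major food group of the *served* code. Items omitted in either mode are
#' excluded; groups with no remaining items do not appear.
#'
#' @param ds A [study_dataset()].
#' @param include_beverages Drop beverages first if `FALSE`.
#' @param bounds Symmetric percent bounds (default 10, 25).
#' @return A tibble with one row per occupied food group.
#' @export
summarize_by_food_group <- function(ds, include_beverages = TRUE,
                                    bounds = c(10, 25)) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!include_beverages) ds <- exclude_beverages(ds)
  items <- ds$items[!omitted_items(ds$items), ]
  df <- tibble::tibble(
    group_id = major_group(items$served_fndds),
    weighed = items$weighed_kcal,
    auto = items$auto_kcal,
    semi = items$semi_kcal,
    err_auto = suppressWarnings(percent_error(items$auto_kcal, items$weighed_kcal)),
    err_semi = suppressWarnings(percent_error(items$semi_kcal, items$weighed_kcal))
  )
  for (b in bounds) {
    df[[sprintf("within_%g_auto", b)]] <- abs(df$err_auto) <= b
    df[[sprintf("within_%g_semi", b)]] <- abs(df$err_semi) <= b
  }
  df |>
    dplyr::group_by(.data$group_id) |>
    summarise_energy() |>
    dplyr::mutate(stratum = food_group_label(.data$group_id), .after = "group_id")
}
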