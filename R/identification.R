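match_levels <- function() c("exact", "far", "intrusion", "omission")

#' Classify a logged food against the served food
#'
#' Classification uses the hierarchical structure of 8-digit FNDDS codes:
#' an *exact match* agrees in all 8 digits, a *far match* agrees in the
#' first digit only (same major food group, different food), and an
#' *intrusion* disagrees in the first digit. An *omission* is a served item
#' that was never scanned, for which no code was logged, or whose logged
#' food had no nutrient information available in the app.
#'
#' The four categories are mutually exclusive and exhaustive for every
#' (served, logged) pair.
#'
#' @param served Character vector of served-item FNDDS codes.
#' @param logged Character vector of logged FNDDS codes (`NA` = not logged).
#' @param scanned Logical vector; was the item scanned at all?
#' @param nutrient_available Logical vector; did the logged food have
#'   nutrient information?
#' @return Factor with levels `exact`, `far`, `intrusion`, `omission`.
#' @examples
#' classify_match("27510170", "27510170") # exact
#' classify_match("27510170", "27545110") # far
#' classify_match("27510170", "58127310") # intrusion
#' classify_match("27510170", NA)         # omission
#' @export
classify_match <- function(served, logged, scanned = TRUE,
                           nutrient_available = TRUE) {
  served <- fndds_code(served)
  logged <- fndds_code(logged)
  n <- length(served)
  scanned <- rep_len(scanned, n)
  nutrient_available <- rep_len(nutrient_available, n)
  logged <- rep_len(logged, n)
  if (anyNA(served)) stop("served code must not be NA", call. = FALSE)

  omitted <- !scanned | is.na(logged) | !nutrient_available
  out <- character(n)
  out[omitted] <- "omission"
  cmp <- !omitted
  out[cmp & served == logged] <- "exact"
  first_eq <- substr(served, 1, 1) == substr(logged, 1, 1)
  out[cmp & first_eq & served != logged] <- "far"
  out[cmp & !first_eq] <- "intrusion"
  factor(out, levels = match_levels())
}

# append auto_match / semi_match factor columns to an item table
add_match_columns <- function(items) {
  items$auto_match <- classify_match(
    items$served_fndds, items$auto_fndds,
    items$auto_scanned, items$auto_nutrients_available
  )
  items$semi_match <- classify_match(
    items$served_fndds, items$semi_fndds,
    items$auto_scanned, items$semi_nutrients_available
  )
  items
}

stratum_column <- function(items, by) {
  switch(by,
    overall = rep("overall", nrow(items)),
    meal_type = items$menu_type,
    food_group = food_group_label(major_group(items$served_fndds)),
    stop("unknown stratifier: ", by, call. = FALSE)
  )
}

#' Tabulate match categories
#'
#' Counts and percentages of exact matches, far matches, and intrusions per
#' stratum for one logging mode. Items classified as omissions in that mode
#' are excluded from the denominator, so the three percentages are shares of
#' the classified items and sum to 100 within rounding.
#'
#' @param ds A [study_dataset()].
#' @param mode `"automated"` or `"semiautomated"`.
#' @param by Stratifier: `"overall"`, `"meal_type"`, or `"food_group"`
#'   (major group of the *served* code).
#' @param include_beverages If `FALSE`, beverage items are removed before
#'   stratification.
#' @return A tibble with one row per stratum: counts `n_classified`,
#'   `n_exact`, `n_far`, `n_intrusion`, `n_omitted` and raw percentages
#'   `pct_exact`, `pct_far`, `pct_intrusion` (NaN when a stratum has no
#'   classified items).
#' @export
tabulate_matches <- function(ds, mode = c("automated", "semiautomated"),
                             by = c("overall", "meal_type", "food_group"),
                             include_beverages = TRUE) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  if (!include_beverages) ds <- exclude_beverages(ds)
  items <- add_match_columns(ds$items)
  cls <- if (mode == "automated") items$auto_match else items$semi_match
  tibble::tibble(stratum = stratum_column(items, by), match = cls) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_exact = sum(.data$match == "exact"),
      n_far = sum(.data$match == "far"),
      n_intrusion = sum(.data$match == "intrusion"),
      n_omitted = sum(.data$match == "omission"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mode = mode,
      n_classified = .data$n_exact + .data$n_far + .data$n_intrusion,
      pct_exact = 100 * .data$n_exact / .data$n_classified,
      pct_far = 100 * .data$n_far / .data$n_classified,
      pct_intrusion = 100 * .data$n_intrusion / .data$n_classified
    ) |>
    dplyr::select(
      "stratum", "mode", "n_classified", "n_exact", "n_far", "n_intrusion",
      "n_omitted", "pct_exact", "pct_far", "pct_intrusion"
    )
}

#' Exact McNemar test from discordant counts
#'
#' Paired test of proportions on the discordant pairs: `b` items positive
#' under the automated mode only, `c` positive under the semiautomated mode
#' only. The exact version refers `min(b, c)` to Binomial(b + c, 1/2)
#' (two-sided); the chi-square version applies the continuity-corrected
#' McNemar statistic.
#'
#' @param b,c Discordant counts.
#' @param method `"exact"` (default) or `"chisq"`. With `method = "auto"`
#'   the exact test is used for `b + c <= 25` and chi-square above.
#' @return A one-row tibble: `b`, `c`, `statistic`, `p_value`, `method`,
#'   `degenerate` (TRUE when `b + c == 0`, where `p = 1` by convention).
#' @export
mcnemar_paired <- function(b, c, method = c("exact", "chisq", "auto")) {
  method <- match.arg(method)
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  n_disc <- b + c
  if (method == "auto") method <- if (n_disc > 25) "chisq" else "exact"
  if (n_disc == 0) {
    return(tibble::tibble(b = b, c = c, statistic = NA_real_, p_value = 1,
                          method = method, degenerate = TRUE))
  }
  if (method == "exact") {
    ht <- stats::binom.test(b, n_disc, p = 0.5)
    stat <- as.numeric(ht$statistic)
    p <- ht$p.value
  } else {
    stat <- (abs(b - c) - 1)^2 / n_disc
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b = b, c = c, statistic = stat, p_value = p,
                 method = method, degenerate = FALSE)
}

#' Paired test of proportions between logging modes
#'
#' For each stratum, tests whether the proportion of items falling in a
#' match category differs between automated and semiautomated logging.
#' Items are paired with themselves across modes; only items classified
#' (non-omission) in *both* modes enter, and the test is driven by the
#' discordant counts (category membership under one mode only).
#'
#' @param ds A [study_dataset()].
#' @param category One of `"exact"`, `"far"`, `"intrusion"`.
#' @param by Stratifier as in [tabulate_matches()].
#' @param include_beverages Drop beverages first if `FALSE`.
#' @param method Test flavour passed to [mcnemar_paired()].
#' @return A tibble with one row per stratum: `n_pairs`, discordant counts
#'   `b` (automated-only) and `c` (semiautomated-only), `statistic`,
#'   `p_value`, `method`, `degenerate`.
#' @export
paired_proportions_test <- function(ds, category = c("exact", "far", "intrusion"),
                                    by = c("overall", "meal_type", "food_group"),
                                    include_beverages = TRUE,
                                    method = c("exact", "chisq", "auto")) {
  category <- match.arg(category)
  by <- match.arg(by)
  method <- match.arg(method)
  if (!include_beverages) ds <- exclude_beverages(ds)
  items <- add_match_columns(ds$items)
  items <- items[items$auto_match != "omission" & items$semi_match != "omission", ]
  tibble::tibble(
    stratum = stratum_column(items, by),
    in_auto = items$auto_match == category,
    in_semi = items$semi_match == category
  ) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      category = category,
      n_pairs = dplyr::n(),
      test = list(mcnemar_paired(
        b = sum(.data$in_auto & !.data$in_semi),
        c = sum(!.data$in_auto & .data$in_semi),
        method = method
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest("test")
}
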