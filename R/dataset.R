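#' @keywords internal
items_schema <- function() {
  c(
    participant_id = "character", meal_id = "character",
    menu_type = "character", menu_variant_kcal = "integer",
    item_id = "character", item_name = "character",
    served_fndds = "character", weighed_kcal = "double",
    weighed_grams = "double", is_beverage = "logical",
    auto_scanned = "logical", auto_fndds = "character",
    auto_kcal = "double", auto_nutrients_available = "logical",
    semi_fndds = "character", semi_kcal = "double",
    semi_nutrients_available = "logical"
  )
}

menu_types <- function() c("chicken", "hamburger", "pizza", "pork_chop", "salad")

#' Construct a study dataset
#'
#' Bundles an item-level food log (one row per served food item, with its
#' weighed reference kcal and its automated and semiautomated log entries)
#' with participant metadata. The item table follows the documented
#' `items.csv` schema; see [read_food_log()].
#'
#' @param items Tibble of item records in the `items.csv` schema.
#' @param participants Optional tibble of participant metadata with at least
#'   a `participant_id` column. Derived from `items` when absent.
#' @param beverages Character vector of item names treated as beverages;
#'   the `is_beverage` flag is recomputed from this list.
#' @return An object of class `study_dataset`: a list with elements `items`
#'   and `participants`.
#' @export
study_dataset <- function(items, participants = NULL,
                          beverages = default_beverages()) {
  items <- tibble::as_tibble(items)
  required <- names(items_schema())
  missing_cols <- setdiff(required, names(items))
  if ("weighed_grams" %in% missing_cols) {
    items$weighed_grams <- NA_real_
    missing_cols <- setdiff(missing_cols, "weighed_grams")
  }
  if (length(missing_cols) > 0) {
    stop("items table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  items$served_fndds <- fndds_code(items$served_fndds)
  items$auto_fndds <- fndds_code(items$auto_fndds)
  items$semi_fndds <- fndds_code(items$semi_fndds)
  items$is_beverage <- items$item_name %in% beverages
  if (is.null(participants)) {
    participants <- tibble::tibble(participant_id = unique(items$participant_id))
  }
  structure(
    list(items = items[required], participants = tibble::as_tibble(participants)),
    beverages = beverages,
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  n_om <- sum(omitted_items(x$items))
  cat(sprintf(
    "<study_dataset> %d items / %d meals / %d participants (%d omission-affected items)\n",
    nrow(x$items),
    nrow(dplyr::distinct(x$items, .data$participant_id, .data$meal_id)),
    nrow(x$participants), n_om
  ))
  invisible(x)
}

# TRUE where the item is an omission in either logging mode
omitted_items <- function(items) {
  auto_om <- !items$auto_scanned | is.na(items$auto_fndds) |
    !items$auto_nutrients_available
  semi_om <- !items$auto_scanned | is.na(items$semi_fndds) |
    !items$semi_nutrients_available
  auto_om | semi_om
}

#' Read an item-level food log
#'
#' Reads the comma-delimited `items.csv` schema: one row per served item
#' carrying the staff-assigned FNDDS code and weighed kcal, plus the
#' automated and semiautomated log entries (logged FNDDS code, estimated
#' kcal, scan and nutrient-availability flags). Beverage flags are
#' recomputed from the configured beverage name list.
#'
#' @param path Path to the CSV file.
#' @param beverages Beverage item names (see [default_beverages()]).
#' @param quiet Suppress the row/omission summary message.
#' @return A [study_dataset()].
#' @export
read_food_log <- function(path, beverages = default_beverages(), quiet = FALSE) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  required <- setdiff(names(items_schema()), "weighed_grams")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # parse problems are re-raised as errors with row context below
  items <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      meal_id = readr::col_character(),
      menu_type = readr::col_character(),
      menu_variant_kcal = readr::col_integer(),
      item_id = readr::col_character(),
      item_name = readr::col_character(),
      served_fndds = readr::col_character(),
      weighed_kcal = readr::col_double(),
      weighed_grams = readr::col_double(),
      is_beverage = readr::col_logical(),
      auto_scanned = readr::col_logical(),
      auto_fndds = readr::col_character(),
      auto_kcal = readr::col_double(),
      auto_nutrients_available = readr::col_logical(),
      semi_fndds = readr::col_character(),
      semi_kcal = readr::col_double(),
      semi_nutrients_available = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  prob <- readr::problems(items)
  if (nrow(prob) > 0) {
    stop(sprintf("parse error in '%s' at row %d, column '%s': expected %s",
                 path, prob$row[1], names(items)[prob$col[1]], prob$expected[1]),
         call. = FALSE)
  }
  ds <- study_dataset(items, beverages = beverages)
  dup <- duplicated(ds$items[c("participant_id", "meal_id", "item_id")])
  if (any(dup)) {
    stop(sprintf("duplicate item key at row %d of '%s'", which(dup)[1] + 1L, path),
         call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("Read %d item records (%d omission-affected) from %s",
                    nrow(ds$items), sum(omitted_items(ds$items)), path))
  }
  ds
}

#' Write an item-level food log
#'
#' @param ds A [study_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_log <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  readr::write_csv(ds$items, path, progress = FALSE)
  invisible(path)
}

#' Read Likert survey responses
#'
#' Long format: `participant_id, instrument, item_number, score` where
#' `instrument` is `CSUQ` (19 items, 1-7) or `USS` (5 items, 1-6).
#'
#' @param path Path to the CSV file.
#' @return A tibble of responses.
#' @export
read_surveys <- function(path) {
  resp <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      instrument = readr::col_character(),
      item_number = readr::col_integer(),
      score = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  bad <- setdiff(unique(resp$instrument), c("CSUQ", "USS"))
  if (length(bad) > 0) {
    stop("unknown survey instrument(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  resp
}

#' Write Likert survey responses
#'
#' @param responses Tibble from [read_surveys()] or the generator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(responses, path) {
  readr::write_csv(responses, path, progress = FALSE)
  invisible(path)
}

#' Validate a study dataset
#'
#' Checks the dataset invariants without modifying it: kcal ranges, valid
#' menu types, key uniqueness, the beverage-flag rule, and the
#' log-entry consistency rule (an estimated kcal must be present exactly
#' when the item was scanned, a code was logged, and nutrient information
#' was available).
#'
#' @param ds A [study_dataset()].
#' @return A tibble of violations (`row`, `field`, `message`); zero rows
#'   means the dataset is clean. Violations are reported, never raised.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  items <- ds$items
  v <- list()
  flag <- function(rows, field, msg) {
    if (length(rows) > 0) {
      v[[length(v) + 1L]] <<- tibble::tibble(row = rows, field = field, message = msg)
    }
  }
  flag(which(items$weighed_kcal < 0), "weighed_kcal", "negative weighed kcal")
  flag(which(!is.na(items$auto_kcal) & items$auto_kcal < 0),
       "auto_kcal", "negative estimated kcal")
  flag(which(!is.na(items$semi_kcal) & items$semi_kcal < 0),
       "semi_kcal", "negative estimated kcal")
  flag(which(!items$menu_type %in% menu_types()), "menu_type",
       "unknown menu type")
  dup <- duplicated(items[c("participant_id", "meal_id", "item_id")])
  flag(which(dup), "item_id", "duplicate (participant, meal, item) key")
  auto_ok <- !is.na(items$auto_kcal) ==
    (items$auto_scanned & !is.na(items$auto_fndds) & items$auto_nutrients_available)
  flag(which(!auto_ok), "auto_kcal",
       "estimated kcal present iff scanned, coded, and nutrients available")
  semi_ok <- !is.na(items$semi_kcal) ==
    (items$auto_scanned & !is.na(items$semi_fndds) & items$semi_nutrients_available)
  flag(which(!semi_ok), "semi_kcal",
       "estimated kcal present iff scanned, coded, and nutrients available")
  bev <- items$item_name %in% attr(ds, "beverages", exact = TRUE)
  flag(which(items$is_beverage != bev), "is_beverage",
       "beverage flag disagrees with configured beverage list")
  if (length(v) == 0) {
    tibble::tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(v), .data$row)
  }
}

#' Remove beverage items
#'
#' Restricts a dataset to non-beverage items, leaving the original
#' untouched. The study's beverage-excluded analyses drop 1% milk (milk
#' group) and Coca Cola, Diet Coke and sweet tea (sugars/sweets/beverages
#' group) before stratification.
#'
#' @param ds A [study_dataset()].
#' @return A new [study_dataset()] with `is_beverage` items removed.
#' @export
exclude_beverages <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  out <- ds
  out$items <- ds$items[!ds$items$is_beverage, ]
  out
}
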