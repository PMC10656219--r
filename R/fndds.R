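#' Major FNDDS food groups
#'
#' The nine major food groups of the USDA Food and Nutrient Database for
#' Dietary Studies (FNDDS). Every FNDDS food code is 8 digits long and its
#' first digit indexes one of these groups.
#'
#' @return A tibble with columns `group_id` (integer, 1-9) and `label`.
#' @examples
#' fndds_food_groups()
#' @export
fndds_food_groups <- function() {
  tibble::tibble(
    group_id = 1:9,
    label = c(
      "milk and milk products",
      "meat, poultry, fish, and mixtures",
      "eggs",
      "dry beans, peas, other legumes, nuts, and seeds",
      "grain products",
      "fruits",
      "vegetables",
      "fats, oils, and salad dressings",
      "sugars, sweets, and beverages"
    )
  )
}

#' Parse and validate FNDDS food codes
#'
#' FNDDS codes are fixed-width strings of exactly 8 decimal digits whose
#' first digit is 1-9 (the major food group). Codes are kept as character
#' strings throughout the package: leading zeros in positions 2-8 are
#' meaningful and the digit positions carry the code hierarchy, so integer
#' storage would corrupt them.
#'
#' @param x Character vector of candidate codes. `NA` entries are passed
#'   through unchanged (an absent logged code denotes an omission, not an
#'   invalid one).
#' @return `x`, validated, as a plain character vector.
#' @examples
#' fndds_code("27510170")
#' major_group(fndds_code("58127310"))
#' @export
fndds_code <- function(x) {
  x <- as.character(x)
  ok <- is.na(x) | grepl("^[1-9][0-9]{7}$", x)
  if (!all(ok)) {
    bad <- utils::head(x[!ok], 5L)
    detail <- vapply(bad, function(b) {
      if (!grepl("^[0-9]+$", b)) sprintf("'%s' contains non-digit characters", b)
      else if (nchar(b) != 8L) sprintf("'%s' has %d digits, expected 8", b, nchar(b))
      else sprintf("'%s' has first digit 0; major food group must be 1-9", b)
    }, character(1))
    stop("Invalid FNDDS code(s): ", paste(detail, collapse = "; "), call. = FALSE)
  }
  x
}

#' Major food group of an FNDDS code
#'
#' @param code Character vector of valid FNDDS codes (see [fndds_code()]).
#' @return Integer vector of group ids (1-9); `NA` for `NA` codes.
#' @export
major_group <- function(code) {
  code <- fndds_code(code)
  as.integer(substr(code, 1L, 1L))
}

#' Label of a major food group
#'
#' @param group_id Integer vector in 1..9.
#' @return Character vector of group labels.
#' @export
food_group_label <- function(group_id) {
  stopifnot(all(is.na(group_id) | (group_id %in% 1:9)))
  fndds_food_groups()$label[group_id]
}

#' Default beverage item names
#'
#' Beverage identity is a configured list of item names rather than an
#' FNDDS-group rule, because the sugars/sweets/beverages group also holds
#' non-beverage sweets and the milk group holds non-beverage dairy.
#'
#' @return Character vector of item names treated as beverages.
#' @export
default_beverages <- function() {
  c("1% milk", "Coca Cola", "Diet Coke", "sweet tea")
}

#' Round half away from zero
#'
#' Display rounding used for reported percentages (base `round()` rounds
#' half to even, which is not how the report tables are rounded).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
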