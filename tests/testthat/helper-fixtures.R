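# one fully specified item row; override any field
make_item <- function(participant_id = "P01", meal_id = "M1",
                      menu_type = "hamburger", menu_variant_kcal = 735L,
                      item_id = "I01", item_name = "cheeseburger",
                      served_fndds = "27510170", weighed_kcal = 330,
                      weighed_grams = NA_real_, is_beverage = FALSE,
                      auto_scanned = TRUE, auto_fndds = "27510170",
                      auto_kcal = 350, auto_nutrients_available = TRUE,
                      semi_fndds = "27510170", semi_kcal = 340,
                      semi_nutrients_available = TRUE) {
  tibble::tibble(
    participant_id = participant_id, meal_id = meal_id,
    menu_type = menu_type, menu_variant_kcal = menu_variant_kcal,
    item_id = item_id, item_name = item_name, served_fndds = served_fndds,
    weighed_kcal = weighed_kcal, weighed_grams = weighed_grams,
    is_beverage = is_beverage, auto_scanned = auto_scanned,
    auto_fndds = auto_fndds, auto_kcal = auto_kcal,
    auto_nutrients_available = auto_nutrients_available,
    semi_fndds = semi_fndds, semi_kcal = semi_kcal,
    semi_nutrients_available = semi_nutrients_available
  )
}

# dataset where every logged code realises a requested automated category
# against the shared served code; semiautomated entries are exact. Each
# item is its own one-item meal with varying weighed kcal so meal-level
# analyses are well defined.
make_category_dataset <- function(categories, served = "27510170") {
  logged <- vapply(categories, function(cat) {
    switch(cat,
      exact = served,
      far = paste0(substr(served, 1, 1), "9999999"),
      intrusion = "58127310",
      omission = NA_character_
    )
  }, character(1))
  scanned <- categories != "omission"
  rows <- lapply(seq_along(categories), function(i) {
    w <- 100 + 10 * i
    make_item(
      participant_id = sprintf("P%03d", i),
      item_id = "I01", item_name = paste0("food ", i),
      served_fndds = served, weighed_kcal = w,
      auto_scanned = scanned[i], auto_fndds = logged[i],
      auto_kcal = if (scanned[i]) w * 1.2 else NA_real_,
      auto_nutrients_available = scanned[i],
      semi_fndds = if (scanned[i]) served else NA_character_,
      semi_kcal = if (scanned[i]) w * 1.1 else NA_real_,
      semi_nutrients_available = scanned[i]
    )
  })
  study_dataset(dplyr::bind_rows(rows))
}

# random valid FNDDS codes
random_codes <- function(n) {
  paste0(
    sample(1:9, n, replace = TRUE),
    vapply(seq_len(n),
           function(i) paste(sample(0:9, 7, replace = TRUE), collapse = ""),
           character(1))
  )
}

# a small clean simulated study shared across tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(default_study_config(seed = 42))
    cache
  }
})
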