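test_that("the default configuration matches the study design", {
  cfg <- default_study_config(seed = 1)
  menus <- dplyr::distinct(cfg$menu_table, menu_type, variant,
                           menu_variant_kcal)
  expect_identical(nrow(menus), 10L)
  expect_identical(sort(unique(menus$menu_type)),
                   c("chicken", "hamburger", "pizza", "pork_chop", "salad"))
  expect_true(all(table(menus$menu_type) == 2))
  expect_true(all(menus$menu_variant_kcal >= 400 &
                    menus$menu_variant_kcal <= 800))
  expect_identical(length(unique(cfg$menu_table$item_name)), 32L)
  # per-item kcal sums to the variant level
  sums <- cfg$menu_table |>
    dplyr::group_by(menu_type, variant) |>
    dplyr::summarise(total = sum(item_kcal),
                     level = menu_variant_kcal[1], .groups = "drop")
  expect_equal(sums$total, as.numeric(sums$level))
  for (p in cfg$match_probs) expect_equal(sum(p), 1)
  expect_identical(cfg$omission_rate, 0.02)
  # beverages carry strong positive automated bias (mean ratio >> 1)
  ee <- cfg$energy_error
  g9 <- ee[ee$mode == "automated" & ee$group_id == 9, ]
  expect_gt(exp(g9$mu + g9$sigma^2 / 2), 3)
  # expected classified items near 255 of ~260
  n_items_per_meal <- cfg$menu_table |>
    dplyr::count(menu_type, variant) |>
    dplyr::pull(n)
  expected_items <- cfg$n_participants * cfg$meals_per_participant *
    mean(n_items_per_meal)
  expect_equal(expected_items * (1 - cfg$omission_rate), 255,
               tolerance = 0.1)
})

test_that("generation is a pure function of the config", {
  cfg <- default_study_config(seed = 314)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$dataset$items, b$dataset$items)
  expect_identical(a$surveys, b$surveys)
  c <- simulate_study(default_study_config(seed = 315))
  expect_false(identical(a$dataset$items, c$dataset$items))

  # global RNG state is preserved
  set.seed(1); before <- .Random.seed
  invisible(simulate_study(cfg))
  expect_identical(.Random.seed, before)
})

test_that("generated datasets satisfy all dataset invariants", {
  sim <- small_sim()
  expect_identical(nrow(validate_dataset(sim$dataset)), 0L)
  expect_identical(nrow(sim$dataset$participants), 24L)
  meals <- dplyr::distinct(sim$dataset$items, participant_id, meal_id)
  expect_identical(nrow(meals), 48L)
})

test_that("a degenerate config yields all-exact matches with zero error", {
  cfg <- default_study_config(seed = 2)
  cfg$match_probs$automated <- c(exact = 1, far = 0, intrusion = 0)
  cfg$match_probs$semiautomated <- c(exact = 1, far = 0, intrusion = 0)
  cfg$energy_error$mu <- 0
  cfg$energy_error$sigma <- 0
  cfg$omission_rate <- 0
  sim <- simulate_study(cfg)
  items <- sim$dataset$items
  expect_true(all(items$auto_fndds == items$served_fndds))
  expect_true(all(items$semi_fndds == items$served_fndds))
  expect_equal(items$auto_kcal, items$weighed_kcal)
  meals <- meal_totals(sim$dataset)
  expect_true(all(meals$pct_error_auto == 0))
})

test_that("generated codes classify as their sampled category", {
  sim <- small_sim()
  items <- sim$dataset$items
  cls <- classify_match(items$served_fndds, items$auto_fndds,
                        items$auto_scanned, items$auto_nutrients_available)
  far_rows <- items[which(cls == "far"), ]
  expect_gt(nrow(far_rows), 0)
  expect_true(all(substr(far_rows$served_fndds, 1, 1) ==
                    substr(far_rows$auto_fndds, 1, 1)))
  expect_true(all(far_rows$served_fndds != far_rows$auto_fndds))
  intr_rows <- items[which(cls == "intrusion"), ]
  expect_true(all(substr(intr_rows$served_fndds, 1, 1) !=
                    substr(intr_rows$auto_fndds, 1, 1)))
})

test_that("category marginals converge to the configured probabilities", {
  cfg <- default_study_config(seed = 2024)
  cfg$n_participants <- 480L # ~5,500 items
  sim <- simulate_study(cfg)
  items <- sim$dataset$items
  for (mode in c("automated", "semiautomated")) {
    cls <- if (mode == "automated") {
      classify_match(items$served_fndds, items$auto_fndds,
                     items$auto_scanned, items$auto_nutrients_available)
    } else {
      classify_match(items$served_fndds, items$semi_fndds,
                     items$auto_scanned, items$semi_nutrients_available)
    }
    n <- sum(cls != "omission")
    probs <- cfg$match_probs[[mode]]
    for (cat in c("exact", "far", "intrusion")) {
      p <- probs[[cat]]
      phat <- sum(cls == cat) / n
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 1e-12,
                label = sprintf("%s %s marginal |%.4f - %.2f|",
                                mode, cat, phat, p))
    }
  }
  # omission marginal
  n_total <- nrow(items)
  p_om <- mean(dietvalidr:::omitted_items(items))
  expect_lt(abs(p_om - 0.02), 3 * sqrt(0.02 * 0.98 / n_total))
})

test_that("worked examples append four reference items", {
  sim <- small_sim()
  out <- inject_worked_examples(sim$dataset)
  expect_identical(nrow(out$items), nrow(sim$dataset$items) + 4L)
  ex <- out$items[out$items$participant_id == "EXAMPLE", ]
  cls <- classify_match(ex$served_fndds, ex$auto_fndds,
                        ex$auto_scanned, ex$auto_nutrients_available)
  expect_identical(as.character(cls),
                   c("exact", "far", "intrusion", "omission"))
  expect_identical(nrow(validate_dataset(out)), 0L)
})

test_that("config files override defaults and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_participants: 6",
    "omission_rate: 0",
    "seed: 77",
    "match_probs:",
    "  automated: [1, 0, 0]"
  ), path)
  cfg <- load_study_config(path)
  expect_identical(cfg$n_participants, 6L)
  expect_identical(cfg$omission_rate, 0)
  expect_identical(cfg$seed, 77L)
  expect_equal(unname(cfg$match_probs$automated), c(1, 0, 0))
  # untouched fields keep their defaults
  expect_equal(unname(cfg$match_probs$semiautomated), c(0.87, 0.13, 0))
  sim <- simulate_study(cfg)
  expect_true(all(sim$dataset$items$auto_fndds ==
                    sim$dataset$items$served_fndds))

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 5, "beverages": ["sweet tea"]}', jpath)
  jcfg <- load_study_config(jpath)
  expect_identical(jcfg$beverages, "sweet tea")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("omision_rate: 0.5", bad)
  expect_error(load_study_config(bad), "unknown config field")

  invalid <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("match_probs:", "  automated: [0.5, 0.2, 0.2]"), invalid)
  expect_error(load_study_config(invalid), "summing to 1")
})

test_that("a single-group menu cannot supply intrusion codes", {
  cfg <- default_study_config(seed = 5)
  cfg$menu_table <- cfg$menu_table[major_group(cfg$menu_table$fndds) == 2, ]
  expect_error(simulate_study(cfg), "no intrusion candidate")
})
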