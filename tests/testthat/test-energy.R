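# two-meal dataset with fully controlled kcal per item
two_meal_dataset <- function() {
  rows <- dplyr::bind_rows(
    make_item(meal_id = "M1", item_id = "I01", item_name = "a",
              weighed_kcal = 100, auto_kcal = 150, semi_kcal = 100),
    make_item(meal_id = "M1", item_id = "I02", item_name = "b",
              weighed_kcal = 200, auto_kcal = 250, semi_kcal = 200),
    make_item(meal_id = "M2", item_id = "I01", item_name = "a",
              menu_type = "salad", served_fndds = "75113000",
              auto_fndds = "75113000", semi_fndds = "75113000",
              weighed_kcal = 400, auto_kcal = 400, semi_kcal = 500)
  )
  study_dataset(rows)
}

test_that("percent_error is the signed relative error in percent", {
  expect_identical(percent_error(100, 100), 0)
  expect_identical(percent_error(150, 100), 50)
  expect_identical(percent_error(75, 100), -25)
  expect_warning(out <- percent_error(50, 0), "weighed kcal = 0")
  expect_true(is.nan(out))
  # scale invariance
  set.seed(5)
  est <- runif(50, 50, 500); wt <- runif(50, 50, 500)
  expect_equal(percent_error(3.7 * est, 3.7 * wt), percent_error(est, wt))
})

test_that("meal_totals sums included items and flags bounds", {
  meals <- meal_totals(two_meal_dataset())
  m1 <- meals[meals$meal_id == "M1", ]
  expect_equal(m1$weighed_kcal_total, 300)
  expect_equal(m1$auto_kcal_total, 400)
  expect_equal(m1$pct_error_auto, 100 / 3, tolerance = 1e-12)
  expect_false(m1$within_25_auto)
  expect_equal(m1$pct_error_semi, 0)
  expect_true(m1$within_10_semi && m1$within_25_semi)
  m2 <- meals[meals$meal_id == "M2", ]
  expect_equal(m2$pct_error_semi, 25)
  expect_true(m2$within_25_semi) # closed boundary
  expect_false(m2$within_10_semi)
})

test_that("items omitted in either mode leave all three totals", {
  rows <- two_meal_dataset()$items
  # make item b a semiautomated-only omission (no nutrients for semi entry)
  rows$semi_nutrients_available[2] <- FALSE
  rows$semi_kcal[2] <- NA
  meals <- meal_totals(study_dataset(rows))
  m1 <- meals[meals$meal_id == "M1", ]
  expect_identical(m1$n_items, 1L)
  expect_equal(m1$weighed_kcal_total, 100)
  expect_equal(m1$auto_kcal_total, 150)

  # a meal with no included items is dropped with a warning
  rows2 <- two_meal_dataset()$items
  rows2$auto_scanned[3] <- FALSE
  rows2$auto_fndds[3] <- NA
  rows2$auto_kcal[3] <- NA
  rows2$semi_fndds[3] <- NA
  rows2$semi_kcal[3] <- NA
  expect_warning(meals2 <- meal_totals(study_dataset(rows2)),
                 "no included items")
  expect_identical(nrow(meals2), 1L)
})

test_that("meal totals conserve item kcal exactly", {
  sim <- small_sim()
  meals <- meal_totals(sim$dataset)
  items <- sim$dataset$items
  keep <- !dietvalidr:::omitted_items(items)
  by_hand <- tapply(items$weighed_kcal[keep],
                    paste(items$participant_id, items$meal_id)[keep], sum)
  expect_equal(as.numeric(by_hand[paste(meals$participant_id, meals$meal_id)]),
               meals$weighed_kcal_total)
})

test_that("elevation_of_means is the relative elevation of the mean total", {
  meals <- tibble::tibble(weighed_kcal_total = 577,
                          auto_kcal_total = 826, semi_kcal_total = 769)
  expect_equal(round_half_up(elevation_of_means(meals, "automated")), 43)
  expect_equal(round_half_up(elevation_of_means(meals, "semiautomated")), 33)
  meals2 <- tibble::tibble(weighed_kcal_total = 481,
                           auto_kcal_total = 560, semi_kcal_total = 683)
  expect_equal(round_half_up(elevation_of_means(meals2, "automated")), 16)
  expect_equal(elevation_of_means(
    tibble::tibble(weighed_kcal_total = 500, auto_kcal_total = 500),
    "automated"), 0)

  # algebraic identity with the ratio of sums
  sim_meals <- meal_totals(small_sim()$dataset)
  expect_equal(
    elevation_of_means(sim_meals, "automated"),
    100 * (sum(sim_meals$auto_kcal_total) - sum(sim_meals$weighed_kcal_total)) /
      sum(sim_meals$weighed_kcal_total)
  )
})

test_that("summarize_by_menu_type aggregates per-meal errors (mean-of-ratios)", {
  meals <- dplyr::bind_rows(
    meal_totals(two_meal_dataset()),
    meal_totals(two_meal_dataset()) |>
      dplyr::slice(1) |>
      dplyr::mutate(participant_id = "P02")
  )
  s <- summarize_by_menu_type(meals)
  hb <- s[s$stratum == "hamburger", ]
  expect_identical(hb$n, 2L)
  expect_equal(hb$pct_error_auto_mean, 100 / 3, tolerance = 1e-12)
  expect_equal(hb$pct_error_auto_sd, 0)
  expect_identical(s[s$stratum == "salad", ]$n, 1L)
  expect_true(is.na(s[s$stratum == "salad", ]$weighed_sd))

  errs <- tibble::tibble(
    participant_id = "P01", meal_id = c("M1", "M2", "M3"),
    menu_type = "pizza", menu_variant_kcal = 500L, n_items = 1L,
    weighed_kcal_total = 100,
    auto_kcal_total = c(100, 150, 50),
    semi_kcal_total = 100,
    pct_error_auto = c(0, 50, -50), pct_error_semi = 0,
    within_10_auto = c(TRUE, FALSE, FALSE), within_10_semi = TRUE,
    within_25_auto = c(TRUE, FALSE, FALSE), within_25_semi = TRUE
  )
  s2 <- summarize_by_menu_type(errs)
  expect_equal(s2$pct_error_auto_mean, 0)
  expect_identical(s2$within_25_auto_n, 1L)
  expect_equal(s2$within_25_auto_pct, 100 / 3)
})

test_that("summarize_by_food_group works at the item level", {
  rows <- dplyr::bind_rows(
    make_item(item_id = "I01", item_name = "a", weighed_kcal = 100,
              auto_kcal = 200, semi_kcal = 100),
    make_item(item_id = "I02", item_name = "b", weighed_kcal = 50,
              auto_kcal = 100, semi_kcal = 50),
    make_item(item_id = "I03", item_name = "c", served_fndds = "58106210",
              auto_fndds = "58106210", semi_fndds = "58106210",
              weighed_kcal = 86, auto_kcal = 88, semi_kcal = 86)
  )
  s <- summarize_by_food_group(study_dataset(rows))
  g2 <- s[s$group_id == 2, ]
  expect_equal(g2$pct_error_auto_mean, 100) # uniform x2 overestimation
  g5 <- s[s$group_id == 5, ]
  expect_equal(g5$pct_error_auto_mean, 100 * 2 / 86, tolerance = 1e-12)
  expect_identical(g5$within_10_auto_n, 1L)

  # beverage exclusion shrinks the milk and beverage groups
  sim <- small_sim()
  with_bev <- summarize_by_food_group(sim$dataset)
  no_bev <- summarize_by_food_group(sim$dataset, include_beverages = FALSE)
  bev_items <- sim$dataset$items[sim$dataset$items$is_beverage &
                                   !dietvalidr:::omitted_items(sim$dataset$items), ]
  bev_groups <- table(major_group(bev_items$served_fndds))
  n_in <- function(s, g) {
    n <- s$n[s$group_id == g]
    if (length(n) == 0) 0L else n # a fully-beverage group vanishes entirely
  }
  for (g in as.integer(names(bev_groups))) {
    expect_identical(n_in(with_bev, g) - n_in(no_bev, g),
                     as.integer(bev_groups[[as.character(g)]]))
  }
})
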