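#' Default study menus
#'
#' Ten menus: five meal types (chicken, hamburger, pizza, pork chop, salad),
#' each in a lower- and a higher-energy variant, with per-item target kcal
#' summing to the variant level. Levels span 400-800 kcal and 32 distinct
#' foods appear across the menus, including four beverages (1% milk,
#' Coca Cola, Diet Coke, sweet tea). Item kcal values are representative
#' menu-planning figures, not measurements; the generator perturbs them to
#' produce weighed values.
#'
#' @return A tibble: `menu_type`, `variant`, `menu_variant_kcal` (the
#'   variant's target level), `item_name`, `fndds`, `item_kcal`.
#' @export
default_menus <- function() {
  row <- function(type, variant, items) {
    tibble::tibble(
      menu_type = type, variant = variant,
      item_name = names(items),
      fndds = unname(vapply(items, `[[`, character(1), 1)),
      item_kcal = unname(vapply(items, function(x) as.numeric(x[[2]]), numeric(1)))
    )
  }
  menus <- dplyr::bind_rows(
    row("chicken", "low", list(
      "grilled chicken breast" = list("24122300", 160),
      "wild rice" = list("56205010", 120),
      "green beans" = list("75216110", 35),
      "hard butter" = list("81101000", 35),
      "sweet tea" = list("92302000", 90)
    )),
    row("chicken", "high", list(
      "grilled chicken breast" = list("24122300", 220),
      "wild rice" = list("56205010", 160),
      "dinner roll" = list("51320500", 105),
      "hard butter" = list("81101000", 70),
      "glazed carrots" = list("75124250", 65),
      "sweet tea" = list("92302000", 90)
    )),
    row("hamburger", "low", list(
      "cheeseburger" = list("27510170", 230),
      "french fries" = list("71401020", 110),
      "dill pickle" = list("75117020", 5),
      "Coca Cola" = list("92410310", 140)
    )),
    row("hamburger", "high", list(
      "cheeseburger" = list("27510170", 330),
      "french fries" = list("71401020", 160),
      "ketchup" = list("74401010", 20),
      "coleslaw" = list("75141000", 85),
      "Coca Cola" = list("92410310", 140)
    )),
    row("pizza", "low", list(
      "cheese pizza slice" = list("58106210", 250),
      "garden salad" = list("75113080", 30),
      "ranch dressing" = list("83107000", 120),
      "fruit cup" = list("63203010", 98),
      "Diet Coke" = list("92410340", 2)
    )),
    row("pizza", "high", list(
      "pepperoni pizza slice" = list("58106230", 300),
      "cheese pizza slice" = list("58106210", 250),
      "garden salad" = list("75113080", 30),
      "ranch dressing" = list("83107000", 120),
      "fruit cup" = list("63203010", 98),
      "Diet Coke" = list("92410340", 2)
    )),
    row("pork_chop", "low", list(
      "baked pork chop" = list("22210310", 180),
      "mashed potatoes" = list("71501010", 100),
      "steamed broccoli" = list("75109510", 30),
      "applesauce" = list("63101210", 55),
      "1% milk" = list("11112110", 105)
    )),
    row("pork_chop", "high", list(
      "baked pork chop" = list("22210310", 230),
      "mashed potatoes" = list("71501010", 130),
      "cornbread" = list("52101510", 150),
      "applesauce" = list("63101210", 70),
      "1% milk" = list("11112110", 105)
    )),
    row("salad", "low", list(
      "romaine lettuce" = list("75113000", 15),
      "cherry tomatoes" = list("74101010", 15),
      "grilled chicken strips" = list("24122120", 120),
      "shredded cheddar cheese" = list("14104100", 90),
      "italian dressing" = list("83102000", 100),
      "sweet tea" = list("92302000", 90)
    )),
    row("salad", "high", list(
      "romaine lettuce" = list("75113000", 20),
      "grilled chicken strips" = list("24122120", 160),
      "shredded cheddar cheese" = list("14104100", 110),
      "croutons" = list("51501010", 90),
      "italian dressing" = list("83102000", 110),
      "grapes" = list("63123000", 90),
      "sweet tea" = list("92302000", 90)
    ))
  )
  menus$fndds <- fndds_code(menus$fndds)
  menus |>
    dplyr::group_by(.data$menu_type, .data$variant) |>
    dplyr::mutate(menu_variant_kcal = as.integer(sum(.data$item_kcal)),
                  .after = "variant") |>
    dplyr::ungroup()
}

#' Default per-group multiplicative energy-error parameters
#'
#' Log-scale location (`mu`) and spread (`sigma`) of the multiplicative
#' log-normal error `estimated = weighed * exp(mu + sigma * Z)` per
#' logging mode and major food group. `mu` is set so that the *mean* error
#' ratio `exp(mu + sigma^2 / 2)` equals the targeted mean percent error
#' for the cell; the automated beverages-and-sweets cell (group 9) carries
#' extreme overestimation, and amorphous groups (vegetables, fats/oils)
#' carry high spread.
#'
#' @return A tibble: `mode`, `group_id`, `target_pct_error`, `sigma`, `mu`.
#' @export
default_energy_error <- function() {
  auto_pct <- c(-28, 60, 0, 0, 78, 6, 251, -22, 255)
  auto_sigma <- c(0.35, 0.60, 0.30, 0.30, 0.70, 0.30, 0.90, 0.80, 1.10)
  semi_pct <- c(9, 42, 0, 0, 102, 23, 65, 2, -10)
  semi_sigma <- c(0.35, 0.50, 0.25, 0.25, 0.80, 0.25, 0.60, 0.50, 0.50)
  out <- tibble::tibble(
    mode = rep(c("automated", "semiautomated"), each = 9L),
    group_id = rep(1:9, 2L),
    target_pct_error = c(auto_pct, semi_pct),
    sigma = c(auto_sigma, semi_sigma)
  )
  out$mu <- log(1 + out$target_pct_error / 100) - out$sigma^2 / 2
  out
}

#' Default study generator configuration
#'
#' The study conditions the generator emulates: 24 participants each
#' logging 2 meals drawn from the 10 default menus; overall match-category
#' probabilities of (0.46, 0.41, 0.13) over (exact, far, intrusion) for
#' automated logging and (0.87, 0.13, 0) for semiautomated logging; a 2%
#' omission rate; and the group-specific multiplicative energy-error model
#' of [default_energy_error()].
#'
#' @param seed Integer RNG seed stored in the config.
#' @return An object of class `generator_config` (a named list).
#' @export
default_study_config <- function(seed = 1L) {
  structure(
    list(
      n_participants = 24L,
      meals_per_participant = 2L,
      menu_table = default_menus(),
      match_probs = list(
        automated = c(exact = 0.46, far = 0.41, intrusion = 0.13),
        semiautomated = c(exact = 0.87, far = 0.13, intrusion = 0.00)
      ),
      omission_rate = 0.02,
      unscanned_share = 0.6,
      energy_error = default_energy_error(),
      error_model = "lognormal",
      additive_offset_kcal = c(automated = 50, semiautomated = 30),
      additive_sd_kcal = 20,
      semiautomated_coupling = 0.3,
      weighed_noise_sd = 0.05,
      beverages = default_beverages(),
      surveys = list(
        csuq_item_mean = 2.4, csuq_item_sd = 1.1,
        uss_item_means = c(4.1, 4.0, 4.2, 4.0, 5.5),
        uss_item_sds = c(1.3, 1.5, 1.4, 1.6, 0.7)
      ),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  n_menus <- nrow(dplyr::distinct(x$menu_table, .data$menu_type, .data$variant))
  cat(sprintf(
    "<generator_config> %d participants x %d meals, %d menus, %d distinct foods, seed %d\n",
    x$n_participants, x$meals_per_participant, n_menus,
    length(unique(x$menu_table$item_name)), x$seed
  ))
  invisible(x)
}

#' Load generator settings from a YAML or JSON file
#'
#' Reads a config file and applies it over [default_study_config()] (or
#' another base config). Recognised fields are the scalar generator
#' settings (`n_participants`, `meals_per_participant`, `omission_rate`,
#' `unscanned_share`, `semiautomated_coupling`, `weighed_noise_sd`,
#' `error_model`, `seed`), the `beverages` list, and `match_probs` as a
#' mapping from mode to a 3-vector over (exact, far, intrusion). Unknown
#' fields are an error, so typos do not silently keep defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Config to override; defaults to [default_study_config()].
#' @return A validated `generator_config`.
#' @export
load_study_config <- function(path, base = default_study_config()) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  scalar_fields <- c("n_participants", "meals_per_participant",
                     "omission_rate", "unscanned_share",
                     "semiautomated_coupling", "weighed_noise_sd",
                     "error_model", "seed")
  unknown <- setdiff(names(raw), c(scalar_fields, "beverages", "match_probs"))
  if (length(unknown) > 0) {
    stop("unknown config field(s) in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- base
  for (f in intersect(names(raw), scalar_fields)) {
    out[[f]] <- if (f %in% c("n_participants", "meals_per_participant", "seed")) {
      as.integer(raw[[f]])
    } else if (f == "error_model") as.character(raw[[f]]) else as.numeric(raw[[f]])
  }
  if (!is.null(raw$beverages)) out$beverages <- as.character(raw$beverages)
  for (m in names(raw$match_probs)) {
    p <- as.numeric(unlist(raw$match_probs[[m]]))
    out$match_probs[[m]] <- stats::setNames(p, c("exact", "far", "intrusion"))
  }
  validate_config(out)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  for (m in names(config$match_probs)) {
    p <- config$match_probs[[m]]
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("match_probs for mode '", m,
           "' must be 3 nonnegative probabilities summing to 1", call. = FALSE)
    }
  }
  stopifnot(
    config$omission_rate >= 0, config$omission_rate <= 1,
    all(config$energy_error$sigma >= 0),
    config$error_model %in% c("lognormal", "additive")
  )
  fndds_code(config$menu_table$fndds)
  invisible(config)
}

# candidate logged codes per served code: far = same first digit, different
# remainder; intrusion = different first digit. Built from the menu's own
# codes, padded with deterministic tail perturbations when a group has no
# alternative code.
build_code_pool <- function(menu_table) {
  codes <- unique(menu_table$fndds)
  groups <- major_group(codes)
  perturb_tail <- function(code) {
    tail <- substr(code, 2, 8)
    digits <- as.integer(strsplit(tail, "")[[1]])
    alt <- paste0(substr(code, 1, 1),
                  paste((digits + 3) %% 10, collapse = ""))
    alt
  }
  pool <- lapply(codes, function(cd) {
    g <- major_group(cd)
    far <- setdiff(codes[groups == g], cd)
    if (length(far) == 0) far <- perturb_tail(cd)
    intr <- codes[groups != g]
    if (length(intr) == 0) {
      stop("code pool has no intrusion candidate for code ", cd,
           " (menu uses a single food group)", call. = FALSE)
    }
    list(far = far, intrusion = intr)
  })
  names(pool) <- codes
  pool
}

# draw a logged code consistent with a match category
draw_code <- function(category, served, pool) {
  switch(as.character(category),
    exact = served,
    far = {
      cands <- pool[[served]]$far
      cands[sample.int(length(cands), 1L)]
    },
    intrusion = {
      cands <- pool[[served]]$intrusion
      cands[sample.int(length(cands), 1L)]
    },
    NA_character_
  )
}

error_lookup <- function(energy_error, mode, group_id) {
  idx <- match(paste(mode, group_id), paste(energy_error$mode, energy_error$group_id))
  if (anyNA(idx)) {
    stop("no energy-error parameters for mode '", mode, "', group(s) ",
         paste(unique(group_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  energy_error[idx, ]
}

draw_kcal <- function(config, mode, weighed, group_id) {
  n <- length(weighed)
  if (config$error_model == "lognormal") {
    par <- error_lookup(config$energy_error, mode, group_id)
    weighed * exp(stats::rnorm(n, par$mu, par$sigma))
  } else {
    pmax(0, weighed + config$additive_offset_kcal[[mode]] +
           stats::rnorm(n, 0, config$additive_sd_kcal))
  }
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic validation study
#'
#' Simulates the full laboratory protocol: participants are each assigned
#' `meals_per_participant` distinct menus at random; every served item gets
#' a weighed kcal (the menu figure with small multiplicative portioning
#' noise), an automated log entry, and a semiautomated log entry.
#'
#' Per item, the automated match category is drawn from the configured
#' category probabilities and a logged code consistent with that category
#' is drawn from the code pool; the estimated kcal applies the
#' group-specific multiplicative log-normal error to the weighed kcal
#' (or a constant additive offset under `error_model = "additive"`).
#' The semiautomated category is drawn from its own probability vector;
#' when both entries are exact, the semiautomated entry reuses the
#' automated kcal with probability `semiautomated_coupling`, modelling a
#' user who accepts a correct automated entry unchanged. A configured
#' fraction of items are omissions: either never scanned or logged without
#' nutrient information, in both cases carrying no estimated kcal in either
#' mode. Survey responses are integers drawn around the configured means
#' and truncated to the instrument range.
#'
#' Generation is a pure function of the config: the same config (including
#' its seed) always yields identical output, and the global RNG state is
#' left untouched.
#'
#' @param config A [default_study_config()], possibly modified.
#' @return A list with elements `dataset` (a [study_dataset()]), `surveys`
#'   (long response tibble), and `config`.
#' @export
simulate_study <- function(config = default_study_config()) {
  validate_config(config)
  with_preserved_rng(config$seed, {
    menus <- dplyr::distinct(config$menu_table, .data$menu_type, .data$variant)
    pool <- build_code_pool(config$menu_table)

    assignments <- lapply(seq_len(config$n_participants), function(p) {
      picks <- sample.int(nrow(menus), config$meals_per_participant)
      tibble::tibble(
        participant_id = sprintf("P%02d", p),
        meal_id = sprintf("M%d", seq_along(picks)),
        menu_type = menus$menu_type[picks],
        variant = menus$variant[picks]
      )
    }) |> dplyr::bind_rows()

    items <- assignments |>
      dplyr::inner_join(config$menu_table, by = c("menu_type", "variant"),
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$participant_id, .data$meal_id) |>
      dplyr::mutate(item_id = sprintf("I%02d", dplyr::row_number())) |>
      dplyr::ungroup()

    n <- nrow(items)
    group_id <- major_group(items$fndds)
    weighed <- items$item_kcal * exp(stats::rnorm(n, 0, config$weighed_noise_sd))
    weighed <- round(weighed, 1)

    cats <- c("exact", "far", "intrusion")
    auto_cat <- sample(cats, n, replace = TRUE, prob = config$match_probs$automated)
    semi_cat <- sample(cats, n, replace = TRUE, prob = config$match_probs$semiautomated)

    auto_code <- character(n)
    semi_code <- character(n)
    for (i in seq_len(n)) {
      auto_code[i] <- draw_code(auto_cat[i], items$fndds[i], pool)
      semi_code[i] <- draw_code(semi_cat[i], items$fndds[i], pool)
    }
    auto_kcal <- round(draw_kcal(config, "automated", weighed, group_id), 1)
    semi_kcal <- round(draw_kcal(config, "semiautomated", weighed, group_id), 1)

    keep_auto <- auto_cat == "exact" & semi_cat == "exact" &
      stats::runif(n) < config$semiautomated_coupling
    semi_kcal[keep_auto] <- auto_kcal[keep_auto]

    omitted <- stats::runif(n) < config$omission_rate
    unscanned <- omitted & stats::runif(n) < config$unscanned_share
    no_nutrients <- omitted & !unscanned

    scanned <- !unscanned
    auto_code[unscanned] <- NA_character_
    semi_code[unscanned] <- NA_character_
    auto_nutr <- !no_nutrients
    semi_nutr <- !no_nutrients
    blank <- unscanned | no_nutrients
    auto_kcal[blank] <- NA_real_
    semi_kcal[blank] <- NA_real_

    out_items <- tibble::tibble(
      participant_id = items$participant_id,
      meal_id = items$meal_id,
      menu_type = items$menu_type,
      menu_variant_kcal = items$menu_variant_kcal,
      item_id = items$item_id,
      item_name = items$item_name,
      served_fndds = items$fndds,
      weighed_kcal = weighed,
      weighed_grams = round(weighed / 1.8, 1),
      is_beverage = items$item_name %in% config$beverages,
      auto_scanned = scanned,
      auto_fndds = auto_code,
      auto_kcal = auto_kcal,
      auto_nutrients_available = auto_nutr,
      semi_fndds = semi_code,
      semi_kcal = semi_kcal,
      semi_nutrients_available = semi_nutr
    )

    surveys <- simulate_surveys(config)

    list(
      dataset = study_dataset(out_items, beverages = config$beverages),
      surveys = surveys,
      config = config
    )
  })
}

# integer Likert draws around a target mean, truncated to the scale
draw_likert <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(stats::rnorm(n, mean, sd)))))
}

simulate_surveys <- function(config) {
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  sv <- config$surveys
  csuq <- tidyr::expand_grid(participant_id = ids, item_number = 1:19) |>
    dplyr::mutate(
      instrument = "CSUQ",
      score = draw_likert(dplyr::n(), sv$csuq_item_mean, sv$csuq_item_sd, 1L, 7L)
    )
  uss <- tidyr::expand_grid(participant_id = ids, item_number = 1:5) |>
    dplyr::mutate(
      instrument = "USS",
      score = draw_likert(dplyr::n(), sv$uss_item_means[.data$item_number],
                          sv$uss_item_sds[.data$item_number], 1L, 6L)
    )
  dplyr::bind_rows(csuq, uss) |>
    dplyr::select("participant_id", "instrument", "item_number", "score")
}

#' Append the worked classification examples
#'
#' Adds four labelled fixture items to a dataset — a cheeseburger served
#' four times and logged as a cheeseburger (exact match), a turkey burger
#' (far match), a croissant sandwich (intrusion), and not scanned at all
#' (omission) — so that the classifier's reference behaviour can be
#' regression-tested inside any dataset.
#'
#' @param ds A [study_dataset()].
#' @return A new [study_dataset()] with four extra items under participant
#'   `"EXAMPLE"`.
#' @export
inject_worked_examples <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  logged <- c("27510170", "27545110", "58127310", NA)
  scanned <- c(TRUE, TRUE, TRUE, FALSE)
  ex <- tibble::tibble(
    participant_id = "EXAMPLE",
    meal_id = "M1",
    menu_type = "hamburger",
    menu_variant_kcal = 735L,
    item_id = sprintf("X%02d", 1:4),
    item_name = "cheeseburger",
    served_fndds = "27510170",
    weighed_kcal = 330,
    weighed_grams = NA_real_,
    is_beverage = FALSE,
    auto_scanned = scanned,
    auto_fndds = logged,
    auto_kcal = ifelse(scanned, 350, NA_real_),
    auto_nutrients_available = scanned,
    semi_fndds = ifelse(scanned, "27510170", NA),
    semi_kcal = ifelse(scanned, 340, NA_real_),
    semi_nutrients_available = scanned
  )
  out <- ds
  out$items <- dplyr::bind_rows(ds$items, ex)
  out
}
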