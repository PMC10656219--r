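survey_spec <- function(instrument) {
  switch(instrument,
    CSUQ = list(n_items = 19L, lo = 1L, hi = 7L),
    USS = list(n_items = 5L, lo = 1L, hi = 6L),
    stop("unknown instrument: ", instrument, call. = FALSE)
  )
}

# wide participant x item matrix for one instrument, validating ranges;
# participants with missing or out-of-range items are dropped with a warning
survey_matrix <- function(responses, instrument) {
  spec <- survey_spec(instrument)
  resp <- responses[responses$instrument == instrument, ]
  if (nrow(resp) == 0) {
    return(matrix(integer(), nrow = 0, ncol = spec$n_items))
  }
  if (any(resp$item_number < 1 | resp$item_number > spec$n_items)) {
    stop(instrument, " responses contain item numbers outside 1..",
         spec$n_items, call. = FALSE)
  }
  wide <- resp |>
    dplyr::select("participant_id", "item_number", "score") |>
    tidyr::pivot_wider(names_from = "item_number", values_from = "score") |>
    dplyr::arrange(.data$participant_id)
  absent <- setdiff(as.character(seq_len(spec$n_items)), names(wide))
  if (length(absent) > 0) {
    stop(instrument, " responses lack item number(s) ",
         paste(absent, collapse = ", "), " for every participant",
         call. = FALSE)
  }
  mat <- as.matrix(wide[as.character(seq_len(spec$n_items))])
  rownames(mat) <- wide$participant_id
  ok <- apply(mat, 1, function(r) {
    !anyNA(r) && all(r >= spec$lo & r <= spec$hi)
  })
  if (!all(ok)) {
    warning(sum(!ok), " participant(s) excluded from ", instrument,
            ": missing or out-of-range item scores", call. = FALSE)
  }
  mat[ok, , drop = FALSE]
}

#' Score the Computer Systems Usability Questionnaire
#'
#' The CSUQ has 19 items on a 7-point scale (lower is more favorable). Each
#' participant's overall usability is the mean of their 19 item scores; the
#' reported overall score is the mean and SD of those per-participant means.
#' Per-item means across participants and the standard three subscales
#' (system usefulness: items 1-8; information quality: items 9-15;
#' interface quality: items 16-18) are also returned.
#'
#' @param responses Long response tibble (see [read_surveys()]).
#' @return A tibble of scores: `instrument`, `item_label`, `n`, `mean`, `sd`,
#'   with rows for `"overall"`, each subscale, and each item.
#' @export
score_csuq <- function(responses) {
  mat <- survey_matrix(responses, "CSUQ")
  if (nrow(mat) == 0) {
    return(tibble::tibble(instrument = character(), item_label = character(),
                          n = integer(), mean = double(), sd = double()))
  }
  participant_overall <- unname(rowMeans(mat))
  subscales <- list(
    "system usefulness" = 1:8,
    "information quality" = 9:15,
    "interface quality" = 16:18
  )
  rows <- list(
    tibble::tibble(item_label = "overall", n = nrow(mat),
                   mean = mean(participant_overall),
                   sd = stats::sd(participant_overall))
  )
  for (nm in names(subscales)) {
    ss <- unname(rowMeans(mat[, subscales[[nm]], drop = FALSE]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      item_label = nm, n = nrow(mat), mean = mean(ss), sd = stats::sd(ss)
    )
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    item_label = paste0("item_", seq_len(ncol(mat))),
    n = nrow(mat),
    mean = unname(colMeans(mat)),
    sd = unname(apply(mat, 2, stats::sd))
  )
  dplyr::bind_rows(rows) |>
    dplyr::mutate(instrument = "CSUQ", .before = 1)
}

#' Score the User Satisfaction Survey
#'
#' The USS has 5 quantitative items on a 6-point scale (higher is more
#' favorable); each question is reported as its mean and SD across
#' participants. No overall composite is defined for this instrument.
#'
#' @param responses Long response tibble (see [read_surveys()]).
#' @param labels Optional character vector of 5 question labels.
#' @return A tibble of per-question scores: `instrument`, `item_label`,
#'   `n`, `mean`, `sd`.
#' @export
score_uss <- function(responses, labels = uss_question_labels()) {
  mat <- survey_matrix(responses, "USS")
  stopifnot(length(labels) == 5L)
  if (nrow(mat) == 0) {
    return(tibble::tibble(instrument = character(), item_label = character(),
                          n = integer(), mean = double(), sd = double()))
  }
  tibble::tibble(
    instrument = "USS",
    item_label = labels,
    n = nrow(mat),
    mean = unname(colMeans(mat)),
    sd = unname(apply(mat, 2, stats::sd))
  )
}

#' USS question labels
#' @return Character vector of the five quantitative USS questions.
#' @export
uss_question_labels <- function() {
  c(
    "satisfaction with identifying the food provided",
    "satisfaction with estimating the amount of food provided",
    "ease of identifying the food provided",
    "ease of estimating the amount of food provided",
    "helpfulness of training for using the app"
  )
}
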