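#' Bland-Altman agreement analysis with proportional-bias test
#'
#' Differences are `estimated - weighed`; limits of agreement are the mean
#' difference +/- `loa_multiplier` standard deviations (n - 1). Proportional
#' bias is assessed by ordinary least squares of the difference on the pair
#' mean `(estimated + weighed) / 2`, with a two-sided t test on the slope:
#' a positive slope means larger units carry larger error.
#'
#' @param weighed,estimated Numeric kcal vectors of equal length, n >= 3.
#' @param loa_multiplier SD multiplier for the limits of agreement
#'   (conventional 1.96).
#' @return An object of class `bland_altman`: a list with `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `bias_slope`, `bias_intercept`,
#'   `bias_p`, `bias_r2`. When the pair means are constant the bias
#'   regression is undefined and those four fields are `NA` (the mean
#'   difference and limits are still returned).
#' @examples
#' w <- c(400, 500, 600, 700)
#' bland_altman(w, w + 50)
#' @export
bland_altman <- function(weighed, estimated, loa_multiplier = 1.96) {
  stopifnot(length(weighed) == length(estimated), length(weighed) >= 3,
            !anyNA(weighed), !anyNA(estimated))
  d <- estimated - weighed
  m <- (estimated + weighed) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  out <- list(
    n = length(d),
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    loa_low = mean_diff - loa_multiplier * sd_diff,
    loa_high = mean_diff + loa_multiplier * sd_diff,
    loa_multiplier = loa_multiplier,
    bias_slope = NA_real_, bias_intercept = NA_real_,
    bias_p = NA_real_, bias_r2 = NA_real_
  )
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)
    out$bias_slope <- unname(stats::coef(fit)[2])
    out$bias_intercept <- unname(stats::coef(fit)[1])
    out$bias_p <- unname(sm$coefficients[2, 4])
    out$bias_r2 <- sm$r.squared
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean difference: %.1f kcal (SD %.1f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.1f, %.1f] (+/- %.2f SD)\n",
              x$loa_low, x$loa_high, x$loa_multiplier))
  if (is.na(x$bias_slope)) {
    cat("  proportional bias: undefined (constant pair means)\n")
  } else {
    cat(sprintf("  proportional bias: slope %.3f, R^2 %.3f, p %.3g\n",
                x$bias_slope, x$bias_r2, x$bias_p))
  }
  invisible(x)
}

#' Calibration regression of estimated on weighed energy
#'
#' Ordinary least squares `estimated = intercept + slope * weighed`, the
#' "for every 1 kcal served, the app logged `slope` kcal" summary. Reports
#' the slope, intercept, coefficient of determination, and the two-sided
#' t-test p-value on the slope.
#'
#' @param weighed,estimated Numeric kcal vectors of equal length, n >= 3;
#'   `weighed` must not be constant.
#' @return An object of class `calibration_fit`: list with `n`, `slope`,
#'   `intercept`, `r2`, `slope_p`.
#' @export
calibration_ols <- function(weighed, estimated) {
  stopifnot(length(weighed) == length(estimated), length(weighed) >= 3,
            !anyNA(weighed), !anyNA(estimated))
  if (stats::var(weighed) == 0) {
    stop("degenerate calibration fit: weighed energy has zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(estimated ~ weighed)
  sm <- summary(fit)
  structure(
    list(
      n = length(weighed),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = sm$r.squared,
      slope_p = unname(sm$coefficients[2, 4])
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration OLS (n = %d): est = %.1f + %.3f * weighed, R^2 = %.3f, slope p = %.3g\n",
    x$n, x$intercept, x$slope, x$r2, x$slope_p
  ))
  invisible(x)
}

#' Agreement analyses for every mode x beverage cell
#'
#' Runs [bland_altman()] and [calibration_ols()] on the per-meal totals for
#' each of the four analysis cells: automated / semiautomated crossed with
#' beverages included / excluded.
#'
#' @param ds A [study_dataset()].
#' @param loa_multiplier Passed to [bland_altman()].
#' @return A named list of four cells (`automated_with_beverages`, ...),
#'   each a list with elements `bland_altman` and `calibration`.
#' @export
agreement_suite <- function(ds, loa_multiplier = 1.96) {
  cells <- expand.grid(
    mode = c("automated", "semiautomated"),
    beverages = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(cells)), function(i) {
    meals <- meal_totals(ds, include_beverages = cells$beverages[i])
    est <- if (cells$mode[i] == "automated") meals$auto_kcal_total else meals$semi_kcal_total
    list(
      bland_altman = bland_altman(meals$weighed_kcal_total, est, loa_multiplier),
      calibration = calibration_ols(meals$weighed_kcal_total, est)
    )
  })
  names(out) <- paste0(
    cells$mode,
    ifelse(cells$beverages, "_with_beverages", "_without_beverages")
  )
  out
}
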