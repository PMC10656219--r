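---
title: "Validating automated dietary assessment against weighed food records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated dietary assessment against weighed food records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dietvalidr)
```

## The problem

Mobile apps that identify foods and estimate portions from a short video
scan promise low-burden dietary assessment, but their output has to be
validated against a criterion method before the numbers can be trusted.
The reference design this package analyses is a laboratory
meal-provision study: participants are served meals whose components have
been covertly weighed (so the true energy content is known to the kitchen
only), and each served item is logged twice with the app — once using the
automated computer-vision estimate as-is, and once after the participant
corrects the food identity and portion (the *semiautomated* estimate).
Study staff assign an 8-digit FNDDS (USDA Food and Nutrient Database for
Dietary Studies) code to every served food and to every logged food, which
turns "did the app recognise the food?" into a comparison of hierarchical
codes.

`dietvalidr` implements the full analysis of such a study — food
identification accuracy, energy estimation error, method agreement, and
usability scoring — plus a seeded synthetic generator of the study design
so that every stage is testable without access to participant data.

## Match classification

FNDDS codes are 8 decimal digits; the first digit is the major food group
(1 = milk and milk products, 2 = meat/poultry/fish and mixtures, ...,
9 = sugars, sweets, and beverages). For each served/logged pair
`classify_match()` assigns exactly one of four categories:

* **exact match** — all 8 digits agree;
* **far match** — only the first digit agrees (right food group, wrong
  food);
* **intrusion** — the first digit differs (wrong food group);
* **omission** — the item was never scanned, no code was logged, or the
  logged food had no nutrient information in the app.

```{r}
classify_match(
  served = rep("27510170", 4), # cheeseburger
  logged = c("27510170", "27545110", "58127310", NA),
  scanned = c(TRUE, TRUE, TRUE, FALSE)
)
```

The categories are mutually exclusive by construction: "far" excludes
"exact", and every classified (non-omitted) item is exactly one of
exact/far/intrusion, so the three counts always sum to the stratum size.
`tabulate_matches()` computes counts and percentages per stratum
(overall, by meal type, or by the served code's food group), excluding
omissions from the denominator. Percentages are kept raw in machine
output; display output rounds half *away from zero* (`round_half_up()`),
the convention the report tables use — base R's banker's rounding would
turn 26.53% into 27% but 86.5% into 86%.

Codes are stored as strings throughout, never integers: positions 2–8 may
hold meaningful zeros and the digit positions carry the hierarchy.

## Comparing the two logging modes

Whether user correction improves identification is a paired question:
each item has a category under both modes. `paired_proportions_test()`
forms, per item, the indicator of membership in a category under each
mode and tests the discordant counts *b* (automated only) and *c*
(semiautomated only) with McNemar's test. The default is the exact
binomial version — `min(b, c)` referred to Binomial(b + c, 1/2),
two-sided — which is preferable at the discordance counts a 260-item
study produces; `method = "auto"` switches to the continuity-corrected
chi-square statistic when b + c > 25, and the method used is always
recorded in the output. Items omitted in either mode are dropped from the
pair set. When b + c = 0 the test is degenerate and reported as p = 1
with a flag.

## Energy error

Percent error for an estimate is signed and relative:

```
percent error = 100 * (estimated kcal - weighed kcal) / weighed kcal
```

so overestimation is positive. Two aggregation conventions both appear in
validation reports and are deliberately kept as distinct operations:

* **mean of per-meal errors** (`summarize_by_menu_type()`): each meal's
  percent error is computed first, then averaged within a stratum — the
  "% error mean ± SD" of the stratified tables;
* **elevation of means** (`elevation_of_means()`):
  `100 * (mean(estimated) - mean(weighed)) / mean(weighed)`, the headline
  "estimates were X% higher" figure, algebraically the ratio of summed
  totals.

They agree only when all weighed totals are equal, so conflating them
misreads the results. Concordance is summarised as the share of meals
(or items) within ±10% and ±25%; the bounds are closed (|error| ≤ b
counts as within — the boundary convention is not observable in rounded
report tables, so the inclusive choice is fixed and documented here).

Meal totals (`meal_totals()`) exclude an item from *all three* totals
(weighed, automated, semiautomated) if it is an omission in *either*
mode, so the modes are always compared on identical item sets. For the
identification tables, by contrast, omissions are excluded mode-wise,
since each mode's denominator is its own classified items.

Beverage exclusion (`exclude_beverages()`) removes a configured list of
item names — by default 1% milk, Coca Cola, Diet Coke, and sweet tea —
rather than an FNDDS-group rule, because group 9 also holds non-beverage
sweets and group 1 non-beverage dairy. Automated estimation of beverages
in unmarked transparent cups is essentially unconstrained visually, and
the with/without-beverages contrast isolates how much of the total error
they drive.

## Agreement analyses

`bland_altman()` assesses agreement on per-meal totals: differences
(estimated − weighed) against pair means, with limits of agreement at the
mean difference ± 1.96 SD (the conventional multiplier; configurable).
Proportional bias — error growing with meal size — is tested by OLS of
the difference on the pair mean with a two-sided t test on the slope.
The regression of difference on mean is the standard Bland–Altman bias
specification; regressing on the criterion alone is an alternative some
studies use, so the convention is fixed here and stated. When the pair
means are constant the bias regression is undefined and reported as `NA`
while the mean difference and limits are still returned.

`calibration_ols()` fits `estimated = intercept + slope * weighed`, the
"for every 1 kcal served, the app logged `slope` kcal" summary, with R²
and the slope's p-value. Both analyses are unadjusted for repeated meals
within participant: with 2 meals per participant and randomized menu
assignment the within-participant correlation of meal-level error is
expected to be small, and an unadjusted fit keeps the estimand identical
to the simple published quantity; users who want cluster robustness can
aggregate per participant before calling these functions.

## Usability instruments

`score_csuq()` scores the 19-item Computer Systems Usability
Questionnaire (7-point scale, lower more favorable): each participant's
overall usability is the mean of their 19 items, and the reported score is
the mean ± SD of those per-participant means. The standard subscales
(system usefulness 1–8, information quality 9–15, interface quality
16–18) are computed as well. No reverse-scored items are assumed; if an
administration reverses items, recode before scoring. `score_uss()`
scores the 5 quantitative User Satisfaction Survey items (6-point scale,
higher more favorable) per question; the instrument defines no overall
composite. Participants with missing or out-of-range responses are
excluded with a warning rather than imputed.

## The synthetic study generator

`simulate_study()` emulates the study design end-to-end so the pipeline
is testable without participant data. The defaults in
`default_study_config()` are the study conditions:

* 24 participants × 2 meals, drawn without replacement per participant
  from 10 menus (5 meal types × low/high energy variant, totals spanning
  400–800 kcal, e.g. the pizza menu at 500 and 800 kcal), 32 distinct
  foods including the four beverages — about 260 item records per run;
* overall match-category probabilities (exact, far, intrusion) of
  (0.46, 0.41, 0.13) for automated and (0.87, 0.13, 0) for semiautomated
  logging;
* an omission rate of 0.02, split between never-scanned items and items
  logged without nutrient information (both leave no usable kcal in
  either mode);
* weighed kcal = menu kcal × exp(N(0, 0.05)) — small portioning noise
  around the menu target;
* estimated kcal = weighed × exp(μ + σZ), with (μ, σ) per logging mode ×
  food group (`default_energy_error()`). μ is parameterised so the *mean*
  error ratio exp(μ + σ²/2) matches the targeted mean percent error of
  that cell; the automated beverage cell carries extreme overestimation
  (+255% mean) and amorphous groups (vegetables, fats/oils/dressings)
  carry wide spread.

Far-match codes are drawn from same-group menu codes (or a deterministic
tail perturbation when a group has a single code) and intrusions from
other-group codes, so generated codes always classify back into the
category they were sampled from. When both modes draw "exact" for an
item, the semiautomated entry reuses the automated kcal with probability
`semiautomated_coupling` (default 0.3) — a user accepting a correct
automated entry unchanged. The category itself is never resampled, so the
configured marginals hold exactly; the coupling only mixes the automated
error into the semiautomated kcal for that subset.

The multiplicative log-normal error makes estimates positive by
construction and makes the absolute error grow with meal energy, so
significant proportional bias emerges naturally in the Bland–Altman
analysis — the qualitative signature of the reference study. An
`error_model = "additive"` switch (constant kcal offset per item) is
provided as a null model under which the item-level bias slope is zero.

**What the generator does not emulate.** Within a food group, the error
ratio is independent of item size. Real data concentrate the largest
relative errors on small-kcal items (a 20-kcal lettuce estimated at 80
kcal), which is why a study can report item-level group mean errors in
the hundreds of percent while the kcal-weighted meal-level elevation of
means stays near 40%. Simulated data reproduce the per-group item-level
error structure, so their meal-level elevation runs higher than a real
study's headline figure. Passing tests on simulated data therefore
demonstrate correctness of the *analysis* (classification, pairing,
aggregation, agreement statistics), not that the generator is a
statistical twin of any particular dataset. Menu compositions are
likewise representative placeholders at the stated energy levels, not
replicas of any kitchen's recipes. Surveys are sampled independently per
item around configured means, with truncation to the scale — means near
the scale ends shrink slightly toward the centre.

Generation is a pure function of the config: the same seed yields
byte-identical output and the global RNG state is restored afterwards.

## Numerical and design choices

* **Rounding**: half away from zero for display percentages; raw values
  in all machine output.
* **Bounds**: closed (≤), at ±10% and ±25% by default; configurable.
* **Paired test**: exact binomial by default; chi-square with continuity
  correction optionally or automatically above 25 discordant pairs.
* **Limits of agreement**: 1.96 SD, not t-based; configurable multiplier.
* **Degenerate inputs**: zero weighed kcal gives an undefined percent
  error (NaN, excluded from means with a warning); empty strata report
  n = 0 with NaN percentages rather than erroring; meals whose items are
  all omitted are dropped with a warning; constant pair means disable the
  bias regression only.
* **Keys**: (participant, meal, item) uniquely identify a record; mixed
  dishes logged as components are separate records sharing a meal, with
  the component index embedded in `item_id`.

## Problem sizes used in the test suite

Unit and property tests run on hand-built fixtures of 3–200 items and on
the default 24-participant simulation. Parameter-recovery tests scale the
generator to 1,200 participants (~13,000 items) and check category
marginals within 3-sigma binomial bounds and per-cell log-bias recovery
within 3σ/√n; the full suite completes in well under a minute.

## Limitations

The package analyses served-versus-logged validation data; it does not
model the vision pipeline, consult any nutrient database, or handle
free-living (non-provisioned) logging where the true intake is unknown.
Statistical comparisons are unadjusted for participant clustering, as
discussed above. The CSUQ subscale groupings follow the standard 19-item
layout and should be re-checked if a variant administration is used.
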