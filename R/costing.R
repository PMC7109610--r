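# Costing engine: converts respondent-wave survey answers into monetized
# quarterly cost breakdowns (microcosting: every consumed resource is priced
# per unit), aggregates cohorts, and annualizes. All internal arithmetic is
# unrounded; rounding to cents happens only when results are displayed or
# written.

#' Reporting-period conventions
#'
#' The engine reports costs per quarter. A quarter is 91.25 days (365/4) for
#' recall scaling of count items and 13 whole weeks for weekly-rate items
#' (care hours, working hours); both conventions are configurable here.
#'
#' @param quarter_days Days per quarter used for recall scaling.
#' @param weeks_per_quarter Weeks per quarter used for weekly-rate items.
#' @param quarters_per_year Quarters per year used for annualization.
#' @return A validated list of class `mshrs_period`.
#' @export
period_model <- function(quarter_days = 91.25, weeks_per_quarter = 13,
                         quarters_per_year = 4) {
  check_number(quarter_days, "quarter_days", lower = 1)
  check_number(weeks_per_quarter, "weeks_per_quarter", lower = 1)
  check_number(quarters_per_year, "quarters_per_year", lower = 1)
  if (weeks_per_quarter * 7 > 92) {
    stop_mshrs("weeks_per_quarter x 7 must not exceed 92 days.", "mshrs_config_error")
  }
  structure(list(quarter_days = quarter_days,
                 weeks_per_quarter = weeks_per_quarter,
                 quarters_per_year = quarters_per_year),
            class = "mshrs_period")
}

#' Scale a reported quantity to the quarterly reporting window
#'
#' Survey items may be reported over recall windows of different lengths
#' (never more than 12 months); quantities are rescaled proportionally to
#' the quarter before pricing: `quantity * quarter_days / recall_days`.
#'
#' @param quantity Reported quantity (vectorized).
#' @param recall_days Recall-window length in days, in (0, 365].
#' @param period A [period_model()].
#' @return Per-quarter quantity.
#' @export
recall_scale <- function(quantity, recall_days, period = period_model()) {
  if (any(is.na(recall_days)) || any(recall_days <= 0 | recall_days > 365)) {
    stop_mshrs("recall_days must lie in (0, 365]: the recall window never exceeds 12 months.",
               "mshrs_recall_error")
  }
  quantity * period$quarter_days / recall_days
}

# component costs -------------------------------------------------------------

#' Quarterly cost of informal care
#'
#' Unpaid assistance by family and friends, valued by opportunity cost at the
#' configured hourly rate with hours capped at the policy maximum
#' (60 h/week under the default tables).
#'
#' @param hours_per_week Reported informal-care hours per week (vectorized).
#' @param val An `mshrs_valuation` object.
#' @param period A [period_model()].
#' @return EUR per quarter.
#' @export
informal_care_cost <- function(hours_per_week, val = mshrs_valuation(),
                               period = period_model()) {
  if (any(hours_per_week < 0, na.rm = TRUE)) {
    stop_mshrs("Care hours must be nonnegative.", "mshrs_range_error")
  }
  cap <- val$labor_market$informal_care_cap_hours_per_week
  pmin(hours_per_week, cap) * val$unit_costs$informal_care_per_hour *
    period$weeks_per_quarter
}

#' Quarterly cost of absenteeism (sick leave)
#'
#' Human-capital valuation: each sick day is a lost working day worth
#' `annual_work_hours / annual_work_days * hourly_labor_cost` (any hour not
#' worked is considered lost).
#'
#' @param sick_days Sick days in the quarter (vectorized); must not exceed
#'   the working days in a quarter.
#' @param val An `mshrs_valuation` object.
#' @return EUR per quarter, unrounded.
#' @export
absenteeism_cost <- function(sick_days, val = mshrs_valuation()) {
  if (any(sick_days < 0, na.rm = TRUE)) {
    stop_mshrs("Sick days must be nonnegative.", "mshrs_range_error")
  }
  max_days <- val$labor_market$annual_work_days / 4
  if (any(sick_days > max_days, na.rm = TRUE)) {
    stop_mshrs(sprintf("Sick days exceed the %.2f working days in a quarter.", max_days),
               "mshrs_range_error")
  }
  sick_days * sick_leave_per_day(val)
}

#' Quarterly cost of disability pension (occupational disability)
#'
#' Product of the disability percentage and the annual full-disability value
#' (daily wage x working days), capped at the configured annual maximum and
#' divided evenly over the year's quarters; at 100% the annualized value
#' equals the cap exactly.
#'
#' @param pct Disability pension percentage in \[0, 100\] (vectorized).
#' @param val An `mshrs_valuation` object.
#' @param period A [period_model()].
#' @return EUR per quarter.
#' @export
disability_pension_cost <- function(pct, val = mshrs_valuation(),
                                    period = period_model()) {
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop_mshrs("Disability percentage must lie in [0, 100].", "mshrs_range_error")
  }
  (pct / 100) * val$unit_costs$disability_pension_cap_per_year /
    period$quarters_per_year
}

#' Quarterly cost of presenteeism (reduced productivity at work)
#'
#' The 0-10 Likert answer maps linearly to a lost-productivity fraction
#' (score/10). The base is the hours actually attended in the quarter --
#' contracted weekly hours times weeks per quarter, net of sick days (one
#' sick day = `weekly_work_hours / standard_week_days` contracted hours) --
#' so presenteeism never double-counts absenteeism. Lost hours are valued at
#' the average hourly labor cost.
#'
#' @param score Likert answer 0-10 (vectorized).
#' @param weekly_work_hours Contracted working hours per week.
#' @param sick_days Sick days in the quarter (default 0).
#' @param val An `mshrs_valuation` object.
#' @param period A [period_model()].
#' @return EUR per quarter.
#' @export
presenteeism_cost <- function(score, weekly_work_hours, sick_days = 0,
                              val = mshrs_valuation(), period = period_model()) {
  if (any(score < 0 | score > 10 | score != floor(score), na.rm = TRUE)) {
    stop_mshrs("Presenteeism score must be an integer in 0..10.", "mshrs_range_error")
  }
  if (any(weekly_work_hours < 0, na.rm = TRUE)) {
    stop_mshrs("Weekly working hours must be nonnegative.", "mshrs_range_error")
  }
  lm <- val$labor_market
  attended <- pmax(0, weekly_work_hours * period$weeks_per_quarter -
                        sick_days * weekly_work_hours / lm$standard_week_days)
  (score / 10) * attended * lm$hourly_labor_cost
}

#' Quarterly cost of a disease-modifying therapy
#'
#' DMTs are priced annually (defined daily dose net cost x 365); the
#' quarterly share is the annual value divided by the quarters per year.
#'
#' @param dmt_name DMT code or `"none"` (vectorized).
#' @param year Calendar year used for the price lookup.
#' @param val An `mshrs_valuation` object.
#' @param period A [period_model()].
#' @return EUR per quarter (0 for `"none"`).
#' @export
dmt_cost_quarter <- function(dmt_name, year, val = mshrs_valuation(),
                             period = period_model()) {
  vapply(dmt_name, function(d) {
    if (is.na(d) || identical(d, "none")) return(0)
    dmt_annual_cost(val, d, year) / period$quarters_per_year
  }, numeric(1), USE.NAMES = FALSE)
}

# full breakdown --------------------------------------------------------------

#' Names of the monetized cost components of a breakdown
#'
#' @param include_dmt Include the DMT component.
#' @return Character vector of component column names, grouped by domain:
#'   direct medical, direct nonmedical, indirect.
#' @export
mshrs_cost_components <- function(include_dmt = TRUE) {
  c("inpatient", "day_admission", "consultations", "examinations", "otc",
    "consumables", "professional_care", if (include_dmt) "dmt", "investments",
    "informal_care", "absenteeism", "disability_pension", "presenteeism")
}

sum_observed <- function(m) {
  # row sums over observed components; NA only when every component is NA
  out <- rowSums(m, na.rm = TRUE)
  out[rowSums(!is.na(m)) == 0L] <- NA_real_
  out
}

priced_group <- function(df, prefix, keys, rates, scale) {
  # recall-scale then price a map-valued item group; sums observed sub-items,
  # NA when all sub-items of the group are unanswered
  cols <- paste0(prefix, keys)
  m <- as.matrix(df[, cols, drop = FALSE])
  priced <- sweep(m * scale, 2L, rates, `*`)
  out <- sum_observed(priced)
  list(cost = out, any_missing = rowSums(is.na(m)) > 0L)
}

#' Monetize a table of survey responses into quarterly cost breakdowns
#'
#' The core scoring operation: for each respondent-wave row, count items are
#' recall-scaled to the quarter and priced per unit, weekly-rate items are
#' priced per hour over the quarter's weeks, out-of-pocket expenditures pass
#' through as reported (indexated to the valuation's reference year), and
#' productivity losses are valued by the human-capital approach. Components
#' are grouped into direct medical (excluding DMT by convention), direct
#' nonmedical, and indirect costs.
#'
#' Unanswered items propagate as `NA` components; subtotals and totals are
#' computed over the observed components only (no imputation) and the
#' logical `complete` column flags rows with no unanswered item.
#'
#' @param responses Respondent-wave tibble (see [read_responses()]).
#' @param val An `mshrs_valuation` object.
#' @param dmt_year Calendar year for DMT price lookup; defaults to the year
#'   of each row's `assessment_date` (clamped to the DMT table's coverage,
#'   with indexation from the nearest covered year).
#' @param period A [period_model()].
#' @param include_dmt Price the DMT component (`TRUE`) or force it to zero.
#' @return A tibble, one row per input row: identifier columns, one column
#'   per component (see [mshrs_cost_components()]), subtotals
#'   `direct_medical_excl_dmt`, `direct_nonmedical`, `indirect`, totals
#'   `total_excl_dmt`, `total_incl_dmt`, `period` (`"quarter"`), `complete`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 5), seed = 1)
#' cost_responses(coh)
#' @export
cost_responses <- function(responses, val = mshrs_valuation(), dmt_year = NULL,
                           period = period_model(), include_dmt = TRUE) {
  df <- as_tibble(responses)
  n <- nrow(df)
  if (n == 0L) {
    return(tibble(respondent_id = character(), wave = integer()))
  }
  uc <- val$unit_costs
  scale <- period$quarter_days / df$recall_days
  if (any(is.na(df$recall_days)) || any(df$recall_days <= 0 | df$recall_days > 365)) {
    stop_mshrs("recall_days must lie in (0, 365] for every row.", "mshrs_recall_error")
  }

  wards <- mshrs_wards()
  inp <- priced_group(df, "inpatient_days_", wards,
                      unlist(uc$inpatient_per_day[wards]), scale)
  day <- priced_group(df, "day_admission_days_", wards,
                      unlist(uc$day_admission_per_day[wards]), scale)
  cons <- priced_group(df, "consultations_", mshrs_providers(),
                       unlist(uc$consultation_per_contact[mshrs_providers()]), scale)
  exam <- priced_group(df, "examinations_", mshrs_modalities(),
                       unlist(uc$examination_per_unit[mshrs_modalities()]), scale)

  assess_year <- as.integer(format(df$assessment_date, "%Y"))
  deflate <- (1 + val$price_adjustment$default_inflation_rate)^
    (val$reference_year - assess_year)
  otc <- df$otc_expenditure * deflate
  consum <- df$consumables_expenditure * deflate
  invest <- df$investments_expenditure * deflate

  prof <- df$professional_care_hours_per_week * uc$professional_care_per_hour *
    period$weeks_per_quarter
  informal <- ifelse(is.na(df$informal_care_hours_per_week), NA_real_,
                     informal_care_cost(dplyr::coalesce(df$informal_care_hours_per_week, 0),
                                        val, period))
  sick_q <- recall_scale(df$sick_days, df$recall_days, period)
  absent <- ifelse(is.na(sick_q), NA_real_,
                   absenteeism_cost(dplyr::coalesce(sick_q, 0), val))
  pension <- ifelse(is.na(df$disability_pension_pct), NA_real_,
                    disability_pension_cost(dplyr::coalesce(df$disability_pension_pct, 0),
                                            val, period))
  present <- ifelse(
    is.na(df$presenteeism_score) | is.na(df$weekly_work_hours), NA_real_,
    presenteeism_cost(dplyr::coalesce(df$presenteeism_score, 0L),
                      dplyr::coalesce(df$weekly_work_hours, 0),
                      dplyr::coalesce(sick_q, 0), val, period))

  dmt <- if (include_dmt) {
    tbl_years <- range(val$dmt_annual_costs$year)
    vapply(seq_len(n), function(i) {
      d <- df$dmt_name[i]
      if (is.na(d)) return(NA_real_)
      if (identical(d, "none")) return(0)
      yr <- dmt_year %||% assess_year[i]
      lookup_yr <- min(max(yr, tbl_years[1]), tbl_years[2])
      amt <- dmt_annual_cost(val, d, lookup_yr) / period$quarters_per_year
      # outside table coverage: indexate from the nearest covered year
      if (lookup_yr != yr) amt <- indexate(amt, lookup_yr, yr,
                                           val$price_adjustment$default_inflation_rate)
      amt
    }, numeric(1))
  } else {
    rep(0, n)
  }

  comp <- tibble(
    inpatient = inp$cost, day_admission = day$cost, consultations = cons$cost,
    examinations = exam$cost, otc = otc, consumables = consum,
    professional_care = prof, dmt = dmt, investments = invest,
    informal_care = informal, absenteeism = absent,
    disability_pension = pension, presenteeism = present
  )
  direct_med <- sum_observed(as.matrix(comp[, c("inpatient", "day_admission",
    "consultations", "examinations", "otc", "consumables", "professional_care")]))
  nonmed <- sum_observed(as.matrix(comp[, c("investments", "informal_care")]))
  indirect <- sum_observed(as.matrix(comp[, c("absenteeism", "disability_pension",
                                              "presenteeism")]))
  total_ex <- sum_observed(cbind(direct_med, nonmed, indirect))
  complete <- rowSums(is.na(comp)) == 0L &
    !inp$any_missing & !day$any_missing & !cons$any_missing & !exam$any_missing

  ids <- df[, intersect(c("respondent_id", "wave"), names(df)), drop = FALSE]
  dplyr::bind_cols(ids, comp) %>%
    mutate(
      direct_medical_excl_dmt = direct_med,
      direct_nonmedical = nonmed,
      indirect = indirect,
      total_excl_dmt = total_ex,
      total_incl_dmt = total_ex + .data$dmt,
      period = "quarter",
      complete = complete
    )
}

monetary_columns <- function() {
  c(mshrs_cost_components(TRUE), "direct_medical_excl_dmt", "direct_nonmedical",
    "indirect", "total_excl_dmt", "total_incl_dmt")
}

#' Annualize a quarterly cost breakdown
#'
#' Multiplies every monetary column by the quarters per year (default 4) and
#' relabels the period. Errors if the breakdown is already annual.
#'
#' @param costs Quarterly breakdown from [cost_responses()].
#' @param period A [period_model()].
#' @return The annual breakdown tibble (`period == "year"`).
#' @export
annualize <- function(costs, period = period_model()) {
  if (!all(costs$period == "quarter")) {
    stop_mshrs("Breakdown is already annual (or has mixed periods).",
               "mshrs_period_error")
  }
  cols <- intersect(monetary_columns(), names(costs))
  k <- period$quarters_per_year
  costs %>%
    mutate(across(all_of(cols), ~ .x * k), period = "year")
}

#' Cohort cost summary per item
#'
#' Descriptive cohort summary in the conventional layout of a resource-use
#' cost table: for each component and subtotal, the number and percentage of
#' users (observed cost > 0), mean, SD, median and IQR, computed over
#' observed values (unanswered items are excluded, never imputed).
#'
#' @param costs Breakdown tibble from [cost_responses()].
#' @return A tibble with columns `item`, `n_users`, `pct_users`, `mean`,
#'   `sd`, `median`, `q25`, `q75`. Percentages are on the 0-100 scale.
#' @export
cohort_cost_summary <- function(costs) {
  cols <- intersect(monetary_columns(), names(costs))
  purrr::map_dfr(cols, function(cl) {
    x <- costs[[cl]]
    obs <- x[!is.na(x)]
    tibble(
      item = cl,
      n_users = sum(obs > 0),
      pct_users = if (length(obs)) 100 * sum(obs > 0) / length(obs) else NA_real_,
      mean = if (length(obs)) mean(obs) else NA_real_,
      sd = if (length(obs) > 1) sd(obs) else NA_real_,
      median = if (length(obs)) median(obs) else NA_real_,
      q25 = if (length(obs)) unname(quantile(obs, 0.25)) else NA_real_,
      q75 = if (length(obs)) unname(quantile(obs, 0.75)) else NA_real_
    )
  })
}

#' Plot a cohort cost summary
#'
#' Bar chart of mean quarterly cost per component, grouped by cost domain.
#'
#' @param costs Breakdown tibble from [cost_responses()].
#' @param include_dmt Show the DMT component.
#' @return A ggplot object.
#' @export
plot_cost_components <- function(costs, include_dmt = TRUE) {
  comp <- mshrs_cost_components(include_dmt)
  smry <- cohort_cost_summary(costs) %>% filter(.data$item %in% comp)
  domain <- case_when(
    smry$item %in% c("inpatient", "day_admission", "consultations",
                     "examinations", "otc", "consumables",
                     "professional_care", "dmt") ~ "direct medical",
    smry$item %in% c("investments", "informal_care") ~ "direct nonmedical",
    TRUE ~ "indirect"
  )
  smry$domain <- domain
  smry$item <- factor(smry$item, levels = comp)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$item, y = .data$mean,
                                     fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mean cost per quarter (EUR)", fill = "Domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
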