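# Fixtures built in code: a zeroed respondent-wave row with overridable
# fields, and an independent brute-force costing oracle that prices a row
# item by item with the 2011 constants written out literally.

make_response <- function(..., respondent_id = "R1", recall_days = 91.25) {
  row <- tibble::tibble(
    respondent_id = respondent_id, wave = 0L,
    assessment_date = as.Date("2011-06-30"), recall_days = recall_days
  )
  for (f in mshrs_item_columns()) {
    row[[f]] <- if (f == "dmt_name") "none" else 0
  }
  row$presenteeism_score <- 0L
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

make_respondents <- function(n, completed = rep(TRUE, n)) {
  tibble::tibble(
    respondent_id = sprintf("R%d", seq_len(n)),
    age = 40, sex = rep_len(c("female", "male"), n), edss = 2,
    relapses_last_year = 0L, disease_duration_years = 7,
    employed = TRUE, full_time = FALSE, completed_survey = completed
  )
}

# Brute-force per-row quarterly totals (excluding DMT), with every 2011 unit
# cost spelled out; independent of the engine's code path.
oracle_quarter_costs <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    s <- 91.25 / r$recall_days
    inp <- r$inpatient_days_hospital * 593.04 +
      r$inpatient_days_rehabilitation * 121.85 +
      r$inpatient_days_nursing * 69.80
    day <- r$day_admission_days_hospital * 385.48 +
      r$day_admission_days_rehabilitation * 46.68 +
      r$day_admission_days_nursing * 46.15
    cons <- r$consultations_general_practitioner * 20.06 +
      r$consultations_neurologist * 44.72 +
      r$consultations_other_specialist * 34.73 +
      r$consultations_nurse * 16.42 +
      r$consultations_physiotherapist * 16.42 +
      r$consultations_psychologist * 78.08 +
      r$consultations_occupational_therapist * 37.51 +
      r$consultations_optician * 34.78 +
      r$consultations_speech_therapist * 38.59 +
      r$consultations_acupuncturist * 18.24 +
      r$consultations_other_alternative * 27.40
    exam <- r$examinations_mri * 120.21 + r$examinations_ct * 73.78 +
      r$examinations_lumbar_puncture * 38.90 + r$examinations_blood_test * 1.10 +
      r$examinations_other * 60.66
    direct <- (inp + day + cons + exam) * s + r$otc_expenditure +
      r$consumables_expenditure +
      r$professional_care_hours_per_week * 27.57 * 13
    nonmed <- r$investments_expenditure +
      min(r$informal_care_hours_per_week, 60) * 21.09 * 13
    sick_q <- r$sick_days * s
    absent <- sick_q * (1406.2 / 233) * 29.90
    pension <- r$disability_pension_pct / 100 * 42045.38 / 4
    attended <- max(0, r$weekly_work_hours * 13 -
                         sick_q * r$weekly_work_hours / 5)
    present <- r$presenteeism_score / 10 * attended * 29.90
    direct + nonmed + absent + pension + present
  }, numeric(1))
}

# rescale every monetary constant of a valuation object by a factor,
# preserving internal consistency (labor cost scales, hours do not)
scale_valuation <- function(val, f) {
  uc <- val$unit_costs
  for (blk in c("inpatient_per_day", "day_admission_per_day",
                "consultation_per_contact", "examination_per_unit")) {
    keys <- setdiff(names(uc[[blk]]), "source")
    for (k in keys) uc[[blk]][[k]] <- uc[[blk]][[k]] * f
  }
  uc$professional_care_per_hour <- uc$professional_care_per_hour * f
  uc$informal_care_per_hour <- uc$informal_care_per_hour * f
  uc$disability_pension_cap_per_year <- uc$disability_pension_cap_per_year * f
  val$unit_costs <- uc
  val$labor_market$hourly_labor_cost <- val$labor_market$hourly_labor_cost * f
  val$dmt_annual_costs$annual_cost <- val$dmt_annual_costs$annual_cost * f
  val
}

`%||%` <- function(x, y) if (is.null(x)) y else x
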