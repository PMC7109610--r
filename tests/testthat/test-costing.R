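# Costing engine: recall scaling, component valuations, totals, invariants.

val <- mshrs_valuation()

test_that("recall scaling maps reported windows onto the quarter", {
  expect_equal(recall_scale(4, 91.25), 4)
  expect_equal(recall_scale(8, 182.5), 4)
  expect_equal(recall_scale(12, 365), 3)
  expect_error(recall_scale(1, 366), class = "mshrs_recall_error")
  expect_error(recall_scale(1, 0), class = "mshrs_recall_error")
})

test_that("direct medical components price counts at the table constants", {
  resp <- make_response(consultations_neurologist = 2, examinations_mri = 1)
  out <- cost_responses(resp, val)
  expect_equal(out$consultations, 89.44)
  expect_equal(out$examinations, 120.21)
  expect_equal(out$direct_medical_excl_dmt, 209.65)

  out2 <- cost_responses(make_response(inpatient_days_hospital = 3), val)
  expect_equal(out2$inpatient, 1779.12)

  zero <- cost_responses(make_response(), val)
  comps <- unlist(zero[, mshrs_cost_components(TRUE)])
  expect_true(all(comps == 0))
  expect_equal(zero$total_incl_dmt, 0)
})

test_that("informal care is valued at opportunity cost with a 60 h/week cap", {
  expect_equal(informal_care_cost(0, val), 0)
  expect_equal(informal_care_cost(10, val), 2741.70)
  expect_equal(informal_care_cost(80, val), 16450.20)
  # constant beyond the cap
  expect_equal(informal_care_cost(c(60, 75, 120), val), rep(16450.20, 3))
  expect_error(informal_care_cost(-1, val), class = "mshrs_range_error")
})

test_that("absenteeism values each sick day at the derived daily loss", {
  expect_equal(absenteeism_cost(0, val), 0)
  expect_equal(round(absenteeism_cost(1, val), 2), 180.45)
  expect_equal(absenteeism_cost(1, val), 1406.2 / 233 * 29.90)
  expect_equal(round(absenteeism_cost(5, val), 2), 902.26)
  expect_error(absenteeism_cost(-1, val), class = "mshrs_range_error")
  expect_error(absenteeism_cost(60, val), class = "mshrs_range_error")
})

test_that("disability pension reproduces the annual cap exactly at 100%", {
  expect_equal(4 * disability_pension_cost(100, val), 42045.38)
  expect_equal(disability_pension_cost(0, val), 0)
  expect_equal(disability_pension_cost(50, val), 5255.6725)
  expect_error(disability_pension_cost(101, val), class = "mshrs_range_error")
})

test_that("presenteeism scales attended hours by the Likert fraction", {
  expect_equal(presenteeism_cost(0, 40, 0, val), 0)
  expect_equal(presenteeism_cost(10, 40, 0, val), 15548.00)
  expect_equal(presenteeism_cost(5, 40, 5, val), 7176.00)
  # attended hours never go negative
  expect_equal(presenteeism_cost(10, 40, 100, val), 0)
  expect_error(presenteeism_cost(11, 40, 0, val), class = "mshrs_range_error")
})

test_that("DMT quarterly costs are annual table values over four", {
  expect_equal(dmt_cost_quarter("GIL", 2011, val), 6674.645)
  expect_equal(dmt_cost_quarter("none", 2011, val), 0)
  expect_equal(dmt_cost_quarter("TYS", 2013, val), 6053.6025)
  expect_error(dmt_cost_quarter("GIL", 2010, val),
               class = "mshrs_not_available_error")
})

test_that("assembled totals match the hand-summed fixture to the cent", {
  fix <- make_response(consultations_neurologist = 2, examinations_mri = 1,
                       informal_care_hours_per_week = 10, sick_days = 5)
  out <- cost_responses(fix, val)
  # 209.65 + 2741.70 + 902.26 (component hand sums)
  expect_equal(round(out$total_excl_dmt, 2), 3853.61)
  expect_equal(out$total_excl_dmt, oracle_quarter_costs(fix), tolerance = 1e-9)
  expect_equal(out$total_incl_dmt - out$total_excl_dmt, out$dmt)

  on_dmt <- cost_responses(make_response(dmt_name = "GIL"), val)
  expect_equal(on_dmt$dmt, 6674.645)
  expect_equal(on_dmt$total_incl_dmt - on_dmt$total_excl_dmt, 6674.645)
})

test_that("breakdown identities hold on simulated cohorts", {
  costs <- cost_responses(generate_cohort(cohort_spec(n = 300), seed = 11), val)
  expect_equal(costs$direct_medical_excl_dmt,
               rowSums(costs[, c("inpatient", "day_admission", "consultations",
                                 "examinations", "otc", "consumables",
                                 "professional_care")]))
  expect_equal(costs$direct_nonmedical,
               rowSums(costs[, c("investments", "informal_care")]))
  expect_equal(costs$indirect,
               rowSums(costs[, c("absenteeism", "disability_pension",
                                 "presenteeism")]))
  expect_equal(costs$total_excl_dmt,
               costs$direct_medical_excl_dmt + costs$direct_nonmedical +
                 costs$indirect)
  expect_equal(costs$total_incl_dmt, costs$total_excl_dmt + costs$dmt)
  expect_true(all(as.matrix(costs[, mshrs_cost_components(TRUE)]) >= 0))
})

test_that("engine totals equal the brute-force oracle on random cohorts", {
  coh <- generate_cohort(cohort_spec(n = 1000), seed = 20200317)
  got <- cost_responses(coh, val, include_dmt = FALSE)$total_excl_dmt
  expect_equal(round(got, 2), round(oracle_quarter_costs(coh), 2))
})

test_that("increasing any single resource quantity never decreases a total", {
  base <- make_response(consultations_neurologist = 1, sick_days = 2,
                        weekly_work_hours = 40, presenteeism_score = 3,
                        informal_care_hours_per_week = 5)
  t0 <- cost_responses(base, val)
  bump <- c("consultations_neurologist", "examinations_mri", "sick_days",
            "inpatient_days_hospital", "informal_care_hours_per_week",
            "otc_expenditure", "investments_expenditure",
            "disability_pension_pct", "presenteeism_score",
            "professional_care_hours_per_week")
  for (f in bump) {
    up <- base
    up[[f]] <- up[[f]] + if (f == "presenteeism_score") 1L else 2
    t1 <- cost_responses(up, val)
    for (tot in c("direct_medical_excl_dmt", "direct_nonmedical", "indirect",
                  "total_excl_dmt", "total_incl_dmt")) {
      expect_gte(t1[[tot]], t0[[tot]])
    }
  }
})

test_that("doubling every unit cost doubles every priced output", {
  val2 <- scale_valuation(val, 2)
  coh <- generate_cohort(cohort_spec(n = 100), seed = 5)
  # patient-reported expenditures are amounts, not prices; the equivariance
  # property concerns the priced items, so zero the pass-through inputs
  coh$otc_expenditure <- 0
  coh$consumables_expenditure <- 0
  coh$investments_expenditure <- 0
  a <- cost_responses(coh, val)
  b <- cost_responses(coh, val2)
  cols <- intersect(mshrs:::monetary_columns(), names(a))
  expect_equal(as.matrix(b[, cols]), 2 * as.matrix(a[, cols]), tolerance = 1e-9)
})

test_that("unanswered items propagate as missing components, not zeros", {
  resp <- make_response(consultations_neurologist = 2, sick_days = NA,
                        otc_expenditure = NA)
  out <- cost_responses(resp, val)
  expect_true(is.na(out$absenteeism))
  expect_true(is.na(out$otc))
  expect_false(out$complete)
  # totals computed over observed components only
  expect_equal(out$direct_medical_excl_dmt, 89.44)
  expect_equal(out$total_excl_dmt, 89.44)
  full <- cost_responses(make_response(consultations_neurologist = 2), val)
  expect_true(full$complete)
})

test_that("annualization multiplies by four exactly once", {
  q <- cost_responses(make_response(dmt_name = "GIL",
                                    consultations_neurologist = 1), val)
  y <- annualize(q)
  expect_equal(y$dmt, 26698.58)
  expect_equal(y$total_incl_dmt, 4 * q$total_incl_dmt)
  expect_equal(unique(y$period), "year")
  expect_error(annualize(y), class = "mshrs_period_error")
  zeroy <- annualize(cost_responses(make_response(), val))
  expect_equal(zeroy$total_incl_dmt, 0)
})

test_that("cohort summary reports users, center and spread per item", {
  coh <- generate_cohort(cohort_spec(n = 500), seed = 8)
  costs <- cost_responses(coh, val)
  smry <- cohort_cost_summary(costs)
  cons <- smry[smry$item == "consultations", ]
  expect_equal(cons$n_users, sum(costs$consultations > 0))
  expect_equal(cons$pct_users, 100 * cons$n_users / nrow(costs))
  expect_equal(cons$mean, mean(costs$consultations))
  expect_true(all(smry$q25 <= smry$q75, na.rm = TRUE))
})
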