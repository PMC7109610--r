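# Pipeline entry points tying the modules together: simulate -> cost ->
# validate. These functions back the thin command-line wrapper shipped at
# inst/cli/mshrs.R (subcommands `simulate`, `cost`, `validate`).

round_money <- function(x) round(x, 2)

#' Simulate a synthetic cohort to disk
#'
#' Generates a cohort, its paired retest measurements and PRO scores, and
#' writes them (CSV) together with a sidecar JSON of the true generating
#' parameters for recovery tests. Deterministic under `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec An `mshrs_cohort_spec`.
#' @param seed Random seed; overrides `spec$seed`.
#' @return Invisibly, a list with the written paths and the in-memory tables.
#' @export
run_simulate <- function(out_dir, spec = cohort_spec(), seed = spec$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, seed = seed)
  paths <- list(responses = file.path(out_dir, "responses.csv"),
                retest = file.path(out_dir, "retest.csv"),
                pro_scores = file.path(out_dir, "pro_scores.csv"),
                truth = file.path(out_dir, "truth.json"))
  write_responses(cohort, paths$responses, format = "csv")
  if (nrow(cohort) > 0L) {
    costs <- cost_responses(cohort, include_dmt = FALSE)$total_excl_dmt
    retest <- generate_retest(cohort, spec, seed = seed + 1L, costs = costs)
    pro <- generate_pro_scores(cohort, spec, seed = seed + 2L, costs = costs)
  } else {
    retest <- tibble(); pro <- tibble()
    warn("Simulated cohort is empty; wrote header-only outputs.")
  }
  readr::write_csv(retest, paths$retest, na = "")
  readr::write_csv(pro, paths$pro_scores, na = "")
  truth <- list(n = spec$n, seed = seed, bin_probs = as.list(spec$bin_probs),
                implied_icc = implied_icc(spec),
                retest = spec$retest, pro_targets = as.list(spec$pro_targets),
                dmt_mix = as.list(spec$dmt_mix),
                completion_prob = spec$completion_prob)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, cohort = cohort, retest = retest,
                 pro_scores = pro))
}

#' Cost a response file to per-respondent and cohort-summary tables
#'
#' Reads respondent-wave records, prices them with the valuation tables, and
#' writes a tidy per-respondent breakdown CSV plus a cohort summary table
#' (users n/%, mean, SD, median, IQR per item). Monetary values are rounded
#' to cents only in the written files.
#'
#' @param input Path to a responses CSV/JSON file.
#' @param out_dir Output directory.
#' @param val An `mshrs_valuation` object.
#' @param include_dmt Include DMT costs.
#' @param annual Also write the annualized breakdown.
#' @return Invisibly, a list with the breakdown and summary tibbles and the
#'   written paths.
#' @export
run_cost <- function(input, out_dir, val = mshrs_valuation(),
                     include_dmt = TRUE, annual = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  responses <- read_responses(input)
  costs <- cost_responses(responses, val = val, include_dmt = include_dmt)
  paths <- list(costs = file.path(out_dir, "costs.csv"),
                summary = file.path(out_dir, "cost_summary.csv"))
  if (nrow(costs) == 0L) {
    warn(sprintf("No valid records in '%s'; writing empty outputs.", input))
    readr::write_csv(costs, paths$costs, na = "")
    readr::write_csv(tibble(), paths$summary, na = "")
    return(invisible(list(costs = costs, summary = tibble(), paths = paths)))
  }
  out <- costs %>%
    mutate(across(all_of(intersect(monetary_columns(), names(costs))), round_money))
  readr::write_csv(out, paths$costs, na = "")
  smry <- cohort_cost_summary(costs)
  readr::write_csv(mutate(smry, across(c("pct_users", "mean", "sd", "median",
                                         "q25", "q75"), round_money)),
                   paths$summary, na = "")
  if (annual) {
    paths$annual <- file.path(out_dir, "costs_annual.csv")
    readr::write_csv(annualize(costs) %>%
                       mutate(across(all_of(intersect(monetary_columns(), names(costs))),
                                     round_money)),
                     paths$annual, na = "")
  }
  invisible(list(costs = costs, summary = smry, paths = paths))
}

#' Run the full validation analysis on paired-wave inputs
#'
#' Computes the reliability report (stable-subgroup ICC, Guttman lambdas
#' over the monetized standardized items excluding DMT), the known-group
#' analysis of quarterly totals across EDSS strata, and the
#' convergent/discriminant Spearman correlations with PRO scores, and writes
#' a structured JSON report plus a human-readable text summary.
#'
#' @param responses Path to a responses CSV/JSON file.
#' @param retest Path to the paired-wave CSV (see [generate_retest()]).
#' @param pro_scores Optional path to a PRO-score CSV.
#' @param out_dir Output directory.
#' @param val An `mshrs_valuation` object.
#' @return Invisibly, a list with `reliability`, `known_group`,
#'   `correlations`, and the written paths. If no stable patients remain the
#'   reliability status is `"reliability undefined"` (a warning, not an
#'   error).
#' @export
run_validate <- function(responses, retest, pro_scores = NULL, out_dir,
                         val = mshrs_valuation()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resp <- read_responses(responses)
  pairs <- readr::read_csv(retest, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cost_w1", "cost_w2") %in% names(pairs))) {
    stop_mshrs("Retest input must contain paired waves (columns cost_w1, cost_w2).",
               "mshrs_input_error")
  }
  costs <- cost_responses(resp, val = val, include_dmt = FALSE)
  rel <- reliability_report(pairs, monetized_item_matrix(costs))
  if (rel$status != "ok") warn("Reliability undefined: no stable variance or no stable patients.")
  kg <- known_group_analysis(costs$total_excl_dmt, resp$edss)
  corr <- NULL
  if (!is.null(pro_scores)) {
    pro <- readr::read_csv(pro_scores, show_col_types = FALSE, progress = FALSE)
    pro <- pro[match(resp$respondent_id, pro$respondent_id), , drop = FALSE]
    corr <- convergent_discriminant(costs$total_excl_dmt,
                                    select(pro, -"respondent_id"))
  }
  paths <- list(json = file.path(out_dir, "validation_report.json"),
                text = file.path(out_dir, "validation_report.txt"))
  report <- list(
    reliability = unclass(tidy(rel)),
    known_group = list(summary = kg$summary,
                       omnibus = kg$omnibus, pairwise = kg$pairwise,
                       n_excluded = kg$n_excluded),
    correlations = corr
  )
  jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  txt <- c(
    "MS-HRS validation report",
    "========================",
    sprintf("Stable subgroup: n = %d (excluded %d)", rel$n_stable, rel$n_excluded),
    if (rel$status == "ok") {
      sprintf("Test-retest ICC(1,1) = %.3f (%s reliability)", rel$icc, rel$icc_band)
    } else "Test-retest ICC: reliability undefined",
    sprintf("Guttman lambda2 = %.3f, lambda6 = %.3f", rel$lambda2, rel$lambda6),
    "",
    "Known-group analysis (quarterly total cost excluding DMT):",
    utils::capture.output(print(as.data.frame(kg$summary), row.names = FALSE)),
    sprintf("Kruskal-Wallis H = %.2f (df %d), p = %.3g; %d record(s) outside strata",
            kg$omnibus$statistic, kg$omnibus$df, kg$omnibus$p_value, kg$n_excluded),
    "Pairwise Mann-Whitney (Bonferroni-adjusted):",
    utils::capture.output(print(as.data.frame(kg$pairwise), row.names = FALSE)),
    if (!is.null(corr)) c("", "Spearman correlations with PRO scores:",
                          utils::capture.output(print(as.data.frame(corr),
                                                      row.names = FALSE)))
  )
  writeLines(unlist(txt), paths$text)
  invisible(list(reliability = rel, known_group = kg, correlations = corr,
                 paths = paths))
}
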