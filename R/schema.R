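# Survey response data model: column dictionary, invariant validation, and
# CSV/JSON readers/writers. One row = one respondent-wave. An unanswered item
# is carried as NA (CSV: empty cell; JSON: absent key) and is never silently
# treated as zero; an explicit 0 is a true zero (e.g. a gated follow-up whose
# gate was answered "no").

count_item_columns <- function() {
  c(paste0("inpatient_days_", mshrs_wards()),
    paste0("day_admission_days_", mshrs_wards()),
    paste0("consultations_", mshrs_providers()),
    paste0("examinations_", mshrs_modalities()),
    "sick_days")
}

money_item_columns <- function() {
  c("otc_expenditure", "consumables_expenditure", "investments_expenditure")
}

hours_item_columns <- function() {
  c("professional_care_hours_per_week", "informal_care_hours_per_week",
    "weekly_work_hours")
}

#' Survey item columns of a response table
#'
#' The cost-relevant item columns of the wide respondent-wave table, i.e.
#' every column whose `NA` counts as an unanswered item.
#' @return Character vector of column names.
#' @export
mshrs_item_columns <- function() {
  c(count_item_columns(), money_item_columns(), hours_item_columns(),
    "presenteeism_score", "disability_pension_pct", "dmt_name")
}

respondent_columns <- function() {
  c("age", "sex", "edss", "relapses_last_year", "disease_duration_years",
    "employed", "full_time", "completed_survey")
}

#' Column dictionary of the respondent-wave table
#'
#' @return A tibble with one row per column of the documented file dialect:
#'   name, type, and role (identifier, survey item, or respondent
#'   characteristic).
#' @export
mshrs_dictionary <- function() {
  items <- mshrs_item_columns()
  tibble(
    name = c("respondent_id", "wave", "assessment_date", "recall_days",
             items, respondent_columns()),
    type = c("character", "integer", "date", "numeric",
             ifelse(items %in% "dmt_name", "character",
                    ifelse(items %in% count_item_columns(), "count", "numeric")),
             "numeric", "character", "numeric", "count", "numeric",
             "logical", "logical", "logical"),
    role = c(rep("identifier", 4L), rep("survey item", length(items)),
             rep("respondent characteristic", length(respondent_columns())))
  )
}

# validation ------------------------------------------------------------------

row_problems <- function(df) {
  checks <- list()
  add <- function(field, bad, message) {
    if (any(bad, na.rm = TRUE)) {
      checks[[length(checks) + 1L]] <<- tibble(
        row = which(bad), field = field, message = message
      )
    }
  }
  for (f in count_item_columns()) {
    if (!f %in% names(df)) next
    x <- df[[f]]
    add(f, !is.na(x) & (x < 0 | x != floor(x) | !is.finite(x)),
        "must be a nonnegative integer count")
  }
  for (f in money_item_columns()) {
    if (!f %in% names(df)) next
    add(f, !is.na(df[[f]]) & df[[f]] < 0, "expenditure must be nonnegative")
  }
  for (f in hours_item_columns()) {
    if (!f %in% names(df)) next
    x <- df[[f]]
    add(f, !is.na(x) & (x < 0 | x > 168), "weekly hours must lie in [0, 168]")
  }
  if ("recall_days" %in% names(df)) {
    x <- df$recall_days
    add("recall_days", is.na(x) | x <= 0 | x > 365,
        "recall window must lie in (0, 365] days (never exceed 12 months)")
  }
  if ("presenteeism_score" %in% names(df)) {
    x <- df$presenteeism_score
    add("presenteeism_score", !is.na(x) & (x < 0 | x > 10 | x != floor(x)),
        "presenteeism score must be an integer in 0..10")
  }
  if ("disability_pension_pct" %in% names(df)) {
    x <- df$disability_pension_pct
    add("disability_pension_pct", !is.na(x) & (x < 0 | x > 100),
        "disability pension percentage must lie in [0, 100]")
  }
  if ("dmt_name" %in% names(df)) {
    x <- df$dmt_name
    add("dmt_name", !is.na(x) & !x %in% c(mshrs_dmts(), "none"),
        sprintf("unknown DMT code; valid codes: %s, none",
                paste(mshrs_dmts(), collapse = ", ")))
  }
  if ("edss" %in% names(df)) {
    x <- df$edss
    add("edss", !is.na(x) & (x < 0 | x > 10 | abs(x * 2 - round(x * 2)) > 1e-8),
        "EDSS must be a multiple of 0.5 in [0, 10]")
  }
  if (all(c("employed", "full_time") %in% names(df))) {
    add("full_time",
        !is.na(df$full_time) & df$full_time & !is.na(df$employed) & !df$employed,
        "full_time implies employed")
  }
  if ("relapses_last_year" %in% names(df)) {
    x <- df$relapses_last_year
    add("relapses_last_year", !is.na(x) & (x < 0 | x != floor(x)),
        "relapse count must be a nonnegative integer (NA if unknown)")
  }
  if (length(checks) == 0L) {
    return(tibble(row = integer(), field = character(), message = character()))
  }
  arrange(bind_rows(checks), .data$row, .data$field)
}

#' Validate a respondent-wave table against the survey invariants
#'
#' Checks every type invariant of the data model (nonnegative counts, weekly
#' hours at most 168, recall window in (0, 365] days, presenteeism score in
#' 0..10, pension percentage in 0..100, known DMT codes, EDSS on the 0.5
#' grid, full-time implying employed). Rows are partitioned into accepted and
#' rejected; `nrow(valid) + nrow(distinct rejected rows) == nrow(x)`.
#'
#' Records with an EDSS above 6.0 are accepted but flagged in the logical
#' column `edss_above_validation_range`, because the instrument's validation
#' analyses are restricted to EDSS 0-6.0.
#'
#' @param x A respondent-wave tibble (see [mshrs_dictionary()]).
#' @return A list with `valid` (accepted rows, flag column added), and
#'   `problems` (tibble of row, field, message for each violation).
#' @export
validate_responses <- function(x) {
  x <- as_tibble(x)
  problems <- if (nrow(x) == 0L) {
    tibble(row = integer(), field = character(), message = character())
  } else {
    row_problems(x)
  }
  bad_rows <- unique(problems$row)
  valid <- if (length(bad_rows)) x[-bad_rows, , drop = FALSE] else x
  if ("edss" %in% names(valid)) {
    valid$edss_above_validation_range <- !is.na(valid$edss) & valid$edss > 6
  }
  list(valid = valid, problems = problems)
}

#' Read respondent-wave records from CSV or JSON
#'
#' Applies the documented file dialect: CSV with one header row, UTF-8,
#' decimal point, empty cell = unanswered item; JSON as an array of objects
#' with absent key = unanswered item. No imputation is ever performed:
#' unanswered items are carried as `NA`, distinct from an explicit zero.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @param on_invalid `"stop"` (default) raises an error naming the first
#'   offending row and field; `"drop"` returns the accepted rows with the
#'   rejected rows attached as attribute `"problems"`.
#' @return A validated respondent-wave tibble.
#' @export
read_responses <- function(path, format = c("guess", "csv", "json"),
                           on_invalid = c("stop", "drop")) {
  format <- match.arg(format)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    stop_mshrs(sprintf("File not found: '%s'.", path), "mshrs_io_error")
  }
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  } else {
    out <- jsonlite::fromJSON(path)
    if (length(out) == 0L) tibble() else as_tibble(out)
  }
  if (nrow(df) > 0L) {
    if ("assessment_date" %in% names(df)) {
      df$assessment_date <- as.Date(df$assessment_date)
    }
    if ("dmt_name" %in% names(df)) df$dmt_name <- as.character(df$dmt_name)
  }
  res <- validate_responses(df)
  if (nrow(res$problems) > 0L && on_invalid == "stop") {
    first <- res$problems[1L, ]
    id <- if ("respondent_id" %in% names(df)) df$respondent_id[first$row] else "?"
    stop_mshrs(
      sprintf("Invalid record at row %d (respondent %s), field '%s': %s. %d violation(s) in total.",
              first$row, id, first$field, first$message, nrow(res$problems)),
      "mshrs_validation_error"
    )
  }
  out <- res$valid
  attr(out, "problems") <- res$problems
  out
}

#' Write respondent-wave records to CSV or JSON
#'
#' Inverse of [read_responses()]: `NA` items become empty CSV cells or absent
#' JSON keys, so a write/read round trip preserves every value including
#' which items were unanswered.
#'
#' @param x Respondent-wave tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, format = c("guess", "csv", "json")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  x <- select(as_tibble(x), -dplyr::any_of("edss_above_validation_range"))
  if (format == "csv") {
    readr::write_csv(x, path, na = "")
  } else {
    recs <- purrr::map(seq_len(nrow(x)), function(i) {
      row <- as.list(x[i, ])
      row$assessment_date <- as.character(row$assessment_date)
      row[!vapply(row, function(v) is.na(v)[1], logical(1))]
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Which items are unanswered in each record
#'
#' @param x Respondent-wave tibble.
#' @return A list (one element per row) of item-column names carried as `NA`.
#' @export
missing_items <- function(x) {
  items <- intersect(mshrs_item_columns(), names(x))
  purrr::map(seq_len(nrow(x)), function(i) {
    items[vapply(items, function(f) is.na(x[[f]][i]), logical(1))]
  })
}

# cohort descriptives ---------------------------------------------------------

#' Survey completion rate
#'
#' Proportion of respondents whose `completed_survey` flag is `TRUE`,
#' computed as an exact fraction (rounding happens only at display).
#'
#' @param records Respondent tibble with a logical `completed_survey` column.
#' @return Proportion in \[0, 1\].
#' @examples
#' completion_rate(tibble::tibble(completed_survey = rep(c(TRUE, FALSE), c(2207, 181))))
#' @export
completion_rate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_mshrs("Completion rate needs a nonempty respondent table.", "mshrs_input_error")
  }
  if (!"completed_survey" %in% names(records)) {
    stop_mshrs("Column 'completed_survey' is required.", "mshrs_input_error")
  }
  sum(records$completed_survey, na.rm = TRUE) / nrow(records)
}

#' Cohort characteristics table
#'
#' Descriptive summary of a respondent table in the conventional layout of a
#' study-population table: counts and percentages for categorical
#' characteristics (sex, employment, completion), mean/SD/median/IQR for
#' continuous ones (age, disease duration, EDSS), and the relapse-count
#' distribution.
#'
#' @param records Respondent tibble.
#' @return A tibble with columns `characteristic`, `level`, `n`, `pct`,
#'   `mean`, `sd`, `median`, `q25`, `q75` (unused cells `NA`). Percentages
#'   are on the 0-100 scale.
#' @export
cohort_characteristics <- function(records) {
  if (nrow(records) == 0L) {
    stop_mshrs("Empty respondent table.", "mshrs_input_error")
  }
  n_all <- nrow(records)
  cont_row <- function(name, x) {
    x <- x[!is.na(x)]
    tibble(characteristic = name, level = NA_character_, n = length(x),
           pct = NA_real_, mean = mean(x), sd = sd(x), median = median(x),
           q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)))
  }
  cat_row <- function(name, level, k, denom) {
    tibble(characteristic = name, level = level, n = k, pct = 100 * k / denom,
           mean = NA_real_, sd = NA_real_, median = NA_real_,
           q25 = NA_real_, q75 = NA_real_)
  }
  out <- list()
  if ("completed_survey" %in% names(records)) {
    out <- c(out, list(cat_row("completed_survey", "yes",
                               sum(records$completed_survey, na.rm = TRUE), n_all)))
  }
  if ("age" %in% names(records)) out <- c(out, list(cont_row("age", records$age)))
  if ("sex" %in% names(records)) {
    out <- c(out, list(cat_row("sex", "female",
                               sum(records$sex == "female", na.rm = TRUE), n_all)))
  }
  if ("employed" %in% names(records)) {
    n_emp <- sum(records$employed, na.rm = TRUE)
    out <- c(out, list(cat_row("employed", "yes", n_emp, n_all)))
    if ("full_time" %in% names(records) && n_emp > 0L) {
      # full-time share is conventionally reported among the employed
      out <- c(out, list(cat_row("full_time (of employed)", "yes",
                                 sum(records$full_time & records$employed,
                                     na.rm = TRUE), n_emp)))
    }
  }
  if ("relapses_last_year" %in% names(records)) {
    r <- records$relapses_last_year
    lv <- c("0", "1", "2", ">=3", "unknown")
    ks <- c(sum(r == 0, na.rm = TRUE), sum(r == 1, na.rm = TRUE),
            sum(r == 2, na.rm = TRUE), sum(r >= 3, na.rm = TRUE), sum(is.na(r)))
    out <- c(out, purrr::map2(lv, ks, ~cat_row("relapses_last_year", .x, .y, n_all)))
  }
  if ("disease_duration_years" %in% names(records)) {
    out <- c(out, list(cont_row("disease_duration_years", records$disease_duration_years)))
  }
  if ("edss" %in% names(records)) out <- c(out, list(cont_row("edss", records$edss)))
  bind_rows(out)
}
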