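#' Load MS-HRS valuation tables
#'
#' Reads a versioned valuation config (YAML) holding every monetary constant
#' the costing engine uses: unit costs per resource item, labor-market
#' parameters for the human-capital approach, annual costs of
#' disease-modifying therapies (DMTs) by calendar year, and price-adjustment
#' constants (inflation rate, EUR/USD exchange rate). The package ships the
#' 2011 German reference tables as its default; pass `path` to localize.
#'
#' On load the tables are checked for internal consistency: all unit costs
#' must be strictly positive, and the disability-pension cap must equal
#' `annual_work_hours * hourly_labor_cost` to within half a cent.
#'
#' @param path Path to a YAML valuation config. `NULL` loads the bundled
#'   2011 German tables.
#' @return An object of class `mshrs_valuation`: a list with elements
#'   `reference_year`, `unit_costs`, `labor_market`, `dmt_annual_costs`
#'   (a tibble with columns `drug`, `year`, `annual_cost`), and
#'   `price_adjustment`.
#' @examples
#' val <- mshrs_valuation()
#' lookup_unit_cost(val, "consultation", "neurologist")
#' @export
mshrs_valuation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "valuation_de2011.yaml", package = "mshrs")
  if (!file.exists(path)) {
    stop_mshrs(sprintf("Valuation config not found: '%s'.", path), "mshrs_io_error")
  }
  raw <- yaml::read_yaml(path)
  dmt <- raw$dmt_annual_costs
  drugs <- setdiff(names(dmt), c("source", "years"))
  dmt_tbl <- purrr::map_dfr(drugs, function(d) {
    tibble(drug = d, year = as.integer(dmt$years),
           annual_cost = as.numeric(unlist(dmt[[d]])))
  })
  val <- structure(
    list(
      reference_year = as.integer(raw$reference_year),
      currency = raw$currency %||% "EUR",
      unit_costs = raw$unit_costs,
      labor_market = raw$labor_market,
      dmt_annual_costs = dmt_tbl,
      price_adjustment = raw$price_adjustment,
      source_path = path
    ),
    class = "mshrs_valuation"
  )
  validate_valuation(val)
  val
}

validate_valuation <- function(val) {
  uc <- val$unit_costs
  lm <- val$labor_market
  flat <- unlist(uc[c("inpatient_per_day", "day_admission_per_day",
                      "consultation_per_contact", "examination_per_unit")])
  flat <- flat[!is.na(suppressWarnings(as.numeric(flat)))]
  scalars <- c(uc$professional_care_per_hour, uc$informal_care_per_hour,
               uc$disability_pension_cap_per_year)
  if (any(as.numeric(flat) <= 0) || any(scalars <= 0)) {
    stop_mshrs("All unit costs must be strictly positive.", "mshrs_config_error")
  }
  for (f in c("annual_work_hours", "annual_work_days", "hourly_labor_cost",
              "informal_care_cap_hours_per_week", "standard_week_days")) {
    check_number(lm[[f]], paste0("labor_market$", f), lower = 1e-9)
  }
  if (lm$informal_care_cap_hours_per_week > 168) {
    stop_mshrs("Informal-care cap cannot exceed 168 h/week.", "mshrs_config_error")
  }
  cap <- uc$disability_pension_cap_per_year
  if (abs(cap - lm$annual_work_hours * lm$hourly_labor_cost) > 0.005) {
    stop_mshrs(
      "Disability-pension cap must equal annual_work_hours x hourly_labor_cost (within 0.005 EUR).",
      "mshrs_config_error"
    )
  }
  adj <- val$price_adjustment
  if (adj$default_inflation_rate <= -0.5 || adj$default_inflation_rate >= 0.5) {
    stop_mshrs("Inflation rate must lie in (-0.5, 0.5).", "mshrs_config_error")
  }
  if (adj$eur_usd_rate <= 0) stop_mshrs("FX rate must be positive.", "mshrs_config_error")
  if (any(val$dmt_annual_costs$annual_cost <= 0, na.rm = TRUE)) {
    stop_mshrs("All present DMT annual costs must be positive.", "mshrs_config_error")
  }
  invisible(val)
}

#' @export
print.mshrs_valuation <- function(x, ...) {
  cat(sprintf("<mshrs_valuation> reference year %d (%s)\n", x$reference_year, x$currency))
  cat(sprintf("  unit-cost categories: %s\n",
              paste(names(x$unit_costs), collapse = ", ")))
  cat(sprintf("  DMTs priced %d-%d: %s\n",
              min(x$dmt_annual_costs$year), max(x$dmt_annual_costs$year),
              paste(unique(x$dmt_annual_costs$drug), collapse = ", ")))
  invisible(x)
}

# vocabularies ----------------------------------------------------------------

#' Controlled vocabularies of the survey's resource items
#'
#' @return Character vectors of the valid ward types, provider types,
#'   examination modalities, and DMT codes.
#' @export
mshrs_wards <- function() c("hospital", "rehabilitation", "nursing")

#' @rdname mshrs_wards
#' @export
mshrs_providers <- function() {
  c("general_practitioner", "neurologist", "other_specialist", "nurse",
    "physiotherapist", "psychologist", "occupational_therapist", "optician",
    "speech_therapist", "acupuncturist", "other_alternative")
}

#' @rdname mshrs_wards
#' @export
mshrs_modalities <- function() c("mri", "ct", "lumbar_puncture", "blood_test", "other")

#' @rdname mshrs_wards
#' @export
mshrs_dmts <- function() c("AVO", "REB", "BET", "EXT", "COP", "GIL", "TYS")

# lookups ---------------------------------------------------------------------

#' Look up a unit cost
#'
#' Returns the per-unit monetary valuation of one resource item: EUR per
#' inpatient/day-admission day, per ambulant contact, per examination, or per
#' care hour.
#'
#' @param val An `mshrs_valuation` object.
#' @param category One of `"inpatient"`, `"day_admission"`, `"consultation"`,
#'   `"examination"`, `"professional_care"`, `"informal_care"`.
#' @param item Item key within the category (e.g. `"neurologist"`); ignored
#'   for the per-hour care categories.
#' @return EUR per unit, unchanged from the table.
#' @export
lookup_unit_cost <- function(val, category, item = NULL) {
  stopifnot(inherits(val, "mshrs_valuation"))
  block <- switch(category,
    inpatient = val$unit_costs$inpatient_per_day,
    day_admission = val$unit_costs$day_admission_per_day,
    consultation = val$unit_costs$consultation_per_contact,
    examination = val$unit_costs$examination_per_unit,
    professional_care = return(val$unit_costs$professional_care_per_hour),
    informal_care = return(val$unit_costs$informal_care_per_hour),
    stop_mshrs(
      sprintf(paste0(
        "Unknown cost category '%s'. Valid categories: inpatient, day_admission, ",
        "consultation, examination, professional_care, informal_care."), category),
      "mshrs_vocabulary_error"
    )
  )
  keys <- setdiff(names(block), "source")
  if (is.null(item) || !item %in% keys) {
    stop_mshrs(
      sprintf("Unknown item '%s' in category '%s'. Valid items: %s.",
              item %||% "<missing>", category, paste(keys, collapse = ", ")),
      "mshrs_vocabulary_error"
    )
  }
  block[[item]]
}

#' Annual cost of a disease-modifying therapy
#'
#' @param val An `mshrs_valuation` object.
#' @param drug DMT code (see [mshrs_dmts()]).
#' @param year Calendar year within the table's coverage.
#' @return Annual EUR cost of the drug in that year.
#' @export
dmt_annual_cost <- function(val, drug, year) {
  stopifnot(inherits(val, "mshrs_valuation"))
  tbl <- val$dmt_annual_costs
  if (!drug %in% tbl$drug) {
    stop_mshrs(sprintf("Unknown DMT code '%s'. Valid codes: %s.",
                       drug, paste(unique(tbl$drug), collapse = ", ")),
               "mshrs_vocabulary_error")
  }
  if (!year %in% tbl$year) {
    stop_mshrs(
      sprintf("Year %s outside DMT table coverage %d-%d; indexate from a covered year instead.",
              year, min(tbl$year), max(tbl$year)),
      "mshrs_range_error"
    )
  }
  out <- tbl$annual_cost[tbl$drug == drug & tbl$year == year]
  if (is.na(out)) {
    stop_mshrs(sprintf("No annual cost available for %s in %d.", drug, year),
               "mshrs_not_available_error")
  }
  out
}

#' Adjust an amount between price levels
#'
#' Compound inflation adjustment: `amount * (1 + rate)^(to_year - from_year)`.
#' A negative exponent deflates to an earlier price level, so
#' `indexate(indexate(x, a, b), b, a) == x`.
#'
#' @param amount Nonnegative EUR amount(s).
#' @param from_year,to_year Calendar years of the source and target price level.
#' @param rate Annual inflation rate as a fraction (default 2%).
#' @return Adjusted amount(s).
#' @export
indexate <- function(amount, from_year, to_year, rate = 0.02) {
  if (any(amount < 0, na.rm = TRUE)) {
    stop_mshrs("Amounts to indexate must be nonnegative.", "mshrs_range_error")
  }
  amount * (1 + rate)^(to_year - from_year)
}

#' Convert EUR to USD at the configured annual average rate
#'
#' @param amount Nonnegative EUR amount(s).
#' @param val An `mshrs_valuation` object (uses its `eur_usd_rate`).
#' @return USD amount(s).
#' @export
convert_eur_usd <- function(amount, val = mshrs_valuation()) {
  if (any(amount < 0, na.rm = TRUE)) {
    stop_mshrs("Amounts to convert must be nonnegative.", "mshrs_range_error")
  }
  amount * val$price_adjustment$eur_usd_rate
}

#' Monetary value of one day of sick leave
#'
#' Human-capital valuation of a lost working day:
#' `annual_work_hours / annual_work_days * hourly_labor_cost`, kept unrounded
#' internally (about EUR 180.45 under the default 2011 tables).
#'
#' @param val An `mshrs_valuation` object.
#' @return EUR per sick day.
#' @export
sick_leave_per_day <- function(val = mshrs_valuation()) {
  lm <- val$labor_market
  lm$annual_work_hours / lm$annual_work_days * lm$hourly_labor_cost
}
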