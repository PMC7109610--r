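# Synthetic cohort generator. Emulates the statistical structure the
# validation procedure assumes: a single latent severity scalar per subject
# drives the EDSS stratum, zero-inflated cost components (occurrence
# probability rising with severity, log-normal positive parts), employment
# and productivity items, a retest measurement model with a controlled
# intraclass correlation, and PRO scores coupled to total cost through a
# Gaussian copula. Default calibration follows the published cohort's
# marginal shape (stratum sizes, user percentages, stratum cost gradients);
# it is a calibration aid, not ground truth.

default_components <- function() {
  # occurrence probabilities are per EDSS stratum (four analysis strata plus
  # the above-range stratum at EDSS 6.0)
  list(
    inpatient = list(occ = c(0.03, 0.07, 0.09, 0.17, 0.22),
                     meanlog = log(6), sdlog = 0.6,
                     ward_probs = c(hospital = 0.6, rehabilitation = 0.3, nursing = 0.1)),
    day_admission = list(occ = c(0.012, 0.025, 0.045, 0.09, 0.11), lambda = 2,
                         ward_probs = c(hospital = 0.8, rehabilitation = 0.1, nursing = 0.1)),
    consultations = list(occ = c(0.75, 0.82, 0.87, 0.92, 0.92),
                         physio_lambda = c(0.5, 1.5, 3, 6, 8),
                         occupational_lambda = c(0.05, 0.1, 0.3, 0.8, 1)),
    examinations = list(occ = c(0.60, 0.65, 0.68, 0.72, 0.75)),
    otc = list(occ = c(0.25, 0.31, 0.36, 0.40, 0.40), meanlog = log(30), sdlog = 1),
    consumables = list(occ = c(0.04, 0.07, 0.10, 0.18, 0.25),
                       meanlog = log(25), sdlog = 1),
    professional_care = list(occ = c(0.005, 0.015, 0.04, 0.12, 0.25),
                             meanlog = log(2), sdlog = 0.7),
    informal_care = list(occ = c(0.02, 0.05, 0.10, 0.25, 0.40),
                         meanlog = log(1.5), sdlog = 0.8),
    investments = list(occ = c(0.005, 0.01, 0.02, 0.05, 0.08),
                       meanlog = log(300), sdlog = 1),
    sick_leave = list(occ = c(0.11, 0.17, 0.18, 0.25, 0.30),
                      meanlog = log(9), sdlog = 1),
    presenteeism = list(occ = c(0.18, 0.32, 0.38, 0.48, 0.50), lambda = 1.5),
    disability_pension = list(occ = c(0.05, 0.19, 0.30, 0.55, 0.70),
                              meanlog = log(40), sdlog = 0.6)
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles every generating parameter of the synthetic cohort: size, EDSS
#' stratum probabilities, zero-inflated log-normal component models per
#' stratum, employment and relapse structure, DMT mix, the retest
#' measurement model (between/within SDs implying a target intraclass
#' correlation), and the Spearman targets for PRO scores.
#'
#' @param n Cohort size.
#' @param seed Default random seed used by the generators.
#' @param bin_probs Probabilities over the five EDSS strata (four analysis
#'   strata 0-1.0, 1.5-2.5, 3.0-4.0, 4.5-5.5 plus the above-range stratum at
#'   6.0); normalized to sum to 1.
#' @param components Per-component occurrence/positive-part models; see the
#'   package's methods vignette.
#' @param relapse_probs Probabilities of 0, 1, 2, >=3 relapses in the
#'   previous year, plus `unknown`.
#' @param employed_prob_by_bin Employment probability per stratum.
#' @param full_time_prob Probability of full-time work given employment.
#' @param dmt_mix Named distribution over DMT codes and `"none"`.
#' @param retest List with `between_sd`, `within_sd` (EUR) of the retest
#'   measurement model, or `target_icc` to derive `within_sd`; plus
#'   `p_relapse_pre`, `p_relapse_retest`, `p_edss_increase` controlling the
#'   unstable fraction.
#' @param pro_targets Named vector of target Spearman correlations between
#'   each PRO score and quarterly total cost (positive or negative,
#'   magnitude at most 1).
#' @param completion_prob Probability that a respondent completes the survey.
#' @param recall_days Recall window carried on every record.
#' @return A validated list of class `mshrs_cohort_spec`.
#' @export
cohort_spec <- function(
    n = 2207, seed = 1L,
    bin_probs = c("0-1.0" = 562, "1.5-2.5" = 756, "3.0-4.0" = 589,
                  "4.5-5.5" = 152, "6.0" = 148) / 2207,
    components = default_components(),
    relapse_probs = c("0" = 0.5401, "1" = 0.2773, "2" = 0.1210,
                      ">=3" = 0.0444, "unknown" = 0.0172),
    employed_prob_by_bin = c(0.75, 0.68, 0.55, 0.35, 0.20),
    full_time_prob = 0.5895,
    dmt_mix = c(AVO = 0.17, REB = 0.13, BET = 0.14, EXT = 0.08, COP = 0.22,
                GIL = 0.12, TYS = 0.12, none = 0.01),
    retest = list(between_sd = 1100, within_sd = 500,
                  p_relapse_pre = 0.25, p_relapse_retest = 0.25,
                  p_edss_increase = 0.10),
    pro_targets = c(uknds_sum = 0.411, primus_activities = 0.423,
                    primus_qol = -0.350, eq5d = -0.342,
                    tsqm_effectiveness = -0.216, tsqm_convenience = -0.006),
    completion_prob = 0.924,
    recall_days = 91) {
  check_number(n, "n", lower = 0)
  if (n != floor(n)) stop_mshrs("`n` must be an integer.", "mshrs_spec_error")
  if (any(bin_probs < 0) || sum(bin_probs) <= 0) {
    stop_mshrs("Stratum probabilities must be nonnegative and sum > 0.", "mshrs_spec_error")
  }
  bin_probs <- bin_probs / sum(bin_probs)
  for (p in c(employed_prob_by_bin, full_time_prob, completion_prob,
              relapse_probs, dmt_mix)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop_mshrs("All probabilities must lie in [0, 1].", "mshrs_spec_error")
    }
  }
  for (cm in components) {
    if (any(cm$occ < 0 | cm$occ > 1)) {
      stop_mshrs("Component occurrence probabilities must lie in [0, 1].",
                 "mshrs_spec_error")
    }
    if (!is.null(cm$sdlog) && cm$sdlog < 0) {
      stop_mshrs("Component sdlog must be nonnegative.", "mshrs_spec_error")
    }
  }
  if (!is.null(retest$target_icc)) {
    check_number(retest$target_icc, "retest$target_icc", lower = 1e-6, upper = 1)
    retest$within_sd <- retest$between_sd *
      sqrt((1 - retest$target_icc) / retest$target_icc)
  }
  if (retest$between_sd < 0 || retest$within_sd < 0) {
    stop_mshrs("Retest SDs must be nonnegative.", "mshrs_spec_error")
  }
  if (any(abs(pro_targets) > 1)) {
    stop_mshrs("PRO Spearman targets must have magnitude at most 1.",
               "mshrs_spec_error")
  }
  check_number(recall_days, "recall_days", lower = 1e-9, upper = 365)
  structure(list(
    n = as.integer(n), seed = as.integer(seed), bin_probs = bin_probs,
    components = components, relapse_probs = relapse_probs / sum(relapse_probs),
    employed_prob_by_bin = employed_prob_by_bin,
    full_time_prob = full_time_prob, dmt_mix = dmt_mix / sum(dmt_mix),
    retest = retest, pro_targets = pro_targets,
    completion_prob = completion_prob, recall_days = recall_days
  ), class = "mshrs_cohort_spec")
}

#' Implied intraclass correlation of a cohort spec's retest model
#'
#' `between_sd^2 / (between_sd^2 + within_sd^2)`.
#' @param spec An `mshrs_cohort_spec`.
#' @return The implied ICC in \[0, 1\].
#' @export
implied_icc <- function(spec) {
  b2 <- spec$retest$between_sd^2
  w2 <- spec$retest$within_sd^2
  if (b2 + w2 == 0) return(NA_real_)
  b2 / (b2 + w2)
}

edss_grid_for_bin <- function(bin_index) {
  switch(bin_index,
         `1` = c(0, 0.5, 1), `2` = c(1.5, 2, 2.5), `3` = c(3, 3.5, 4),
         `4` = c(4.5, 5, 5.5), `5` = 6)[[1]]
}

draw_positive <- function(n, meanlog, sdlog) rlnorm(n, meanlog, sdlog)

#' Generate a synthetic cohort
#'
#' Draws `spec$n` respondent-wave records. A latent severity scalar per
#' subject (standard normal) determines the EDSS stratum by its quantile;
#' every zero-inflated component then uses the stratum's occurrence
#' probability and positive-part distribution, so mean cost rises
#' monotonically with severity whenever the per-stratum parameters do.
#' Output records always satisfy the survey schema invariants.
#'
#' @param spec An `mshrs_cohort_spec`.
#' @param seed Random seed (defaults to `spec$seed`); the same spec and seed
#'   reproduce the cohort exactly.
#' @return Respondent-wave tibble combining survey items and respondent
#'   characteristics (one row per respondent, wave 0).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "mshrs_cohort_spec"))
  n <- spec$n
  empty <- generate_empty_cohort()
  if (n == 0L) return(empty)
  withr::with_seed(seed, {
    z <- rnorm(n)
    cuts <- qnorm(cumsum(spec$bin_probs))
    bin <- findInterval(z, head(cuts, -1)) + 1L
    edss <- vapply(bin, function(b) {
      g <- edss_grid_for_bin(b)
      if (length(g) == 1L) g else sample(g, 1L)
    }, numeric(1))
    cm <- spec$components
    occ <- function(name) rbinom(n, 1L, cm[[name]]$occ[bin]) == 1L

    # inpatient / day admissions: total days assigned to one primary ward
    ward_split <- function(active, days, probs) {
      out <- matrix(0, n, 3L, dimnames = list(NULL, mshrs_wards()))
      idx <- which(active)
      if (length(idx)) {
        w <- sample(mshrs_wards(), length(idx), replace = TRUE, prob = probs)
        out[cbind(idx, match(w, mshrs_wards()))] <- days[idx]
      }
      out
    }
    inp_act <- occ("inpatient")
    inp_days <- pmax(1, round(draw_positive(n, cm$inpatient$meanlog, cm$inpatient$sdlog)))
    inp <- ward_split(inp_act, inp_days, cm$inpatient$ward_probs)
    day_act <- occ("day_admission")
    day_days <- 1L + rpois(n, cm$day_admission$lambda)
    day <- ward_split(day_act, day_days, cm$day_admission$ward_probs)

    con_act <- occ("consultations")
    cons <- sapply(mshrs_providers(), function(p) rep(0L, n))
    cons <- as.data.frame(cons)
    cons$general_practitioner <- rpois(n, 1.0)
    cons$neurologist <- 1L + rpois(n, 0.7)
    cons$other_specialist <- rpois(n, 0.5)
    cons$nurse <- rpois(n, 0.3)
    cons$physiotherapist <- rpois(n, cm$consultations$physio_lambda[bin])
    cons$psychologist <- rpois(n, 0.15)
    cons$occupational_therapist <- rpois(n, cm$consultations$occupational_lambda[bin])
    cons$optician <- rpois(n, 0.1)
    cons$speech_therapist <- rpois(n, 0.03)
    cons$acupuncturist <- rpois(n, 0.05)
    cons$other_alternative <- rpois(n, 0.1)
    cons[!con_act, ] <- 0L

    exa_act <- occ("examinations")
    exams <- data.frame(
      mri = rbinom(n, 1L, 0.5), ct = rbinom(n, 1L, 0.08),
      lumbar_puncture = rbinom(n, 1L, 0.03), blood_test = 1L + rpois(n, 1),
      other = rbinom(n, 1L, 0.1))
    exams[!exa_act, ] <- 0L

    otc <- ifelse(occ("otc"), round(draw_positive(n, cm$otc$meanlog, cm$otc$sdlog), 2), 0)
    consum <- ifelse(occ("consumables"),
                     round(draw_positive(n, cm$consumables$meanlog, cm$consumables$sdlog), 2), 0)
    prof <- ifelse(occ("professional_care"),
                   pmin(60, draw_positive(n, cm$professional_care$meanlog,
                                          cm$professional_care$sdlog)), 0)
    informal <- ifelse(occ("informal_care"),
                       pmin(120, draw_positive(n, cm$informal_care$meanlog,
                                               cm$informal_care$sdlog)), 0)
    invest <- ifelse(occ("investments"),
                     round(draw_positive(n, cm$investments$meanlog,
                                         cm$investments$sdlog), 2), 0)

    employed <- rbinom(n, 1L, spec$employed_prob_by_bin[bin]) == 1L
    full_time <- employed & rbinom(n, 1L, spec$full_time_prob) == 1L
    hours <- ifelse(full_time, pmin(48, pmax(30, rnorm(n, 39, 3))),
                    ifelse(employed, pmin(30, pmax(5, rnorm(n, 22, 6))), 0))
    sick <- ifelse(employed & occ("sick_leave"),
                   pmin(55, round(draw_positive(n, cm$sick_leave$meanlog,
                                                cm$sick_leave$sdlog)) + 1L), 0L)
    pres <- ifelse(employed & occ("presenteeism"),
                   pmin(10L, 1L + rpois(n, cm$presenteeism$lambda)), 0L)
    pension <- ifelse(occ("disability_pension"),
                      pmin(100, round(draw_positive(n, cm$disability_pension$meanlog,
                                                    cm$disability_pension$sdlog))), 0)

    dmt <- sample(names(spec$dmt_mix), n, replace = TRUE, prob = spec$dmt_mix)
    completed <- rbinom(n, 1L, spec$completion_prob) == 1L
    rel_lab <- sample(names(spec$relapse_probs), n, replace = TRUE,
                      prob = spec$relapse_probs)
    relapses <- dplyr::case_when(rel_lab == "0" ~ 0L, rel_lab == "1" ~ 1L,
                                 rel_lab == "2" ~ 2L, rel_lab == ">=3" ~ 3L,
                                 TRUE ~ NA_integer_)
    duration_mean <- ifelse(completed, 7.36, 9.67)
    duration <- rgamma(n, shape = 1.5, scale = duration_mean / 1.5)

    out <- tibble(
      respondent_id = sprintf("P%05d", seq_len(n)),
      wave = 0L,
      assessment_date = as.Date("2011-01-15") + sample(0:330, n, replace = TRUE),
      recall_days = spec$recall_days
    )
    for (w in mshrs_wards()) out[[paste0("inpatient_days_", w)]] <- inp[, w]
    for (w in mshrs_wards()) out[[paste0("day_admission_days_", w)]] <- day[, w]
    for (p in mshrs_providers()) out[[paste0("consultations_", p)]] <- cons[[p]]
    for (m in mshrs_modalities()) out[[paste0("examinations_", m)]] <- exams[[m]]
    out$otc_expenditure <- otc
    out$consumables_expenditure <- consum
    out$professional_care_hours_per_week <- prof
    out$informal_care_hours_per_week <- informal
    out$investments_expenditure <- invest
    out$weekly_work_hours <- hours
    out$sick_days <- as.integer(sick)
    out$presenteeism_score <- as.integer(pres)
    out$disability_pension_pct <- pension
    out$dmt_name <- dmt
    out$age <- pmin(75, pmax(18, round(rnorm(n, 41.73, 10.19))))
    out$sex <- ifelse(rbinom(n, 1L, 0.729) == 1L, "female", "male")
    out$edss <- edss
    out$relapses_last_year <- relapses
    out$disease_duration_years <- round(duration, 1)
    out$employed <- employed
    out$full_time <- full_time
    out$completed_survey <- completed
    out
  })
}

#' @importFrom stats rgamma
generate_empty_cohort <- function() {
  dict <- mshrs_dictionary()
  out <- purrr::map(dict$type, function(tp) {
    switch(tp, character = character(), integer = integer(), count = integer(),
           date = as.Date(character()), logical = logical(), numeric())
  })
  names(out) <- dict$name
  as_tibble(out)
}

#' Generate paired test-retest measurements with stability histories
#'
#' Builds the paired-wave input for reliability analysis. Each subject's
#' latent total-cost value is a Gaussianized transform (normal scores) of
#' their engine-priced quarterly total, rescaled to the spec's
#' between-subject SD; both wave measurements add independent Gaussian
#' within-subject noise, so the population intraclass correlation of the
#' pairs equals `implied_icc(spec)` by construction. A configurable fraction
#' of subjects receives relapses or EDSS increases in the pre-window or
#' retest window so that stable-subgroup filtering has both outcomes.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec The generating `mshrs_cohort_spec`.
#' @param seed Random seed (defaults to `spec$seed + 1`).
#' @param costs Optional precomputed quarterly totals (excluding DMT); by
#'   default priced from `cohort` with the bundled valuation tables.
#' @return Tibble with `respondent_id`, EDSS and relapse histories
#'   (`edss_pre`, `edss_w1`, `edss_w2`, `relapses_pre`, `relapses_retest`),
#'   the latent value `latent_cost`, and paired measurements `cost_w1`,
#'   `cost_w2`.
#' @export
generate_retest <- function(cohort, spec = cohort_spec(), seed = spec$seed + 1L,
                            costs = NULL) {
  if (nrow(cohort) == 0L) {
    stop_mshrs("Cohort must be nonempty for retest generation.", "mshrs_input_error")
  }
  if (is.null(costs)) {
    costs <- cost_responses(cohort, include_dmt = FALSE)$total_excl_dmt
  }
  n <- nrow(cohort)
  r <- spec$retest
  withr::with_seed(seed, {
    zs <- qnorm((rank(costs, ties.method = "average") - 0.375) / (n + 0.25))
    zs <- if (sd(zs) > 0) as.numeric(scale(zs)) else rep(0, n)
    latent <- mean(costs) + r$between_sd * zs
    cost_w1 <- latent + rnorm(n, 0, r$within_sd)
    cost_w2 <- latent + rnorm(n, 0, r$within_sd)
    inc_pre <- rbinom(n, 1L, r$p_edss_increase) == 1L
    inc_ret <- rbinom(n, 1L, r$p_edss_increase) == 1L
    edss_w1 <- cohort$edss
    tibble(
      respondent_id = cohort$respondent_id,
      edss_pre = pmax(0, edss_w1 - 0.5 * inc_pre),
      edss_w1 = edss_w1,
      edss_w2 = pmin(10, edss_w1 + 0.5 * inc_ret),
      relapses_pre = rbinom(n, 1L, r$p_relapse_pre),
      relapses_retest = rbinom(n, 1L, r$p_relapse_retest),
      latent_cost = latent, cost_w1 = cost_w1, cost_w2 = cost_w2
    )
  })
}

#' Generate PRO summary scores with target Spearman correlations
#'
#' Draws one summary score per instrument via a Gaussian copula on the
#' normal scores of each subject's quarterly total cost: for a target
#' Spearman correlation `r`, the Gaussian mixing weight is
#' `rho = 2 sin(pi r / 6)`, so the realized rank correlation with total cost
#' approximates the target (up to ties among zero-cost respondents).
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec The generating `mshrs_cohort_spec` (uses `spec$pro_targets`).
#' @param seed Random seed (defaults to `spec$seed + 2`).
#' @param costs Optional precomputed quarterly totals (excluding DMT).
#' @return Tibble with `respondent_id` and one numeric score column per
#'   instrument in `spec$pro_targets`.
#' @export
generate_pro_scores <- function(cohort, spec = cohort_spec(),
                                seed = spec$seed + 2L, costs = NULL) {
  if (nrow(cohort) == 0L) {
    stop_mshrs("Cohort must be nonempty for PRO generation.", "mshrs_input_error")
  }
  if (any(abs(spec$pro_targets) > 1)) {
    stop_mshrs("PRO Spearman targets must have magnitude at most 1.",
               "mshrs_spec_error")
  }
  if (is.null(costs)) {
    costs <- cost_responses(cohort, include_dmt = FALSE)$total_excl_dmt
  }
  n <- nrow(cohort)
  withr::with_seed(seed, {
    zc <- qnorm((rank(costs, ties.method = "average") - 0.375) / (n + 0.25))
    zc <- if (sd(zc) > 0) as.numeric(scale(zc)) else rep(0, n)
    out <- tibble(respondent_id = cohort$respondent_id)
    for (nm in names(spec$pro_targets)) {
      r <- spec$pro_targets[[nm]]
      rho <- 2 * sin(pi * r / 6)
      rho <- max(-1, min(1, rho))
      out[[nm]] <- rho * zc + sqrt(1 - rho^2) * rnorm(n)
    }
    out
  })
}
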