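# Psychometric validation of the instrument: stable-subgroup filtering,
# one-way random test-retest ICC, Guttman lambda-2/lambda-6 reliability lower
# bounds, convergent/discriminant Spearman correlations, known-group analyses
# across EDSS strata, and completer/noncompleter comparison.

#' Filter the stable subgroup for test-retest reliability
#'
#' A patient is stable when they had no relapse and no EDSS increase during
#' the retest period *and* during the 3 months prior to the first
#' assessment. Rows with missing history are excluded (with a logged
#' reason), never errors.
#'
#' @param retest Tibble of paired waves with columns `relapses_pre`,
#'   `relapses_retest` (counts in the pre-window and the retest window),
#'   `edss_pre`, `edss_w1`, `edss_w2`.
#' @return The stable subset; excluded rows (with a `reason` column) are
#'   attached as attribute `"exclusions"`.
#' @export
filter_stable <- function(retest) {
  need <- c("relapses_pre", "relapses_retest", "edss_pre", "edss_w1", "edss_w2")
  miss <- setdiff(need, names(retest))
  if (length(miss)) {
    stop_mshrs(sprintf("Retest table lacks history columns: %s.",
                       paste(miss, collapse = ", ")), "mshrs_input_error")
  }
  reason <- dplyr::case_when(
    !complete.cases(retest[, need]) ~ "missing history",
    retest$relapses_pre > 0 ~ "relapse in pre-window",
    retest$relapses_retest > 0 ~ "relapse in retest window",
    retest$edss_w1 > retest$edss_pre ~ "EDSS increase in pre-window",
    retest$edss_w2 > retest$edss_w1 ~ "EDSS increase in retest window",
    TRUE ~ NA_character_
  )
  out <- retest[is.na(reason), , drop = FALSE]
  excl <- retest[!is.na(reason), , drop = FALSE]
  excl$reason <- reason[!is.na(reason)]
  attr(out, "exclusions") <- excl
  out
}

#' One-way random intraclass correlation, ICC(1,1)
#'
#' Test-retest reliability for single measurements from the one-way
#' random-effects ANOVA variance components. For two measurements per
#' subject, ICC(1,1) = (MSB - MSW) / (MSB + MSW), where MSB and MSW are the
#' between- and within-subject mean squares. Interpretation bands: below 0.5
#' poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param x1,x2 Paired measurements (test and retest), one element per
#'   subject; at least 3 complete pairs.
#' @return Object of class `mshrs_icc` with fields `n`, `icc`, `band`,
#'   `ms_between`, `ms_within`. Zero total variance is signalled as an error
#'   of class `mshrs_icc_undefined`.
#' @export
icc_oneway_random <- function(x1, x2) {
  keep <- stats::complete.cases(x1, x2)
  x1 <- x1[keep]; x2 <- x2[keep]
  n <- length(x1)
  if (n < 3L) {
    stop_mshrs("ICC needs at least 3 complete subject pairs.", "mshrs_input_error")
  }
  m <- cbind(x1, x2)
  grand <- mean(m)
  subj_means <- rowMeans(m)
  ms_between <- 2 * sum((subj_means - grand)^2) / (n - 1)
  ms_within <- sum((m - subj_means)^2) / n
  if (ms_between + ms_within < .Machine$double.eps * max(1, abs(grand))^2) {
    stop_mshrs("ICC undefined: total variance of the measurements is zero.",
               "mshrs_icc_undefined")
  }
  icc <- min(1, (ms_between - ms_within) / (ms_between + ms_within))
  structure(list(n = n, icc = icc, band = icc_band(icc),
                 ms_between = ms_between, ms_within = ms_within),
            class = "mshrs_icc")
}

#' @rdname icc_oneway_random
#' @param icc An ICC value in \[-1, 1\].
#' @export
icc_band <- function(icc) {
  dplyr::case_when(icc < 0.5 ~ "poor", icc < 0.75 ~ "moderate",
                   icc <= 0.9 ~ "good", TRUE ~ "excellent")
}

#' @export
print.mshrs_icc <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f (%s reliability), n = %d subjects\n",
              x$icc, x$band, x$n))
  invisible(x)
}

#' @export
tidy.mshrs_icc <- function(x, ...) {
  tibble(estimate = x$icc, band = x$band, n = x$n,
         ms_between = x$ms_between, ms_within = x$ms_within)
}

#' @export
glance.mshrs_icc <- function(x, ...) tidy(x)

# Guttman lower bounds --------------------------------------------------------

item_cov <- function(x, standardize) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    stop_mshrs("Guttman lambdas need at least 2 items.", "mshrs_input_error")
  }
  v <- apply(x, 2L, stats::var)
  zero <- which(v <= .Machine$double.eps)
  if (length(zero)) {
    stop_mshrs(sprintf("Zero-variance item(s): %s.",
                       paste(colnames(x)[zero] %||% zero, collapse = ", ")),
               "mshrs_degenerate_error")
  }
  if (standardize) x <- scale(x)
  stats::cov(x)
}

#' Guttman lambda-2 reliability lower bound
#'
#' From the item covariance matrix `C` with `k` items:
#' `lambda2 = (sum of off-diagonal covariances + sqrt(k/(k-1) * sum of
#' squared off-diagonal covariances)) / total variance of the sum score`.
#' For the instrument this is applied to the monetized, standardized
#' component costs excluding DMT.
#'
#' @param x Numeric matrix or data frame, respondents x items.
#' @param standardize Standardize items first (default `TRUE`, matching the
#'   "monetarized standardized items" convention).
#' @return The lambda-2 coefficient (at most 1).
#' @export
guttman_lambda2 <- function(x, standardize = TRUE) {
  guttman_lambda2_cov(item_cov(x, standardize))
}

#' @rdname guttman_lambda2
#' @param C An item covariance matrix.
#' @export
guttman_lambda2_cov <- function(C) {
  C <- as.matrix(C)
  k <- ncol(C)
  if (k < 2L) stop_mshrs("Guttman lambdas need at least 2 items.", "mshrs_input_error")
  vt <- sum(C)
  off <- C; diag(off) <- 0
  (sum(off) + sqrt(k / (k - 1) * sum(off^2))) / vt
}

#' Guttman lambda-6 reliability lower bound
#'
#' `lambda6 = 1 - sum_i e2_i / total variance`, where `e2_i` is the residual
#' variance of item `i` regressed on all other items (via the squared
#' multiple correlation, `e2_i = 1 / (C^-1)_ii`).
#'
#' @inheritParams guttman_lambda2
#' @return The lambda-6 coefficient (at most 1).
#' @export
guttman_lambda6 <- function(x, standardize = TRUE) {
  guttman_lambda6_cov(item_cov(x, standardize))
}

#' @rdname guttman_lambda6
#' @param C An item covariance matrix.
#' @export
guttman_lambda6_cov <- function(C) {
  C <- as.matrix(C)
  if (ncol(C) < 2L) stop_mshrs("Guttman lambdas need at least 2 items.", "mshrs_input_error")
  inv <- tryCatch(solve(C), error = function(e) {
    stop_mshrs("Item covariance matrix is singular; lambda-6 undefined.",
               "mshrs_degenerate_error")
  })
  e2 <- 1 / diag(inv)
  1 - sum(e2) / sum(C)
}

#' Monetized item matrix for consistency analysis
#'
#' Extracts the monetized component costs of a breakdown (excluding DMT by
#' convention) as the respondents x items matrix entering the Guttman
#' lambdas, dropping rows with any unanswered component.
#'
#' @param costs Breakdown tibble from [cost_responses()].
#' @return Numeric matrix, complete respondents x 12 components.
#' @export
monetized_item_matrix <- function(costs) {
  comp <- mshrs_cost_components(include_dmt = FALSE)
  m <- as.matrix(costs[, comp, drop = FALSE])
  m[stats::complete.cases(m), , drop = FALSE]
}

# rank tests and known groups -------------------------------------------------

#' Default EDSS strata for known-group analyses
#'
#' @return A named list of `c(lower, upper)` EDSS ranges (inclusive).
#' @export
mshrs_edss_bins <- function() {
  list("0-1.0" = c(0, 1.0), "1.5-2.5" = c(1.5, 2.5),
       "3.0-4.0" = c(3.0, 4.0), "4.5-5.5" = c(4.5, 5.5))
}

assign_bins <- function(edss, bins) {
  lab <- rep(NA_character_, length(edss))
  for (nm in names(bins)) {
    rng <- bins[[nm]]
    hit <- !is.na(edss) & edss >= rng[1] & edss <= rng[2]
    lab[hit] <- nm
  }
  factor(lab, levels = names(bins))
}

# Exhaustive permutation p-values for small samples: the observed rank
# statistic is compared against its full conditional distribution over all
# distinct assignments of the pooled observations to the groups.
exact_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_stat <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_stat(seq_len(nx))
  mu <- nx * ny / 2
  sets <- combn(nx + ny, nx)
  us <- apply(sets, 2L, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) h / tie_corr else 0
}

exact_kruskal_p <- function(values, groups) {
  groups <- as.factor(groups)
  h_obs <- kw_statistic(values, groups)
  n <- length(values)
  sizes <- table(groups)
  # enumerate all distinct assignments of the pooled values to group slots
  count <- 0L; hits <- 0L
  recurse <- function(remaining, gi, assignment) {
    if (gi == length(sizes)) {
      full <- assignment
      full[remaining] <- gi
      h <- kw_statistic(values, factor(full))
      count <<- count + 1L
      hits <<- hits + as.integer(h >= h_obs - 1e-12)
      return(invisible())
    }
    picks <- combn(remaining, sizes[gi])
    for (j in seq_len(ncol(picks))) {
      a <- assignment
      a[picks[, j]] <- gi
      recurse(setdiff(remaining, picks[, j]), gi + 1L, a)
    }
  }
  recurse(seq_len(n), 1L, rep(NA_integer_, n))
  hits / count
}

#' Known-group analysis of costs across EDSS strata
#'
#' Construct validity by known groups: respondents are stratified into
#' predefined EDSS ranges, per-stratum cost summaries are reported, group
#' differences are tested with an omnibus Kruskal-Wallis H test, and all
#' pairwise contrasts with Mann-Whitney U tests under Bonferroni correction
#' (adjusted p = min(1, raw p x number of pairwise comparisons), one family
#' per outcome). Respondents whose EDSS falls outside every stratum (e.g.
#' above 5.5) are excluded and counted.
#'
#' @param costs Per-respondent cost totals (conventionally excluding DMT).
#' @param edss Per-respondent EDSS scores, same length.
#' @param bins Named list of EDSS ranges, see [mshrs_edss_bins()].
#' @param exact Use exhaustive permutation p-values (only feasible for tiny
#'   samples, total n at most about 12).
#' @return Object of class `mshrs_known_group`: `summary` (per-stratum n,
#'   mean, sd, median), `omnibus` (H statistic, df, p), `pairwise` (tibble
#'   with raw and Bonferroni-adjusted p-values), `n_excluded`.
#' @export
known_group_analysis <- function(costs, edss, bins = mshrs_edss_bins(),
                                 exact = FALSE) {
  if (length(costs) != length(edss)) {
    stop_mshrs("`costs` and `edss` must have the same length.", "mshrs_input_error")
  }
  keep <- !is.na(costs) & !is.na(edss)
  grp <- assign_bins(edss[keep], bins)
  x <- costs[keep]
  n_excluded <- sum(is.na(grp)) + sum(!keep)
  x <- x[!is.na(grp)]; grp <- droplevels(grp[!is.na(grp)], exclude = NULL)
  grp <- factor(as.character(grp), levels = names(bins))
  counts <- table(grp)
  if (any(counts == 0L)) {
    stop_mshrs(sprintf("Empty EDSS stratum(s): %s.",
                       paste(names(counts)[counts == 0L], collapse = ", ")),
               "mshrs_empty_group_error")
  }
  smry <- tibble(bin = names(bins)) %>%
    mutate(n = as.integer(counts[.data$bin]),
           mean = vapply(.data$bin, function(b) mean(x[grp == b]), numeric(1)),
           sd = vapply(.data$bin, function(b) sd(x[grp == b]), numeric(1)),
           median = vapply(.data$bin, function(b) median(x[grp == b]), numeric(1)))
  h_obs <- kw_statistic(x, grp)
  omni_p <- if (exact) {
    exact_kruskal_p(x, grp)
  } else {
    kruskal.test(x, grp)$p.value
  }
  pairs <- combn(names(bins), 2L)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- x[grp == a]; xb <- x[grp == b]
    if (exact) {
      p <- exact_mann_whitney_p(xa, xb)
      u <- sum(rank(c(xa, xb))[seq_along(xa)]) - length(xa) * (length(xa) + 1) / 2
    } else {
      wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE, correct = TRUE))
      p <- wt$p.value; u <- unname(wt$statistic)
    }
    tibble(bin_a = a, bin_b = b, statistic = u, p_raw = p,
           p_adj = min(1, p * n_pairs))
  })
  structure(list(summary = smry,
                 omnibus = list(statistic = h_obs, df = length(bins) - 1L,
                                p_value = omni_p),
                 pairwise = pairwise, n_excluded = n_excluded,
                 data = tibble(cost = x, bin = grp)),
            class = "mshrs_known_group")
}

#' @export
print.mshrs_known_group <- function(x, ...) {
  cat("Known-group analysis across EDSS strata\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("Kruskal-Wallis H = %.2f, df = %d, p = %.3g (%d excluded)\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value, x$n_excluded))
  invisible(x)
}

#' @export
tidy.mshrs_known_group <- function(x, ...) x$pairwise

#' @export
glance.mshrs_known_group <- function(x, ...) {
  tibble(statistic = x$omnibus$statistic, df = x$omnibus$df,
         p_value = x$omnibus$p_value, n = sum(x$summary$n),
         n_excluded = x$n_excluded)
}

#' Plot a known-group analysis
#'
#' Boxplots of cost by EDSS stratum on a square-root scale.
#'
#' @param object An `mshrs_known_group` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mshrs_known_group <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$bin, y = .data$cost)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "EDSS stratum", y = "Cost per quarter (EUR)") +
    ggplot2::theme_minimal()
}

# correlations ----------------------------------------------------------------

#' Convergent and discriminant validity correlations
#'
#' Spearman rank correlations of cost totals with patient-reported outcome
#' (PRO) summary scores, pairwise-complete. Convergent validity expects
#' correlations above 0.40 with disability/activity scales; discriminant
#' validity expects correlations clearly below 0.3 in magnitude with
#' treatment-satisfaction scales.
#'
#' @param costs Per-respondent cost totals.
#' @param pro_scores Tibble of PRO summary-score columns (one per
#'   instrument), rows aligned with `costs`.
#' @param min_pairs Minimum number of complete pairs per instrument.
#' @return Tibble with columns `instrument`, `n`, `rho`, `p_value`. A
#'   constant vector yields `NA` with a warning (undefined correlation).
#' @export
convergent_discriminant <- function(costs, pro_scores, min_pairs = 10L) {
  pro_scores <- as_tibble(pro_scores)
  purrr::map_dfr(names(pro_scores), function(nm) {
    y <- pro_scores[[nm]]
    keep <- !is.na(costs) & !is.na(y)
    n <- sum(keep)
    if (n < min_pairs) {
      stop_mshrs(sprintf("Instrument '%s' has only %d complete pairs (minimum %d).",
                         nm, n, min_pairs), "mshrs_input_error")
    }
    if (sd(costs[keep]) == 0 || sd(y[keep]) == 0) {
      warn(sprintf("Correlation with '%s' undefined: constant vector.", nm))
      return(tibble(instrument = nm, n = n, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(costs[keep], y[keep], method = "spearman",
                                    exact = FALSE))
    tibble(instrument = nm, n = n, rho = unname(ct$estimate),
           p_value = ct$p.value)
  })
}

#' Compare completers and noncompleters
#'
#' Selection-bias check: contrasts survey completers against noncompleters
#' on age, sex, EDSS and disease duration, using Mann-Whitney U tests for
#' continuous variables and a chi-square test for sex.
#'
#' @param records Respondent tibble with `completed_survey` plus the
#'   contrast variables.
#' @return Tibble with per-variable group means/proportions, test used, and
#'   p-value.
#' @export
completer_comparison <- function(records) {
  if (!"completed_survey" %in% names(records)) {
    stop_mshrs("Column 'completed_survey' is required.", "mshrs_input_error")
  }
  comp <- records[records$completed_survey %in% TRUE, , drop = FALSE]
  nonc <- records[records$completed_survey %in% FALSE, , drop = FALSE]
  if (nrow(comp) == 0L || nrow(nonc) == 0L) {
    stop_mshrs("Both completer and noncompleter groups must be nonempty.",
               "mshrs_empty_group_error")
  }
  rows <- list()
  for (v in intersect(c("age", "edss", "disease_duration_years"), names(records))) {
    x <- comp[[v]][!is.na(comp[[v]])]; y <- nonc[[v]][!is.na(nonc[[v]])]
    p <- if (length(x) && length(y)) {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    } else NA_real_
    rows[[v]] <- tibble(variable = v, test = "Mann-Whitney U",
                        completers = mean(x), noncompleters = mean(y), p_value = p)
  }
  if ("sex" %in% names(records)) {
    tab <- table(records$completed_survey, records$sex)
    p <- if (all(dim(tab) >= 2)) {
      suppressWarnings(chisq.test(tab)$p.value)
    } else NA_real_
    rows[["sex"]] <- tibble(
      variable = "sex (female)", test = "chi-square",
      completers = mean(comp$sex == "female", na.rm = TRUE),
      noncompleters = mean(nonc$sex == "female", na.rm = TRUE), p_value = p)
  }
  bind_rows(rows)
}

# assembled reliability report -------------------------------------------------

#' Reliability report: stable-subgroup ICC and Guttman lambdas
#'
#' Assembles the instrument's reliability evidence: filters the stable
#' subgroup from paired-wave data, estimates the one-way random ICC of the
#' paired total-cost measurements, and computes Guttman lambda-2/lambda-6
#' over the monetized standardized items (excluding DMT).
#'
#' @param retest Paired-wave tibble with histories and measurement columns
#'   `cost_w1`, `cost_w2` (see [generate_retest()]).
#' @param item_matrix Respondents x monetized-items matrix, see
#'   [monetized_item_matrix()]; `NULL` skips the lambdas.
#' @return Object of class `mshrs_reliability` with `n_stable`, `icc`,
#'   `icc_band`, `lambda2`, `lambda6`. If no stable patients remain or the
#'   ICC is undefined, `icc` is `NA` with `status = "reliability undefined"`.
#' @export
reliability_report <- function(retest, item_matrix = NULL) {
  stable <- filter_stable(retest)
  icc_obj <- tryCatch(
    if (nrow(stable) >= 3L) icc_oneway_random(stable$cost_w1, stable$cost_w2) else NULL,
    mshrs_icc_undefined = function(e) NULL
  )
  lambdas <- if (!is.null(item_matrix) && ncol(item_matrix) >= 2L) {
    list(l2 = guttman_lambda2(item_matrix), l6 = guttman_lambda6(item_matrix))
  } else {
    list(l2 = NA_real_, l6 = NA_real_)
  }
  structure(list(
    n_stable = nrow(stable),
    n_excluded = nrow(attr(stable, "exclusions") %||% tibble()),
    icc = if (is.null(icc_obj)) NA_real_ else icc_obj$icc,
    icc_band = if (is.null(icc_obj)) NA_character_ else icc_obj$band,
    lambda2 = lambdas$l2, lambda6 = lambdas$l6,
    status = if (is.null(icc_obj)) "reliability undefined" else "ok"
  ), class = "mshrs_reliability")
}

#' @export
print.mshrs_reliability <- function(x, ...) {
  cat(sprintf("Reliability: n_stable = %d (excluded %d)\n", x$n_stable, x$n_excluded))
  if (x$status == "ok") {
    cat(sprintf("  ICC(1,1) = %.3f (%s)\n", x$icc, x$icc_band))
  } else {
    cat("  ICC: reliability undefined (no stable variance)\n")
  }
  cat(sprintf("  Guttman lambda2 = %.3f, lambda6 = %.3f\n", x$lambda2, x$lambda6))
  invisible(x)
}

#' @export
tidy.mshrs_reliability <- function(x, ...) {
  tibble(n_stable = x$n_stable, icc = x$icc, icc_band = x$icc_band,
         lambda2 = x$lambda2, lambda6 = x$lambda6, status = x$status)
}

#' @export
glance.mshrs_reliability <- function(x, ...) tidy(x)
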