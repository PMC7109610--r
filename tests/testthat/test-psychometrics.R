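# Reliability and validity statistics: stable filtering, ICC, Guttman
# lambdas, rank tests against exhaustive oracles, correlations.

test_that("stable-subgroup filtering follows the relapse/EDSS criteria", {
  rt <- tibble::tibble(
    respondent_id = c("A", "B", "C", "D", "E"),
    edss_pre = c(2.0, 2.0, 2.0, NA, 1.5),
    edss_w1 = c(2.0, 2.0, 2.0, 2.0, 2.0), # E worsened in the pre-window
    edss_w2 = c(2.0, 2.5, 2.0, 2.0, 2.0), # B worsened in the retest window
    relapses_pre = c(0, 0, 1, 0, 0),      # C relapsed before baseline
    relapses_retest = 0,
    cost_w1 = 1, cost_w2 = 1
  )
  st <- filter_stable(rt)
  expect_equal(st$respondent_id, "A")
  excl <- attr(st, "exclusions")
  expect_equal(nrow(excl), 4L)
  expect_setequal(excl$reason[excl$respondent_id == "D"], "missing history")
  expect_match(excl$reason[excl$respondent_id == "E"], "pre-window")
})

test_that("ICC(1,1) matches a one-way ANOVA oracle and its limiting cases", {
  # exact agreement on identical pairs
  x <- c(3, 7, 1, 9, 5)
  expect_equal(icc_oneway_random(x, x)$icc, 1)

  # small fixture against an independently fitted ANOVA table
  x1 <- c(1, 2, 3, 4); x2 <- c(1, 2, 3, 5)
  long <- data.frame(y = c(x1, x2), s = factor(rep(1:4, 2)))
  tab <- anova(stats::lm(y ~ s, data = long))
  msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
  expect_equal(icc_oneway_random(x1, x2)$icc, (msb - msw) / (msb + msw))

  # independent pairs have ICC near zero
  withr::with_seed(101, {
    a <- rnorm(10000); b <- rnorm(10000)
    expect_lt(abs(icc_oneway_random(a, b)$icc), 0.05)
  })

  expect_error(icc_oneway_random(c(1, 1), c(1, 1)), class = "mshrs_input_error")
  expect_error(icc_oneway_random(rep(2, 5), rep(2, 5)),
               class = "mshrs_icc_undefined")
})

test_that("ICC bands follow the 0.5/0.75/0.9 cutoffs", {
  expect_equal(icc_band(c(0.2, 0.5, 0.6, 0.75, 0.85, 0.9, 0.95)),
               c("poor", "moderate", "moderate", "good", "good", "good",
                 "excellent"))
})

test_that("Guttman lambdas match direct formula evaluation on toy matrices", {
  # compound symmetry, 3 items, unit variances, rho = 0.5:
  # lambda2 = (3 + sqrt(3/2 * 6 * 0.25)) / 6 = 0.75
  # lambda6 = 1 - 3 * (2/3) / 6 = 2/3
  C <- matrix(0.5, 3, 3); diag(C) <- 1
  expect_equal(guttman_lambda2_cov(C), 0.75)
  expect_equal(guttman_lambda6_cov(C), 2 / 3)

  # perfectly parallel items
  withr::with_seed(7, {
    x <- rnorm(500)
    expect_equal(guttman_lambda2(cbind(x, x)), 1)
    m <- cbind(x, x + rnorm(500, 0, 1e-4))
    expect_gt(guttman_lambda6(m), 0.999)
  })

  # independent items at large n are near zero
  withr::with_seed(8, {
    m <- matrix(rnorm(5 * 20000), ncol = 5)
    expect_lt(abs(guttman_lambda2(m)), 0.1)
    expect_lt(abs(guttman_lambda6(m)), 0.1)
  })

  expect_error(guttman_lambda2(matrix(1:5, ncol = 1)), class = "mshrs_input_error")
  expect_error(guttman_lambda2(cbind(a = rnorm(10), b = rep(2, 10))),
               class = "mshrs_degenerate_error")
  sing <- matrix(1, 3, 3)
  expect_error(guttman_lambda6_cov(sing), class = "mshrs_degenerate_error")
})

test_that("lambda-2 dominates the alpha-type lower bound on random matrices", {
  withr::with_seed(42, {
    for (i in 1:20) {
      k <- sample(3:8, 1)
      L <- matrix(rnorm(k * k), k)
      C <- crossprod(L) + diag(k)
      vt <- sum(C)
      alpha <- k / (k - 1) * (1 - sum(diag(C)) / vt) # Guttman lambda-3
      expect_gte(guttman_lambda2_cov(C) + 1e-12, alpha)
    }
  })
})

test_that("reliability statistics are invariant under positive scaling of costs", {
  withr::with_seed(13, {
    m <- matrix(rlnorm(200 * 4), ncol = 4)
    x1 <- rnorm(50); x2 <- x1 + rnorm(50, 0, 0.5)
    expect_equal(guttman_lambda2(m), guttman_lambda2(m * 1000))
    expect_equal(guttman_lambda6(m), guttman_lambda6(m * 1000))
    expect_equal(icc_oneway_random(x1, x2)$icc,
                 icc_oneway_random(x1 * 1000, x2 * 1000)$icc)
  })
})

test_that("known-group analysis degenerates correctly on identical groups", {
  costs <- rep(1:25, 4)
  edss <- rep(c(0.5, 2.0, 3.5, 5.0), each = 25)
  kg <- known_group_analysis(costs, edss)
  expect_lt(kg$omnibus$statistic, 1e-10)
  expect_gt(kg$omnibus$p_value, 0.99)
  expect_true(all(kg$pairwise$p_adj > 0.99))
  expect_equal(kg$summary$n, rep(25L, 4))
})

test_that("records outside every stratum are excluded and counted; empty strata error", {
  costs <- c(1:8, 100, 200)
  edss <- c(0.5, 0.5, 2, 2, 3.5, 3.5, 5, 5, 6.0, 7.5)
  kg <- known_group_analysis(costs, edss)
  expect_equal(kg$n_excluded, 2L)
  expect_error(known_group_analysis(1:6, c(0.5, 0.5, 2, 2, 3.5, 3.5)),
               class = "mshrs_empty_group_error")
})

test_that("pairwise tests agree with exhaustive permutation oracles at tiny n", {
  # fully separated supports, custom two-stratum analysis
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  edss <- c(0.5, 0.5, 0.5, 0.5, 3.0, 3.0, 3.0, 3.0)
  bins <- list(lo = c(0, 1), hi = c(3, 4))
  kg <- known_group_analysis(x, edss, bins = bins, exact = TRUE)
  # brute-force two-sided tail over all C(8,4) assignments
  pooled <- x
  u_of <- function(idx) sum(rank(pooled)[idx]) - 4 * 5 / 2
  us <- apply(utils::combn(8, 4), 2, u_of)
  p_oracle <- mean(abs(us - 8) >= abs(u_of(1:4) - 8))
  expect_equal(kg$pairwise$p_raw[1], p_oracle)
  expect_equal(kg$pairwise$p_raw[1], 2 / choose(8, 4))
  # matches the exact distribution used by wilcox.test as a cross-check
  expect_equal(kg$pairwise$p_raw[1],
               wilcox.test(x[1:4], x[5:8], exact = TRUE)$p.value)
  expect_equal(kg$pairwise$p_adj[1], min(1, p_oracle * 1))
})

test_that("the omnibus test agrees with an exhaustive permutation oracle at tiny n", {
  withr::with_seed(33, {
    vals <- c(2.3, 0.1, 5.2, 1.1, 9.9, 3.3, 7.5, 0.4, 6.6)
    edss <- rep(c(0.5, 2.0, 3.5), each = 3)
    bins <- list(a = c(0, 1), b = c(1.5, 2.5), d = c(3, 4))
    kg <- known_group_analysis(vals, edss, bins = bins, exact = TRUE)
    # test-side oracle: nested combinations enumerate all 9!/(3!3!3!) splits
    kwh <- function(assign) {
      r <- rank(vals)
      n <- 9
      12 / (n * (n + 1)) *
        sum(tapply(r, assign, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
    }
    h_obs <- kwh(rep(1:3, each = 3))
    count <- 0; hits <- 0
    for (i in seq_len(ncol(utils::combn(9, 3)))) {
      g1 <- utils::combn(9, 3)[, i]
      rest <- setdiff(1:9, g1)
      for (j in seq_len(ncol(utils::combn(6, 3)))) {
        g2 <- rest[utils::combn(6, 3)[, j]]
        assign <- integer(9); assign[g1] <- 1; assign[g2] <- 2
        assign[assign == 0] <- 3
        count <- count + 1
        hits <- hits + (kwh(assign) >= h_obs - 1e-12)
      }
    }
    expect_equal(kg$omnibus$p_value, hits / count)
  })
})

test_that("Spearman correlations match a brute-force rank computation", {
  x <- c(10, 4, 7, 1, 12)
  y <- c(3, 9, 2, 8, 1)
  got <- convergent_discriminant(x, tibble::tibble(inst = y), min_pairs = 5)
  rx <- rank(x); ry <- rank(y)
  r_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, r_hand)

  self <- convergent_discriminant(x, tibble::tibble(self = x), min_pairs = 5)
  expect_equal(self$rho, 1)

  withr::with_seed(55, {
    big <- rnorm(10000)
    noise <- convergent_discriminant(big, tibble::tibble(z = rnorm(10000)))
    expect_lt(abs(noise$rho), 0.05)
  })

  expect_warning(
    out <- convergent_discriminant(x, tibble::tibble(flat = rep(1, 5)),
                                   min_pairs = 5),
    "undefined")
  expect_true(is.na(out$rho))
  expect_error(convergent_discriminant(x, tibble::tibble(few = y)),
               class = "mshrs_input_error")
})

test_that("completer comparison contrasts groups on the demographic variables", {
  rec <- make_respondents(60, completed = rep(c(TRUE, FALSE), each = 30))
  # identical distributions everywhere
  same <- completer_comparison(rec)
  expect_true(all(same$p_value > 0.9, na.rm = TRUE))

  # groups differing only in duration: the duration contrast is significant
  # and the null contrasts nonsignificant in nearly all replicates
  withr::with_seed(77, {
    hits_dur <- 0; hits_null <- 0
    for (i in 1:20) {
      rec2 <- make_respondents(400, completed = rep(c(TRUE, FALSE), each = 200))
      rec2$age <- rnorm(400, 42, 10)
      rec2$edss <- sample(seq(0, 6, 0.5), 400, replace = TRUE)
      rec2$disease_duration_years <- rnorm(400, 7, 5) +
        ifelse(rec2$completed_survey, 0, 2)
      cmp <- completer_comparison(rec2)
      hits_dur <- hits_dur +
        (cmp$p_value[cmp$variable == "disease_duration_years"] < 0.05)
      hits_null <- hits_null +
        (cmp$p_value[cmp$variable == "age"] > 0.05 &&
           cmp$p_value[cmp$variable == "edss"] > 0.05)
    }
    expect_gte(hits_dur, 19)
    expect_gte(hits_null, 17)
  })

  expect_error(completer_comparison(make_respondents(5)),
               class = "mshrs_empty_group_error")
})

test_that("reliability report assembles ICC and lambdas with explicit undefined status", {
  coh <- generate_cohort(cohort_spec(n = 400), seed = 21)
  costs <- cost_responses(coh, include_dmt = FALSE)
  spec <- cohort_spec(n = 400, retest = list(between_sd = 1100, within_sd = 0,
                                             p_relapse_pre = 0.2,
                                             p_relapse_retest = 0.2,
                                             p_edss_increase = 0.1))
  rt <- generate_retest(coh, spec, seed = 2, costs = costs$total_excl_dmt)
  rep1 <- reliability_report(rt, monetized_item_matrix(costs))
  expect_equal(rep1$icc, 1)
  expect_equal(rep1$icc_band, "excellent")
  expect_lte(rep1$lambda2, 1)
  expect_lte(rep1$lambda6, 1)

  # every subject unstable -> reliability undefined, not an error
  rt2 <- rt
  rt2$relapses_retest <- 1
  rep2 <- reliability_report(rt2, monetized_item_matrix(costs))
  expect_equal(rep2$status, "reliability undefined")
  expect_true(is.na(rep2$icc))
  expect_equal(rep2$n_stable, 0L)
})
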