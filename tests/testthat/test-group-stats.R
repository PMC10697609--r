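test_that("correlations behave under transforms and degenerate input", {
  x <- 1:20
  r <- correlate(x, 2 * x + 1, "pearson", n_boot = 0)
  expect_equal(r$statistic, 1)
  expect_lt(r$p_value, 1e-10)
  y <- exp(x / 5)
  expect_equal(correlate(x, y, "spearman", n_boot = 0)$statistic, 1)
  expect_lt(correlate(x, y, "pearson", n_boot = 0)$statistic, 1)
  # Spearman invariant to strictly monotone transforms, Pearson to affine
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(correlate(a, b, "spearman", n_boot = 0)$statistic,
               correlate(exp(a), b^3 + 5 * b, "spearman",
                         n_boot = 0)$statistic)
  expect_equal(correlate(a, b, "pearson", n_boot = 0)$statistic,
               correlate(3 * a - 2, b / 7 + 1, "pearson",
                         n_boot = 0)$statistic)
  expect_error(correlate(rep(1, 10), rnorm(10), n_boot = 0),
               "zero variance")
  expect_error(correlate(1:3, 3:1, n_boot = 0), "at least 4")
  # listwise deletion of incomplete pairs
  xm <- c(a, NA); ym <- c(b, 1)
  expect_equal(correlate(xm, ym, "pearson", n_boot = 0)$n_used, 50L)
})

test_that("bootstrap CI brackets the estimate and attains nominal coverage", {
  set.seed(12)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  r <- correlate(x, y, "pearson", n_boot = 500, seed = 9)
  expect_true(r$ci_low <= r$statistic && r$statistic <= r$ci_high)
  expect_identical(r, correlate(x, y, "pearson", n_boot = 500, seed = 9))

  rho <- 0.3
  hits <- vapply(seq_len(200), function(k) {
    set.seed(3000 + k)
    u <- rnorm(200)
    v <- rho * u + sqrt(1 - rho^2) * rnorm(200)
    ci <- correlate(u, v, "pearson", n_boot = 300, seed = k)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("Bonferroni uses the fixed four-comparison family", {
  expect_equal(bonferroni(0.01), 0.04)
  expect_equal(bonferroni(0.5), 1)
  expect_equal(bonferroni(c(0.2, 0.03), m = 1), c(0.2, 0.03))
  expect_error(bonferroni(1.2), "p_values")
})

test_that("signed-rank test against optimality is calibrated", {
  # exactly symmetric differences: no evidence of miscalibration
  d <- c(seq(0.01, 0.25, length.out = 25), -seq(0.01, 0.25,
                                                length.out = 25))
  r <- wilcoxon_vs_optimal(0.5 + d, 0.5)
  expect_gte(r$p_value, 0.9)
  expect_equal(r$n_used, 50L)
  # uniform shift is detected
  set.seed(6)
  shift <- wilcoxon_vs_optimal(0.6 + abs(rnorm(20, 0, 0.01)), 0.5)
  expect_lt(shift$p_value, 0.01)
  expect_equal(wilcoxon_vs_optimal(rep(0.47, 10), 0.47)$p_value, 1)
  expect_error(wilcoxon_vs_optimal(rep(0.5, 4), 0.4), "at least 6")
})

test_that("paired t detects shifts and is inert on identical vectors", {
  same <- paired_t(1:10 / 10, 1:10 / 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(7)
  a <- rnorm(30)
  r <- paired_t(a + 0.5, a + rnorm(30, 0, 0.01))
  expect_lt(r$p_value, 1e-10)
  expect_true(r$ci_low > 0)
  expect_error(paired_t(a, a + 2), "zero variance")
})

test_that("estimation error is larger under the wide likelihood in silico", {
  co <- simulate_cohort(cohort_spec(n_participants = 100, seed = 55))
  m <- compute_metrics(co$trials_main, co$trials_likonly)
  r <- paired_t(m$err_likonly_Lw, m$err_likonly_Ln)
  expect_gt(r$statistic, 0)
  expect_lt(r$p_value, 0.05)
})

test_that("two-way ANOVA isolates constructed effects on a balanced design", {
  ids <- sprintf("p%02d", 1:40)
  grid <- expand.grid(participant_id = ids,
                      prior_cond = c("narrow", "wide"),
                      lik_cond = c("narrow", "wide"),
                      stringsAsFactors = FALSE)
  # participant-only variation: factor F statistics are exactly zero
  set.seed(20)
  base <- rnorm(40, 0, 0.1)[match(grid$participant_id, ids)]
  flat <- cbind(grid, value = base)
  av0 <- two_way_anova(flat)
  expect_equal(av0$statistic, rep(0, 3), tolerance = 1e-10)
  # shift on wide-prior cells only
  set.seed(21)
  eff <- cbind(grid, value = base + 0.5 * (grid$prior_cond == "wide") +
                 rnorm(nrow(grid), 0, 0.1))
  av <- two_way_anova(eff)
  expect_lt(av$p_value[av$name == "prior"], 1e-6)
  expect_gt(av$p_value[av$name == "likelihood"], 0.05)
  means <- attr(av, "cell_means")
  expect_gt(mean(means["wide", ]), mean(means["narrow", ]))
  # balanced orthogonality: factor order cannot matter
  swapped <- two_way_anova(eff, prior = "lik_cond", likelihood = "prior_cond")
  expect_equal(sort(swapped$statistic), sort(av$statistic))
  # missing cells are reported by participant
  expect_error(two_way_anova(eff[-1, ]), "p01")
  eff$value[2] <- NA
  expect_error(two_way_anova(eff), "missing cell")
})

test_that("correlation power analysis is monotone and solves the design n", {
  expect_identical(power_n_correlation(0.10, 0.80, 0.05), 782L)
  n_small <- power_n_correlation(0.5)
  expect_lt(n_small, 100)
  expect_gt(power_n_correlation(0.1, power = 0.95),
            power_n_correlation(0.1, power = 0.8))
  expect_gt(power_n_correlation(0.05), power_n_correlation(0.1))
  expect_error(power_n_correlation(1.2), "between 0 and 1")
  expect_error(power_n_correlation(-0.1), "between 0 and 1")
})

test_that("headline battery is ordered, adjusted, and deterministic", {
  co <- simulate_cohort(cohort_spec(n_participants = 40, seed = 91))
  fit <- quiet_fit(co)
  res <- suppressMessages(
    run_headline_analyses(fit, n_boot = 100, seed = 5))
  expect_equal(res$name[1], "sw_global~log_cape_p")
  expect_equal(res$estimator[1], "pearson")
  expect_true(all(c("sensitivity_prior_change~cape_p",
                    "subj_prior_var~cape_p", "subj_lik_var~cape_p") %in%
                    res$name))
  expect_equal(res$p_adjusted, pmin(1, 4 * res$p_value))
  has_ci <- !is.na(res$ci_low)
  expect_true(all(res$ci_low[has_ci] <= res$statistic[has_ci] &
                    res$statistic[has_ci] <= res$ci_high[has_ci]))
  res2 <- suppressMessages(
    run_headline_analyses(fit, n_boot = 100, seed = 5))
  expect_identical(res, res2)
  # orphan participants are an error
  expect_error(
    run_headline_analyses(fit$metrics, fit$participants[-1, ], n_boot = 0),
    "missing from the participant table")
  expect_error(
    run_headline_analyses(fit$metrics[1:5, ], fit$participants, n_boot = 0),
    "remain after exclusions")
})
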