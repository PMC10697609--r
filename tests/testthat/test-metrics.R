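trial_frame <- function(mu_L, response, prior_cond = "narrow",
                        lik_cond = "narrow", block = 1,
                        coin_pos = NULL, task = "main") {
  n <- length(mu_L)
  data.frame(participant_id = "p1", task = task, block_index = block,
             trial_index = seq_len(n), prior_cond = prior_cond,
             lik_cond = lik_cond, mu_L = mu_L,
             coin_pos = coin_pos %||% mu_L, response = response)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mean estimation error averages absolute distances", {
  tr <- trial_frame(c(0, 0), c(0.1, -0.3))
  expect_equal(mean_estimation_error(tr, "coin"), 0.2)
  expect_equal(mean_estimation_error(trial_frame(c(0.5, 0.2), c(0.5, 0.2)),
                                     "centroid"), 0)
  expect_error(mean_estimation_error(tr, "coin", lik_cond = "wide"),
               "no trials")
})

test_that("sensory-weight regression matches lm and handles edge cases", {
  mu <- seq(-0.3, 0.3, length.out = 20)
  expect_equal(fit_sensory_weight(trial_frame(mu, 0.3 * mu)), 0.3)
  expect_equal(fit_sensory_weight(trial_frame(mu, rep(0, 20))), 0)
  set.seed(4)
  y <- 0.6 * mu + 0.1 + rnorm(20, 0, 0.05)
  expect_equal(fit_sensory_weight(trial_frame(mu, y)),
               unname(coef(lm(y ~ mu))[2]))
  expect_error(fit_sensory_weight(trial_frame(rep(0.2, 10), rnorm(10))),
               "zero variance")
  expect_error(fit_sensory_weight(trial_frame(mu[1:2], y[1:2])),
               "at least 3")
})

test_that("optimal weights take their analytic values and ordering", {
  d <- coin_design()
  sw <- optimal_benchmarks(d)$sw_opt
  expect_equal(round(unname(sw), 4), c(0.4647, 0.1220, 0.9094, 0.6162))
  expect_true(sw["PwLn"] > sw["PwLw"] &&
                sw["PwLw"] > sw["PnLn"] && sw["PnLn"] > sw["PnLw"])
  deq <- coin_design(prior_sd_narrow = 0.1,
                     splash_sd_narrow = 0.1 * sqrt(5))
  expect_equal(optimal_sensory_weight(deq, "narrow", "narrow"), 0.5)
  # literal printed-variance convention stays available
  lit <- optimal_benchmarks(d, mode = "literal")$sw_opt
  expect_equal(unname(lit["PnLn"]), 0.0016 / (0.0016 + 0.09625))
  expect_equal(unname(lit["PwLw"]), 0.136^2 / (0.136^2 + 0.2425))
  # monotone in prior variance, antitone in likelihood variance
  grid <- expand.grid(p = c(0.02, 0.05, 0.1), l = c(0.05, 0.1, 0.2))
  w <- mapply(function(p, l) {
    dd <- coin_design(prior_sd_narrow = p, splash_sd_narrow = l)
    optimal_sensory_weight(dd, "narrow", "narrow")
  }, grid$p, grid$l)
  m <- matrix(w, 3, 3)
  expect_true(all(diff(m) > 0))     # rows: increasing prior SD
  expect_true(all(t(diff(t(m))) < 0)) # cols: increasing splash SD
})

test_that("sensitivity to prior change is the mean absolute block step", {
  expect_equal(sensitivity_to_prior_change(c(0.2, 0.6, 0.2, 0.6)), 0.4)
  expect_equal(sensitivity_to_prior_change(rep(0.5, 4)), 0)
  expect_equal(sensitivity_to_prior_change(c(0, 1, 0, 1)), 1)
  expect_error(sensitivity_to_prior_change(c(0.2, NA, 0.3, 0.4)),
               "complete")
})

test_that("trial-wise weights pass through the clamped logistic", {
  w <- trial_sensory_weight(response = c(0.2, 0, 0.4, 0.1),
                            mu_L = c(0.2, 0.2, 0.2, 0), mu_P = 0)
  expect_equal(w$raw[1:3], c(1, 0, 2))
  expect_equal(w$logistic[1:3], plogis(c(1, 0, 2)))
  expect_equal(round(w$logistic[1:3], 4), c(0.7311, 0.5, 0.8808))
  expect_true(is.na(w$raw[4]) && is.na(w$logistic[4]))  # mu_L == mu_P
  # clamp keeps near-degenerate trials finite
  ex <- trial_sensory_weight(1, 1e-9)
  expect_equal(ex$logistic, plogis(50))
})

test_that("trial-weight variance uses n-1 and respects the 0.25 bound", {
  mu <- rep(0.2, 10)
  expect_equal(trial_sw_variance(trial_frame(mu, 0.5 * mu)), 0)
  # half the trials at raw weight 0, half at raw weight 1
  tr <- trial_frame(rep(0.2, 200), rep(c(0, 0.2), each = 100))
  expect_equal(trial_sw_variance(tr),
               var(rep(c(0.5, plogis(1)), each = 100)))
  expect_equal(trial_sw_variance(tr), 0.01341408, tolerance = 1e-5)
  set.seed(8)
  rnd <- trial_frame(runif(500, -0.5, 0.5), runif(500, -0.8, 0.8))
  expect_lte(trial_sw_variance(rnd), 0.25)
  expect_error(trial_sw_variance(trial_frame(0.2, 0.1)), "at least 2")
})

test_that("subjective likelihood variance is the population mean square", {
  lik <- trial_frame(c(0, 0), c(0.1, -0.1), prior_cond = "none",
                     task = "likelihood_only")
  expect_equal(subjective_likelihood_variance(lik), 0.01)
  expect_equal(subjective_likelihood_variance(
    trial_frame(c(0.3, -0.2), c(0.3, -0.2), task = "likelihood_only")), 0)
  # moment recovery from a simulated calibration session
  d <- coin_design(n_likelihood_only_trials = 10000)
  o <- sample_observer(
    cohort_spec(perceptual_noise_sd = 0.07, motor_noise_sd = 0,
                lapse_rate = 0, beta_prior = 0, beta_lik = 0,
                sigma_between = 0, seed = 1), d, "p1", seed = 2)
  lik <- simulate_response(generate_likelihood_only_task(d, "p1", seed = 3),
                           o, d, seed = 4)
  expect_lt(abs(subjective_likelihood_variance(lik) / 0.07^2 - 1), 0.05)
})

test_that("prior-variance inversion is the algebraic inverse of the weight", {
  expect_equal(subjective_prior_variance(0.004, 0.5), 0.004)
  # round trip on a small grid
  for (vp in c(1e-4, 0.002, 0.05)) for (vl in c(1e-3, 0.01, 0.2)) {
    sw <- vp / (vp + vl)
    expect_equal(subjective_prior_variance(vl, sw), vp, tolerance = 1e-12)
  }
  expect_true(is.na(subjective_prior_variance(0.01, 1)))
  expect_true(is.na(subjective_prior_variance(0.01, 1.3)))
  expect_warning(out <- subjective_prior_variance(0.01, -0.2), "clamped")
  expect_equal(out, 0)
  # imposed variant: optimal weight and true centroid variance return the
  # design's prior variance whatever the likelihood width
  d <- coin_design()
  for (lik in c("narrow", "wide")) {
    swo <- optimal_sensory_weight(d, "narrow", lik)
    vl <- (if (lik == "narrow") d$splash_sd_narrow else d$splash_sd_wide)^2 / 5
    expect_equal(subjective_prior_variance(vl, swo), 0.0016,
                 tolerance = 1e-12)
  }
})

test_that("outlier flags implement the two-sided 3-sigma rule", {
  x <- c(rnorm(20, 0, 0.01), 5)
  expect_equal(which(exclude_outliers(x)), 21L)
  expect_false(any(exclude_outliers(rep(0.3, 10))))
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("compute_metrics closes the loop on noise-free cohorts", {
  co <- simulate_cohort(zero_noise_spec(n = 10, seed = 1))
  m <- compute_metrics(co$trials_main, co$trials_likonly)
  gen <- generating_sw_matrix(co)
  for (code in c("PnLn", "PnLw", "PwLn", "PwLw"))
    expect_equal(m[[paste0("sw_", code)]],
                 unname(gen[m$participant_id, code]), tolerance = 1e-8)
  expect_equal(m$err_likonly, rep(0, 10), tolerance = 1e-12)
  expect_false(any(m$excluded))
  # idempotent
  expect_identical(m, compute_metrics(co$trials_main, co$trials_likonly))
})

test_that("metric orchestration flags missing tasks and applies both passes", {
  co <- simulate_cohort(cohort_spec(n_participants = 12, seed = 31))
  main <- co$trials_main[co$trials_main$participant_id != "p003", ]
  m <- compute_metrics(main, co$trials_likonly)
  expect_true(m$excluded[m$participant_id == "p003"])
  expect_equal(m$exclude_reason[m$participant_id == "p003"], "missing_task")
  expect_true(is.na(m$sw_global[m$participant_id == "p003"]))
  # plant a calibration-task outlier: first pass catches it
  lik <- co$trials_likonly
  bad <- lik$participant_id == "p005"
  lik$response[bad] <- lik$response[bad] + rnorm(sum(bad), 0, 1.5)
  m2 <- compute_metrics(co$trials_main, lik)
  expect_true(m2$excluded[m2$participant_id == "p005"])
  expect_equal(m2$exclude_reason[m2$participant_id == "p005"],
               "likelihood_only_error")
})

test_that("fast metric path agrees with the per-operation functions", {
  co <- simulate_cohort(cohort_spec(n_participants = 3, seed = 17))
  m <- compute_metrics(co$trials_main, co$trials_likonly)
  p1_main <- co$trials_main[co$trials_main$participant_id == "p001", ]
  p1_lik <- co$trials_likonly[co$trials_likonly$participant_id == "p001", ]
  expect_equal(m$sw_global[1], fit_sensory_weight(p1_main))
  expect_equal(m$sw_PwLn[1], fit_sensory_weight(
    p1_main[p1_main$prior_cond == "wide" & p1_main$lik_cond == "narrow", ]))
  expect_equal(m$subj_lik_var_Lw[1],
               subjective_likelihood_variance(p1_lik, "wide"))
  expect_equal(m$err_main[1], mean_estimation_error(p1_main, "coin"))
  expect_equal(m$trial_sw_variance[1], trial_sw_variance(p1_main))
  expect_equal(m$sensitivity_prior_change[1], sensitivity_to_prior_change(
    as.numeric(m[1, paste0("sw_block_", 1:4)])))
})
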