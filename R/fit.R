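#' Fit the Bayesian observer analysis to coin-task data
#'
#' The package's central fitting function. Takes the two trial tables (main
#' task and likelihood-only calibration task) for one or many participants
#' and computes every per-participant quantity of the analysis: sensory
#' weights (global, per condition, per block), sensitivity to prior change,
#' trial-weight variance, subjective likelihood and prior variances,
#' estimation errors, and the two-pass 3-sigma exclusion flags, together with
#' the Bayesian-optimal benchmarks implied by the design.
#'
#' @param trials_main Main-task trial table with responses, or a
#'   `coin_cohort` from [simulate_cohort()] (in which case the remaining
#'   table arguments are taken from it).
#' @param trials_likonly Likelihood-only trial table with responses.
#' @param participants Optional participant table (questionnaire scores and
#'   covariates) carried along for group-level analyses.
#' @param design A [coin_design()].
#' @param optimal_variance_mode Likelihood-variance convention for the
#'   benchmarks, see [optimal_sensory_weight()].
#' @param z_cut Outlier exclusion threshold in SDs.
#' @return An object of class `coin_fit` with components `metrics` (one row
#'   per participant), `benchmarks`, `participants`, `design`, and per-trial
#'   fitted values accessible through `predict()` and `residuals()`.
#' @seealso [run_headline_analyses()] for the group-level correlation
#'   battery on a fitted object's metrics.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = 12, seed = 7))
#' fit <- coin_fit(cohort)
#' coef(fit)[1:3, ]
#' @export
coin_fit <- function(trials_main, trials_likonly = NULL, participants = NULL,
                     design = NULL, optimal_variance_mode = c("centroid",
                                                              "literal"),
                     z_cut = 3) {
  optimal_variance_mode <- match.arg(optimal_variance_mode)
  if (inherits(trials_main, "coin_cohort")) {
    cohort <- trials_main
    trials_likonly <- trials_likonly %||% cohort$trials_likonly
    participants <- participants %||% cohort$participants
    design <- design %||% cohort$design
    trials_main <- cohort$trials_main
  }
  design <- design %||% coin_design()
  check_trial_schema(trials_main, "main-task table")
  check_trial_schema(trials_likonly, "likelihood-only table")
  metrics <- compute_metrics(trials_main, trials_likonly, design, z_cut)
  structure(list(
    metrics = metrics,
    benchmarks = optimal_benchmarks(design, optimal_variance_mode),
    participants = participants,
    design = design,
    optimal_variance_mode = optimal_variance_mode,
    trials_main = trials_main,
    trials_likonly = trials_likonly), class = "coin_fit")
}

#' @export
print.coin_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Coin-task observer fit: %d participants (%d excluded)\n",
              nrow(m), sum(m$excluded)))
  ok <- !m$excluded
  sw <- colMeans(m[ok, paste0("sw_", cond_codes()), drop = FALSE],
                 na.rm = TRUE)
  opt <- x$benchmarks$sw_opt
  cat("  mean sensory weight (optimal):\n")
  for (code in cond_codes())
    cat(sprintf("    %s: %.3f (%.3f)\n", code, sw[paste0("sw_", code)],
                opt[code]))
  invisible(x)
}

#' @export
coef.coin_fit <- function(object, ...) {
  m <- object$metrics
  out <- as.matrix(m[, c("sw_global", paste0("sw_", cond_codes()))])
  rownames(out) <- m$participant_id
  out
}

#' @export
summary.coin_fit <- function(object, ...) {
  m <- object$metrics[!object$metrics$excluded, , drop = FALSE]
  num <- c("sw_global", paste0("sw_", cond_codes()),
           "sensitivity_prior_change", "trial_sw_variance",
           "subj_lik_var", "subj_prior_var", "err_likonly", "err_main")
  tab <- data.frame(
    metric = num,
    mean = vapply(num, function(v) mean(m[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) stats::sd(m[[v]], na.rm = TRUE), numeric(1)),
    n = vapply(num, function(v) sum(!is.na(m[[v]])), numeric(1)))
  structure(list(table = tab, benchmarks = object$benchmarks,
                 n = nrow(object$metrics),
                 n_excluded = sum(object$metrics$excluded)),
            class = "summary.coin_fit")
}

#' @export
print.summary.coin_fit <- function(x, ...) {
  cat(sprintf("Coin-task observer fit: %d participants, %d excluded\n",
              x$n, x$n_excluded))
  print(x$table, row.names = FALSE, digits = 4)
  cat("Bayesian-optimal sensory weights:\n")
  print(round(x$benchmarks$sw_opt, 4))
  invisible(x)
}

# Per-participant, per-condition regression lines used by predict/residuals.
condition_lines <- function(object) {
  main <- object$trials_main
  keys <- split(seq_len(nrow(main)),
                list(main$participant_id,
                     cond_code(main$prior_cond, main$lik_cond)),
                drop = TRUE)
  lapply(keys, function(idx) {
    ok <- idx[!is.na(main$response[idx])]
    ols_fit(main$mu_L[ok], main$response[ok])
  })
}

#' @export
predict.coin_fit <- function(object, newdata = NULL, ...) {
  trials <- newdata %||% object$trials_main
  lines <- condition_lines(object)
  key <- paste(trials$participant_id,
               cond_code(trials$prior_cond, trials$lik_cond), sep = ".")
  a <- vapply(lines, `[[`, numeric(1), "intercept")[key]
  b <- vapply(lines, `[[`, numeric(1), "slope")[key]
  unname(a + b * trials$mu_L)
}

#' @export
residuals.coin_fit <- function(object, ...) {
  object$trials_main$response - predict(object)
}

#' @describeIn coin_fit Parametric re-simulation: draws new responses for the
#'   fitted trial structure from each participant's per-condition regression
#'   line plus Gaussian residual noise at the fitted residual SD.
#' @param object,nsim,seed,... Standard [stats::simulate()] arguments.
#' @export
simulate.coin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pred <- predict(object)
  res <- residuals(object)
  main <- object$trials_main
  key <- paste(main$participant_id,
               cond_code(main$prior_cond, main$lik_cond), sep = ".")
  sds <- tapply(res, key, stats::sd, na.rm = TRUE)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, pred +
      stats::rnorm(length(pred), 0, unname(sds[key]))))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
plot.coin_fit <- function(x, ...) {
  m <- x$metrics[!x$metrics$excluded, , drop = FALSE]
  sw <- m[, paste0("sw_", cond_codes()), drop = FALSE]
  graphics::boxplot(sw, names = cond_codes(), ylab = "sensory weight",
                    ylim = c(0, 1.05),
                    main = "Sensory weights by condition", ...)
  graphics::segments(seq_len(4) - 0.4, x$benchmarks$sw_opt,
                     seq_len(4) + 0.4, x$benchmarks$sw_opt,
                     lty = 2, col = "blue", lwd = 2)
  invisible(x)
}
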