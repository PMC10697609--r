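#' Specification of a synthetic observer cohort
#'
#' A cohort of noisy Bayesian observers whose subjective prior and likelihood
#' variances covary (weakly, on the log scale) with a latent psychotic-like
#' experience trait. For observer \eqn{i} with trait \eqn{t_i \sim N(0,1)}:
#' \deqn{\log\sigma^2_{P,subj} = \log\sigma^2_{P,true} + \beta_P t_i + \epsilon_P,}
#' \deqn{\log\sigma^2_{L,subj} = \log\sigma^2_{L,true} + \beta_L t_i + \epsilon_L,}
#' with \eqn{\epsilon \sim N(0, \sigma_{between}^2)} drawn once per observer
#' per variance family (so condition ordering is preserved within observer).
#' Likelihood variances are at the splash-centroid level. The questionnaire
#' score is a deterministic affine-lognormal map of the trait,
#' `clip(round(20 + exp(a + b t)), 20, 80)`, with `(a, b)` solved from the
#' requested instrument-scale mean and SD; this reproduces the right-skewed
#' score distributions typical of the instrument.
#'
#' @param n_participants Cohort size (>= 3).
#' @param beta_prior,beta_lik Trait slopes on the log subjective prior and
#'   likelihood variances. Defaults induce weak positive trait-metric
#'   correlations (about 0.12 for the headline weight-vs-trait association),
#'   the band of the effects the pipeline is designed to detect.
#' @param sigma_between Between-observer SD of the log-variance jitter.
#' @param rho_between Correlation between an observer's prior and likelihood
#'   log-variance jitters: a shared "perceived task instability" component.
#'   Positive values let both subjective variances sit above or below truth
#'   together while their ratio (which sets the sensory weight) varies less.
#' @param cape_p_mean,cape_p_sd Target instrument-scale moments of the
#'   positive-dimension questionnaire score (20 items, 1-4 Likert, range
#'   20-80).
#' @param perceptual_noise_sd Optional SD of internal centroid-encoding noise,
#'   either a single value or a named pair `c(narrow = , wide = )`. The
#'   default `NULL` uses each observer's subjective centroid SD, making the
#'   observer self-consistent: its actual encoding noise equals the
#'   uncertainty it attributes to the likelihood, so the calibration-task
#'   estimator recovers it.
#' @param motor_noise_sd SD of pointing noise added to every response.
#' @param lapse_rate Probability of an off-task uniform response (main task).
#' @param seed Session seed; per-participant streams are derived from it by
#'   stable hashing, so any cohort is reproducible participant-by-participant.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 200,
                        beta_prior = 0.068,
                        beta_lik = 0.02,
                        sigma_between = 0.3,
                        rho_between = 0.6,
                        cape_p_mean = 27,
                        cape_p_sd = 6,
                        perceptual_noise_sd = NULL,
                        motor_noise_sd = 0.02,
                        lapse_rate = 0.02,
                        seed = 1L) {
  if (!is_count(n_participants) || n_participants < 3)
    stop_config("n_participants", "must be an integer >= 3")
  if (!is.numeric(sigma_between) || sigma_between < 0)
    stop_config("sigma_between", "must be >= 0")
  if (!is.numeric(rho_between) || abs(rho_between) > 1)
    stop_config("rho_between", "must be in [-1, 1]")
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate > 1)
    stop_config("lapse_rate", "must be in [0, 1]")
  if (!is.numeric(motor_noise_sd) || motor_noise_sd < 0)
    stop_config("motor_noise_sd", "must be >= 0")
  if (cape_p_mean <= 20)
    stop_config("cape_p_mean", "must exceed the scale minimum of 20")
  structure(list(
    n_participants = as.integer(n_participants),
    beta_prior = beta_prior, beta_lik = beta_lik,
    sigma_between = sigma_between, rho_between = rho_between,
    cape_p_mean = cape_p_mean, cape_p_sd = cape_p_sd,
    perceptual_noise_sd = perceptual_noise_sd,
    motor_noise_sd = motor_noise_sd, lapse_rate = lapse_rate,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d observers (seed %d)\n",
              x$n_participants, x$seed))
  cat(sprintf("  trait slopes: beta_prior %g, beta_lik %g; between-SD %g\n",
              x$beta_prior, x$beta_lik, x$sigma_between))
  cat(sprintf("  CAPE-P target M %g, SD %g; motor SD %g; lapse %g\n",
              x$cape_p_mean, x$cape_p_sd, x$motor_noise_sd, x$lapse_rate))
  invisible(x)
}

# (a, b) of the trait -> 20 + exp(a + b t) map giving the requested
# instrument-scale mean and SD (lognormal moment matching, before clipping).
lognormal_map_coefs <- function(mean, sd, floor) {
  mu <- mean - floor
  b2 <- log(1 + (sd / mu)^2)
  c(a = log(mu) - b2 / 2, b = sqrt(b2))
}

scale_score <- function(trait, mean, sd, floor, top) {
  ab <- lognormal_map_coefs(mean, sd, floor)
  pmin(top, pmax(floor, round(floor + exp(ab["a"] + ab["b"] * trait))))
}

#' Sample one synthetic observer
#'
#' @param spec A [cohort_spec()].
#' @param design A [coin_design()].
#' @param id Participant identifier.
#' @param seed Optional seed (the cohort simulator derives one per
#'   participant).
#' @return A list of class `observer_params`: trait, questionnaire scores,
#'   subjective SD maps (`subj_prior_sd`, `subj_lik_sd`, both named
#'   narrow/wide, likelihood at centroid level), per-condition
#'   `perceptual_noise_sd`, `motor_noise_sd`, `lapse_rate`, and the implied
#'   generating sensory weights `sw_gen` per condition plus their
#'   stimulus-variance-weighted session average `sw_gen_global`.
#' @export
sample_observer <- function(spec, design, id = "p001", seed = NULL) {
  with_seed(seed, {
    trait <- stats::rnorm(1)
    rho <- spec$rho_between %||% 0
    eps_p <- stats::rnorm(1, 0, spec$sigma_between)
    eps_l <- rho * eps_p +
      sqrt(max(0, 1 - rho^2)) * stats::rnorm(1, 0, spec$sigma_between)
    true_prior_var <- c(narrow = design$prior_sd_narrow^2,
                        wide = design$prior_sd_wide^2)
    true_lik_var <- c(narrow = design$splash_sd_narrow^2,
                      wide = design$splash_sd_wide^2) / design$n_splashes
    subj_prior_var <- true_prior_var * exp(spec$beta_prior * trait + eps_p)
    subj_lik_var <- true_lik_var * exp(spec$beta_lik * trait + eps_l)
    perc <- spec$perceptual_noise_sd
    perc_sd <- if (is.null(perc)) sqrt(subj_lik_var) else {
      p <- rep_len(as.numeric(perc), 2L)
      if (!is.null(names(perc)) && all(c("narrow", "wide") %in% names(perc)))
        p <- as.numeric(perc[c("narrow", "wide")])
      stats::setNames(p, c("narrow", "wide"))
    }
    # correlated secondary subscales and independent covariates
    trait_n <- 0.5 * trait + sqrt(0.75) * stats::rnorm(1)
    trait_d <- 0.5 * trait + sqrt(0.75) * stats::rnorm(1)
    obs <- list(
      participant_id = id,
      trait = trait,
      cape_p = as.integer(scale_score(trait, spec$cape_p_mean, spec$cape_p_sd,
                                      20, 80)),
      cape_n = as.integer(scale_score(trait_n, 26, 7, 14, 56)),
      cape_d = as.integer(scale_score(trait_d, 15, 4, 8, 32)),
      spatial_span = as.integer(pmin(9, pmax(2, round(stats::rnorm(1, 6, 1.3))))),
      age = as.integer(pmin(73, pmax(18, round(stats::rnorm(1, 32, 11))))),
      gender = sample(c("female", "male", "other"), 1,
                      prob = c(0.455, 0.527, 0.018)),
      subj_prior_sd = sqrt(subj_prior_var),
      subj_lik_sd = sqrt(subj_lik_var),
      perceptual_noise_sd = perc_sd,
      motor_noise_sd = spec$motor_noise_sd,
      lapse_rate = spec$lapse_rate)
    obs$sw_gen <- generating_weights(obs)
    obs$sw_gen_global <- generating_global_weight(obs, design)
    structure(obs, class = "observer_params")
  })
}

# Subjective-variance weights w = sigma_P^2 / (sigma_P^2 + sigma_L^2) per
# condition cell; the observer's response slope on the perceived centroid.
generating_weights <- function(params) {
  out <- numeric(4)
  names(out) <- cond_codes()
  for (code in cond_codes()) {
    cc <- cond_from_code(code)
    vp <- params$subj_prior_sd[[cc$prior_cond]]^2
    vl <- params$subj_lik_sd[[cc$lik_cond]]^2
    out[code] <- vp / (vp + vl)
  }
  out
}

# The pooled-session regression slope implied by the generating weights: a
# weighted mean of condition weights with weights equal to each condition's
# stimulus variance of mu_L (prior variance + centroid variance), the OLS
# limit for equal trial counts per cell.
generating_global_weight <- function(params, design) {
  w <- generating_weights(params)
  v <- vapply(cond_codes(), function(code) {
    cc <- cond_from_code(code)
    prior_sd(design, cc$prior_cond)^2 +
      splash_sd(design, cc$lik_cond)^2 / design$n_splashes
  }, numeric(1))
  sum(w * v) / sum(v)
}

#' Posterior-mean estimate of the coin position
#'
#' The optimal estimate combines the prior mean and the (perceived) splash
#' centroid with precision weights:
#' \deqn{\hat X = \frac{\sigma_L^2}{\sigma_L^2+\sigma_P^2}\,\mu_P +
#'       \frac{\sigma_P^2}{\sigma_L^2+\sigma_P^2}\,\mu_L.}
#' When called with an observer's parameters the subjective variances for the
#' given condition pair are used.
#'
#' @param mu_L Perceived likelihood mean(s) (splash centroid).
#' @param params An `observer_params` object, or `NULL` to pass variances
#'   directly.
#' @param prior_cond,lik_cond Condition labels selecting the observer's
#'   subjective variances.
#' @param prior_var,lik_var Variances used when `params` is `NULL`.
#' @param prior_mean Prior mean (screen centre).
#' @return Estimated position(s).
#' @examples
#' ideal_estimate(0.2, prior_var = 1, lik_var = 1) # symmetric: 0.1
#' @export
ideal_estimate <- function(mu_L, params = NULL, prior_cond = "narrow",
                           lik_cond = "narrow", prior_var = NULL,
                           lik_var = NULL, prior_mean = 0) {
  if (!is.null(params)) {
    prior_var <- params$subj_prior_sd[[prior_cond]]^2
    lik_var <- params$subj_lik_sd[[lik_cond]]^2
  }
  if (prior_var == 0 && lik_var == 0)
    stop("undefined weights: prior and likelihood variance are both zero",
         call. = FALSE)
  if (is.infinite(prior_var)) return(mu_L)
  w <- prior_var / (prior_var + lik_var)
  (1 - w) * prior_mean + w * mu_L
}

#' Simulate responses for a trial table
#'
#' Response model: the observer encodes the splash centroid with Gaussian
#' perceptual noise, integrates it with the prior using its subjective
#' variances (main task) or reports it directly (likelihood-only task), and
#' points with Gaussian motor noise. On the main task a lapse replaces the
#' response with a uniform draw over the screen with probability
#' `lapse_rate`.
#'
#' @param trials Trial data frame from the generators (both tasks accepted).
#' @param params An `observer_params` object.
#' @param design A [coin_design()].
#' @param seed Optional seed.
#' @return `trials` with the `response` column filled.
#' @export
simulate_response <- function(trials, params, design = coin_design(),
                              seed = NULL) {
  stopifnot(all(c("task", "mu_L", "lik_cond") %in% names(trials)))
  with_seed(seed, {
    n <- nrow(trials)
    perc_sd <- unname(params$perceptual_noise_sd[trials$lik_cond])
    perceived <- trials$mu_L + stats::rnorm(n, 0, perc_sd)
    resp <- numeric(n)
    main <- trials$task == "main"
    if (any(main)) {
      w <- unname(generating_weights(params)[
        cond_code(trials$prior_cond[main], trials$lik_cond[main])])
      resp[main] <- (1 - w) * design$prior_mean + w * perceived[main]
    }
    resp[!main] <- perceived[!main]
    resp <- resp + stats::rnorm(n, 0, params$motor_noise_sd)
    if (params$lapse_rate > 0 && any(main)) {
      lapse <- main & stats::runif(n) < params$lapse_rate
      resp[lapse] <- stats::runif(sum(lapse), -design$screen_halfwidth,
                                  design$screen_halfwidth)
    }
    trials$response <- resp
    trials
  })
}

#' Simulate a full cohort: participants plus responded trial tables
#'
#' Each participant completes the 100-trial likelihood-only task followed by
#' the 4 x 75-trial main task. Thrower order is counterbalanced: odd-indexed
#' participants start with the narrow-prior thrower, even-indexed with the
#' wide. Per-participant RNG streams are derived from the session seed by
#' stable hashing, so the same seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param design A [coin_design()].
#' @param seed Session seed; defaults to `spec$seed`.
#' @return An object of class `coin_cohort`: list with `participants` (one row
#'   per observer: id, questionnaire scores, covariates), `trials_main`,
#'   `trials_likonly`, and `observers` (the generating `observer_params`,
#'   kept for parameter-recovery checks).
#' @export
simulate_cohort <- function(spec, design = coin_design(), seed = NULL) {
  seed <- seed %||% spec$seed
  n <- spec$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  observers <- vector("list", n)
  main_acc <- vector("list", n)
  lik_acc <- vector("list", n)
  rev_order <- rev(design$block_prior_order)
  for (i in seq_len(n)) {
    s <- participant_seed(seed, ids[i])
    with_seed(s, {
      observers[[i]] <- sample_observer(spec, design, ids[i])
      ord <- if (i %% 2L == 1L) design$block_prior_order else rev_order
      lik <- likonly_cols(design, ids[i])
      mt <- main_task_cols(design, ids[i], ord)
      lik_acc[[i]] <- fill_responses_cols(lik, observers[[i]], design)
      main_acc[[i]] <- fill_responses_cols(mt, observers[[i]], design)
    })
  }
  structure(list(
    participants = participants_frame(observers),
    trials_main = bind_col_lists(main_acc),
    trials_likonly = bind_col_lists(lik_acc),
    observers = stats::setNames(observers, ids),
    spec = spec, design = design, seed = seed),
    class = "coin_cohort")
}

# simulate_response over the internal list-of-columns representation
fill_responses_cols <- function(cols, params, design) {
  n <- length(cols$mu_L)
  perc_sd <- unname(params$perceptual_noise_sd[cols$lik_cond])
  perceived <- cols$mu_L + stats::rnorm(n, 0, perc_sd)
  if (cols$task[1L] == "main") {
    w <- unname(generating_weights(params)[
      cond_code(cols$prior_cond, cols$lik_cond)])
    resp <- (1 - w) * design$prior_mean + w * perceived
  } else resp <- perceived
  resp <- resp + stats::rnorm(n, 0, params$motor_noise_sd)
  if (params$lapse_rate > 0 && cols$task[1L] == "main") {
    lapse <- stats::runif(n) < params$lapse_rate
    resp[lapse] <- stats::runif(sum(lapse), -design$screen_halfwidth,
                                design$screen_halfwidth)
  }
  cols$response <- resp
  cols
}

bind_col_lists <- function(acc) {
  cols <- names(acc[[1L]])
  out <- lapply(cols, function(nm)
    unlist(lapply(acc, `[[`, nm), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

participants_frame <- function(observers) {
  data.frame(
    participant_id = vapply(observers, `[[`, "", "participant_id"),
    cape_p = vapply(observers, `[[`, 0L, "cape_p"),
    cape_n = vapply(observers, `[[`, 0L, "cape_n"),
    cape_d = vapply(observers, `[[`, 0L, "cape_d"),
    cape_total = vapply(observers, function(o) o$cape_p + o$cape_n + o$cape_d,
                        0L),
    spatial_span = vapply(observers, `[[`, 0L, "spatial_span"),
    age = vapply(observers, `[[`, 0L, "age"),
    gender = vapply(observers, `[[`, "", "gender"),
    stringsAsFactors = FALSE)
}

#' @export
print.coin_cohort <- function(x, ...) {
  cat(sprintf("Simulated coin-task cohort: %d participants (seed %d)\n",
              nrow(x$participants), x$seed))
  cat(sprintf("  main task: %d trials; likelihood-only: %d trials\n",
              nrow(x$trials_main), nrow(x$trials_likonly)))
  cat(sprintf("  CAPE-P: M = %.1f, SD = %.1f, range %d-%d\n",
              mean(x$participants$cape_p), stats::sd(x$participants$cape_p),
              min(x$participants$cape_p), max(x$participants$cape_p)))
  invisible(x)
}

#' @describeIn cohort_spec `simulate()` method: draws `nsim` cohorts from a
#'   spec (a list of `coin_cohort` objects, or a single cohort when
#'   `nsim = 1`).
#' @param object,nsim,... Standard [stats::simulate()] arguments.
#' @export
simulate.cohort_spec <- function(object, nsim = 1, seed = NULL, ...) {
  base <- seed %||% object$seed
  if (nsim == 1) return(simulate_cohort(object, seed = base, ...))
  lapply(seq_len(nsim), function(k)
    simulate_cohort(object, seed = participant_seed(base, paste0("sim", k)),
                    ...))
}
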