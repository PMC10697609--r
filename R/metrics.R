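#' Mean estimation error
#'
#' Mean absolute distance between the response and a reference position: the
#' true coin location for the main task, or the splash centroid for the
#' likelihood-only task (where the two coincide). Used for performance
#' summaries and outlier exclusion.
#'
#' @param trials Trial data frame with responses.
#' @param reference `"coin"` or `"centroid"`.
#' @param prior_cond,lik_cond Optional condition filters.
#' @return Mean absolute error in screen units.
#' @export
mean_estimation_error <- function(trials, reference = c("coin", "centroid"),
                                  prior_cond = NULL, lik_cond = NULL) {
  reference <- match.arg(reference)
  keep <- !is.na(trials$response)
  if (!is.null(prior_cond)) keep <- keep & trials$prior_cond %in% prior_cond
  if (!is.null(lik_cond)) keep <- keep & trials$lik_cond %in% lik_cond
  if (!any(keep)) stop("no trials match the requested filter", call. = FALSE)
  ref <- if (reference == "coin") trials$coin_pos else trials$mu_L
  mean(abs(trials$response[keep] - ref[keep]))
}

# Closed-form OLS slope of y on x with intercept; identical to
# coef(lm(y ~ x))[2] but cheap enough to run per participant/condition/block.
ols_slope <- function(x, y) {
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / sxx
}

ols_fit <- function(x, y) {
  b <- ols_slope(x, y)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

#' Sensory weight: regression of responses on the splash centroid
#'
#' The sensory weight is the OLS slope (intercept included) of the response
#' \eqn{X_{est}} on the likelihood mean \eqn{\mu_L}. A slope near 1 means pure
#' reliance on the splashes, near 0 pure reliance on the prior; an ideal
#' observer's slope is \eqn{\sigma_P^2 / (\sigma_P^2 + \sigma_L^2)}. Filter
#' the input to obtain per-condition or per-block weights.
#'
#' @param trials Trial data frame with responses (rows already filtered to
#'   the scope of interest).
#' @return The slope (unitless).
#' @export
fit_sensory_weight <- function(trials) {
  keep <- !is.na(trials$response) & !is.na(trials$mu_L)
  if (sum(keep) < 3) stop("need at least 3 responded trials", call. = FALSE)
  x <- trials$mu_L[keep]
  if (stats::var(x) == 0)
    stop("degenerate input: mu_L has zero variance", call. = FALSE)
  ols_slope(x, trials$response[keep])
}

#' Bayesian-optimal sensory weight for a condition
#'
#' \eqn{\sigma_P^2/(\sigma_P^2+\sigma_L^2)} with the design's true prior
#' variance and the likelihood variance of the splash centroid,
#' \eqn{\sigma_{splash}^2 / n_{splashes}} (`mode = "centroid"`, the ideal
#' observer's uncertainty about the coin given 5 splashes). The alternative
#' `mode = "literal"` treats the per-splash SD as if it were the likelihood
#' variance itself (narrow 0.096/5-style reading), retained only for
#' comparison.
#'
#' @param design A [coin_design()].
#' @param prior_cond,lik_cond Condition labels (vectorised).
#' @param mode Likelihood-variance convention, see above.
#' @return Optimal slope(s) in (0, 1).
#' @examples
#' optimal_sensory_weight(coin_design(), "narrow", "narrow") # 0.4647
#' @export
optimal_sensory_weight <- function(design, prior_cond, lik_cond,
                                   mode = c("centroid", "literal")) {
  mode <- match.arg(mode)
  vp <- prior_sd(design, prior_cond)^2
  vl <- likelihood_variance(design, lik_cond, mode)
  vp / (vp + vl)
}

likelihood_variance <- function(design, lik_cond, mode = "centroid") {
  s <- splash_sd(design, lik_cond)
  if (mode == "centroid") return(s^2 / design$n_splashes)
  # "literal" convention: the per-splash SD digits with a trailing 5 read
  # directly as a variance (0.096 -> 0.09625-style), kept for comparison
  as.numeric(paste0(format(s), "25"))
}

#' Optimal benchmarks for all four conditions
#'
#' @inheritParams optimal_sensory_weight
#' @return List with `sw_opt` (named by condition code) and
#'   `prior_var_imposed` (the design's true prior variances).
#' @export
optimal_benchmarks <- function(design, mode = c("centroid", "literal")) {
  mode <- match.arg(mode)
  sw <- vapply(cond_codes(), function(code) {
    cc <- cond_from_code(code)
    optimal_sensory_weight(design, cc$prior_cond, cc$lik_cond, mode)
  }, numeric(1))
  list(sw_opt = sw,
       prior_var_imposed = c(narrow = design$prior_sd_narrow^2,
                             wide = design$prior_sd_wide^2))
}

#' Sensitivity to changes in prior uncertainty
#'
#' Mean absolute difference in sensory weight between consecutive blocks,
#' indexing how strongly an observer adapts to the alternating thrower:
#' \eqn{(|sw_{B1}-sw_{B2}| + |sw_{B2}-sw_{B3}| + |sw_{B3}-sw_{B4}|)/3}.
#'
#' @param sw_by_block Numeric vector of per-block sensory weights, in block
#'   order.
#' @return Non-negative scalar.
#' @export
sensitivity_to_prior_change <- function(sw_by_block) {
  if (length(sw_by_block) < 2 || anyNA(sw_by_block))
    stop("need a complete vector of per-block sensory weights", call. = FALSE)
  mean(abs(diff(sw_by_block)))
}

#' Instantaneous (trial-by-trial) sensory weight
#'
#' Rearranging the posterior-mean rule for a single trial gives a raw
#' instantaneous weight \eqn{(X_{est}-\mu_P)/(\mu_L-\mu_P)}, which is mapped
#' through the logistic \eqn{1/(1+e^{-x})} to bound it in (0, 1). The raw
#' value is clamped to \eqn{\pm 50} before the logistic so near-degenerate
#' trials (\eqn{\mu_L \approx \mu_P}) cannot overflow; trials with
#' \eqn{\mu_L = \mu_P} exactly are undefined and returned as `NA`.
#'
#' @param response Response position(s).
#' @param mu_L Splash centroid(s).
#' @param mu_P Prior mean (the screen centre).
#' @param clamp Symmetric bound applied to the raw weight.
#' @return List with `raw` and `logistic` vectors.
#' @export
trial_sensory_weight <- function(response, mu_L, mu_P = 0, clamp = 50) {
  raw <- (response - mu_P) / (mu_L - mu_P)
  raw[mu_L == mu_P] <- NA_real_
  clamped <- pmin(pmax(raw, -clamp), clamp)
  list(raw = raw, logistic = stats::plogis(clamped))
}

#' Session variance of the trial-by-trial sensory weight
#'
#' Sample variance (n - 1 denominator) of the logistic-transformed
#' instantaneous weights over all responded main-task trials; undefined
#' trials are excluded. Bounded above by 0.25 since the logistic weight lives
#' in (0, 1).
#'
#' @param trials Main-task trial data frame with responses.
#' @param mu_P Prior mean.
#' @return Variance (unitless).
#' @export
trial_sw_variance <- function(trials, mu_P = 0) {
  w <- trial_sensory_weight(trials$response, trials$mu_L, mu_P)$logistic
  w <- w[!is.na(w) & !is.na(trials$response)]
  if (length(w) < 2)
    stop("need at least 2 defined trial weights", call. = FALSE)
  stats::var(w)
}

#' Subjective likelihood variance (sensory noise proxy)
#'
#' From the likelihood-only task: \eqn{\sigma_{SL}^2 = \sum(\mu_{est} -
#' \mu_L)^2 / n_{trials}} with the population (n) denominator, where
#' \eqn{\mu_{est}} is the response. Computed over all trials or filtered by
#' likelihood condition.
#'
#' @param trials Likelihood-only trial data frame with responses.
#' @param lik_cond Optional condition filter.
#' @return Variance in squared screen units.
#' @export
subjective_likelihood_variance <- function(trials, lik_cond = NULL) {
  keep <- !is.na(trials$response)
  if (!is.null(lik_cond)) keep <- keep & trials$lik_cond %in% lik_cond
  if (!any(keep)) stop("no trials match the requested filter", call. = FALSE)
  mean((trials$response[keep] - trials$mu_L[keep])^2)
}

#' Subjective prior variance by inversion of the weight equation
#'
#' Inverting \eqn{sw = \sigma_P^2/(\sigma_P^2+\sigma_{SL}^2)} gives
#' \eqn{\sigma_P^2 = \sigma_{SL}^2 \, sw/(1-sw)}: an observer's implied prior
#' uncertainty from its measured sensory noise and sensory weight. Weights at
#' or above 1 leave the variance undefined (`NA`); non-positive weights are
#' clamped to 0 with a warning.
#'
#' @param sigma_sl2 Subjective likelihood variance(s).
#' @param sw Sensory weight(s).
#' @return Variance(s) in squared screen units.
#' @export
subjective_prior_variance <- function(sigma_sl2, sw) {
  stopifnot(length(sigma_sl2) == length(sw) || length(sigma_sl2) == 1L ||
              length(sw) == 1L)
  out <- sigma_sl2 * sw / (1 - sw)
  undef <- !is.na(sw) & sw >= 1
  out[undef] <- NA_real_
  neg <- !is.na(sw) & sw <= 0
  if (any(neg)) {
    warning(sprintf("%d non-positive sensory weight(s) clamped to variance 0",
                    sum(neg)), call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Flag outlying participants by z-score
#'
#' Participants whose value lies more than `z_cut` sample SDs from the sample
#' mean are flagged. With zero SD nothing is flagged.
#'
#' @param values Numeric vector (one value per participant).
#' @param z_cut Threshold, default 3.
#' @return Logical vector of flags.
#' @export
exclude_outliers <- function(values, z_cut = 3) {
  if (length(values) < 3)
    stop("need at least 3 participants", call. = FALSE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(FALSE, length(values)))
  z <- (values - mean(values, na.rm = TRUE)) / s
  !is.na(z) & abs(z) > z_cut
}

metric_frame_names <- function() {
  codes <- cond_codes()
  c("participant_id",
    "err_likonly", "err_likonly_Ln", "err_likonly_Lw",
    "err_main", paste0("err_main_", codes),
    "sw_global", paste0("sw_", codes), paste0("sw_block_", 1:4),
    "sensitivity_prior_change", "trial_sw_variance",
    "subj_lik_var", "subj_lik_var_Ln", "subj_lik_var_Lw",
    "subj_prior_var", paste0("subj_prior_var_", codes),
    "excluded", "exclude_reason")
}

# All per-participant estimators, on plain vectors for speed; the exported
# per-operation functions are the documented single-participant interface
# and agree with this fast path (checked in the tests).
participant_metrics_row <- function(id, main, likonly, design) {
  mu_P <- design$prior_mean
  codes <- cond_codes()
  row <- list(participant_id = id)
  lerr <- abs(likonly$response - likonly$mu_L)
  lnar <- likonly$lik_cond == "narrow"
  row$err_likonly <- mean(lerr)
  row$err_likonly_Ln <- mean(lerr[lnar])
  row$err_likonly_Lw <- mean(lerr[!lnar])
  merr <- abs(main$response - main$coin_pos)
  code <- cond_code(main$prior_cond, main$lik_cond)
  row$err_main <- mean(merr)
  for (cc in codes) row[[paste0("err_main_", cc)]] <- mean(merr[code == cc])
  row$sw_global <- ols_slope(main$mu_L, main$response)
  for (cc in codes)
    row[[paste0("sw_", cc)]] <- ols_slope(main$mu_L[code == cc],
                                          main$response[code == cc])
  blocks <- sort(unique(main$block_index))
  sw_blocks <- vapply(blocks, function(b) {
    in_b <- main$block_index == b
    ols_slope(main$mu_L[in_b], main$response[in_b])
  }, numeric(1))
  for (b in seq_along(blocks))
    row[[paste0("sw_block_", b)]] <- sw_blocks[b]
  row$sensitivity_prior_change <- sensitivity_to_prior_change(sw_blocks)
  w <- trial_sensory_weight(main$response, main$mu_L, mu_P)$logistic
  row$trial_sw_variance <- stats::var(w[!is.na(w)])
  sl2 <- (likonly$response - likonly$mu_L)^2
  row$subj_lik_var <- mean(sl2)
  row$subj_lik_var_Ln <- mean(sl2[lnar])
  row$subj_lik_var_Lw <- mean(sl2[!lnar])
  row$subj_prior_var <- suppressWarnings(
    subjective_prior_variance(row$subj_lik_var, row$sw_global))
  for (cc in codes) {
    # condition-level inversion pairs the condition's weight with the
    # calibration-task sensory noise of the matching likelihood width
    sl <- if (cond_from_code(cc)$lik_cond == "narrow")
      row$subj_lik_var_Ln else row$subj_lik_var_Lw
    row[[paste0("subj_prior_var_", cc)]] <- suppressWarnings(
      subjective_prior_variance(sl, row[[paste0("sw_", cc)]]))
  }
  row$excluded <- FALSE
  row$exclude_reason <- ""
  row
}

#' Compute all per-participant metrics for a cohort
#'
#' Runs every estimator (estimation errors, global / per-condition /
#' per-block sensory weights, sensitivity to prior change, trial-weight
#' variance, subjective likelihood and prior variances) on each participant,
#' then applies the two-pass 3-sigma exclusion rule: first on mean estimation
#' error in the likelihood-only task, then, among survivors, on mean
#' estimation error in the main task. Participants missing either task are
#' flagged with reason `"missing_task"` and get no metrics.
#'
#' @param trials_main,trials_likonly Trial tables with responses (any number
#'   of participants).
#' @param design A [coin_design()].
#' @param z_cut Exclusion threshold in SDs.
#' @return Data frame, one row per participant, with an `excluded` flag and
#'   `exclude_reason`.
#' @export
compute_metrics <- function(trials_main, trials_likonly,
                            design = coin_design(), z_cut = 3) {
  ids <- union(unique(trials_main$participant_id),
               unique(trials_likonly$participant_id))
  use <- c("participant_id", "block_index", "prior_cond", "lik_cond",
           "mu_L", "coin_pos", "response")
  main_idx <- split(seq_len(nrow(trials_main)),
                    trials_main$participant_id)
  lik_idx <- split(seq_len(nrow(trials_likonly)),
                   trials_likonly$participant_id)
  main_cols <- lapply(trials_main[use], identity)
  lik_cols <- lapply(trials_likonly[use], identity)
  pick <- function(cols, idx) lapply(cols, `[`, idx)
  rows <- lapply(ids, function(id) {
    mi <- main_idx[[id]]
    li <- lik_idx[[id]]
    m <- if (!is.null(mi)) pick(main_cols, mi)
    l <- if (!is.null(li)) pick(lik_cols, li)
    if (is.null(m) || is.null(l) || all(is.na(m$response)) ||
        all(is.na(l$response))) {
      row <- stats::setNames(as.list(rep(NA_real_,
                                         length(metric_frame_names()))),
                             metric_frame_names())
      row$participant_id <- id
      row$excluded <- TRUE
      row$exclude_reason <- "missing_task"
      return(row)
    }
    keep_m <- !is.na(m$response)
    if (!all(keep_m)) m <- pick(m, which(keep_m))
    keep_l <- !is.na(l$response)
    if (!all(keep_l)) l <- pick(l, which(keep_l))
    participant_metrics_row(id, m, l, design)
  })
  nm <- metric_frame_names()
  out <- data.frame(participant_id = vapply(rows, `[[`, "",
                                            "participant_id"),
                    stringsAsFactors = FALSE)
  for (col in setdiff(nm, c("participant_id", "excluded", "exclude_reason")))
    out[[col]] <- vapply(rows, function(r) as.numeric(r[[col]]), numeric(1))
  out$excluded <- vapply(rows, function(r) isTRUE(r$excluded), logical(1))
  out$exclude_reason <- vapply(rows, function(r)
    if (is.character(r$exclude_reason)) r$exclude_reason else "", "")
  out <- out[, nm]
  ok <- !out$excluded
  if (sum(ok) >= 3) {
    f1 <- exclude_outliers(out$err_likonly[ok], z_cut)
    out$excluded[ok][f1] <- TRUE
    out$exclude_reason[ok][f1] <- "likelihood_only_error"
    ok <- !out$excluded
    if (sum(ok) >= 3) {
      f2 <- exclude_outliers(out$err_main[ok], z_cut)
      out$excluded[ok][f2] <- TRUE
      out$exclude_reason[ok][f2] <- "main_task_error"
    }
  }
  out
}

#' Read / write metrics tables as CSV
#' @param metrics Metrics data frame from [compute_metrics()].
#' @param path File path.
#' @return `read_metrics()` returns the data frame; `write_metrics()` returns
#'   `path` invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(metric_frame_names(), names(df))
  if (length(missing))
    stop(sprintf("metrics table: missing column '%s'", missing[1L]),
         call. = FALSE)
  df$excluded <- as.logical(df$excluded)
  df$exclude_reason[is.na(df$exclude_reason)] <- ""
  df
}
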