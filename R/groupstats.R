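group_result <- function(name, estimator, statistic, p_value,
                         ci_low = NA_real_, ci_high = NA_real_,
                         p_adjusted = NA_real_, n_used = NA_integer_) {
  data.frame(name = name, estimator = estimator, statistic = statistic,
             p_value = p_value, ci_low = ci_low, ci_high = ci_high,
             p_adjusted = p_adjusted, n_used = as.integer(n_used),
             stringsAsFactors = FALSE)
}

#' Correlation with percentile-bootstrap confidence interval
#'
#' Pearson (for linearly distributed variables, e.g. log-transformed
#' questionnaire scores) or Spearman (average ranks for ties) correlation
#' with a two-sided p value from [stats::cor.test()] and a percentile
#' bootstrap CI over participants (1000 replicates by default). Incomplete
#' pairs are dropped listwise.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_boot Bootstrap replicates; `0` skips the CI.
#' @param seed Optional seed for the bootstrap.
#' @param name Label stored in the result.
#' @param conf_level CI level.
#' @return One-row data frame (a group result): name, estimator, statistic,
#'   p_value, ci_low, ci_high, p_adjusted (NA here), n_used.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"), n_boot = 1000,
                      seed = NULL, name = "correlation", conf_level = 0.95) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = method,
    exact = if (method == "spearman") FALSE else NULL))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(k) {
        idx <- sample.int(n, n, replace = TRUE)
        suppressWarnings(stats::cor(x[idx], y[idx], method = method))
      }, numeric(1))
      stats::quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                      na.rm = TRUE, names = FALSE)
    })
  }
  group_result(name, method, unname(ct$estimate), ct$p.value,
               ci[1], ci[2], n_used = n)
}

#' Bonferroni adjustment with a fixed comparison family
#'
#' `min(1, m * p)` with `m = 4` by default: the analysis plan makes at most
#' four comparisons per metric family, so the family size is fixed rather
#' than taken from the vector length.
#'
#' @param p_values Vector of p values in \[0, 1\].
#' @param m Family size.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p_values, m = 4) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)), m >= 1)
  pmin(1, m * p_values)
}

#' One-sample Wilcoxon signed-rank test against the optimal weight
#'
#' Tests whether participants' sensory weights differ from the
#' Bayesian-optimal value: a two-sided signed-rank test on `sw - sw_opt`
#' with zero differences dropped, exact for 25 or fewer non-zero differences
#' and a continuity-corrected normal approximation above that. If every
#' difference is zero, `p = 1` by convention.
#'
#' @param sw Participant weights.
#' @param sw_opt Optimal weight (scalar or per-participant).
#' @param name Label for the result.
#' @return One-row group-result data frame.
#' @export
wilcoxon_vs_optimal <- function(sw, sw_opt, name = "sw_vs_optimal") {
  d <- stats::na.omit(sw - sw_opt)
  if (length(d) < 6) stop("need at least 6 values", call. = FALSE)
  nz <- d[d != 0]
  if (!length(nz))
    return(group_result(name, "wilcoxon_signed_rank_vs_value", 0, 1,
                        n_used = length(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    nz, mu = 0, exact = length(nz) <= 25, correct = TRUE))
  group_result(name, "wilcoxon_signed_rank_vs_value", unname(wt$statistic),
               wt$p.value, n_used = length(d))
}

#' Paired t test
#'
#' Two-sided paired t on within-participant differences (df = n - 1), with
#' the mean-difference CI, e.g. estimation error in the wide vs narrow
#' likelihood condition of the calibration task.
#'
#' @param a,b Paired vectors.
#' @param name Label for the result.
#' @return One-row group-result data frame; `statistic` is the t value and
#'   the CI is for the mean difference `a - b`.
#' @export
paired_t <- function(a, b, name = "paired_t") {
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  if (stats::var(d) == 0 ||
      stats::sd(d) < 10 * sqrt(.Machine$double.eps) * abs(mean(d))) {
    # identical vectors: no evidence of a difference, by convention
    if (all(a == b))
      return(group_result(name, "paired_t", 0, 1, 0, 0, n_used = length(a)))
    stop("zero variance in paired differences", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  group_result(name, "paired_t", unname(tt$statistic), tt$p.value,
               tt$conf.int[1], tt$conf.int[2], n_used = length(a))
}

#' Two-way fixed-effects ANOVA on the participant-by-condition table
#'
#' Ordinary two-factor ANOVA with interaction on the long table of one value
#' per participant per condition cell (fixed effects, no subject term). The
#' balanced 2x2 design makes type I and type III sums of squares coincide.
#'
#' @param data Long data frame.
#' @param value,prior,likelihood Column names of the response and the two
#'   factors.
#' @param participant Column name of the participant id, used to check that
#'   every participant contributes one value per cell.
#' @return Data frame of group results, one row per effect (`prior`,
#'   `likelihood`, `prior:likelihood`), with cell means in
#'   `attr(, "cell_means")`.
#' @export
two_way_anova <- function(data, value = "value", prior = "prior_cond",
                          likelihood = "lik_cond",
                          participant = "participant_id") {
  df <- data.frame(value = data[[value]],
                   prior = factor(data[[prior]]),
                   lik = factor(data[[likelihood]]),
                   id = data[[participant]])
  counts <- table(df$id, df$prior, df$lik)
  bad <- rownames(counts)[apply(counts != 1, 1, any)]
  if (length(bad))
    stop(sprintf("participant '%s' does not contribute one value per cell",
                 bad[1L]), call. = FALSE)
  if (anyNA(df$value)) {
    bad <- unique(df$id[is.na(df$value)])
    stop(sprintf("participant '%s' has a missing cell value", bad[1L]),
         call. = FALSE)
  }
  av <- stats::anova(stats::lm(value ~ prior * lik, data = df))
  effects <- c("prior", "lik", "prior:lik")
  labels <- c("prior", "likelihood", "prior:likelihood")
  out <- do.call(rbind, lapply(seq_along(effects), function(i)
    group_result(labels[i], "two_way_anova",
                 av[effects[i], "F value"], av[effects[i], "Pr(>F)"],
                 n_used = length(unique(df$id)))))
  attr(out, "cell_means") <- tapply(df$value, list(df$prior, df$lik), mean)
  out
}

#' Sample size for detecting a correlation
#'
#' Smallest integer n at which a two-sided test of zero correlation reaches
#' the target power, using the Fisher z approximation with small-sample bias
#' correction: the test statistic is compared against the critical
#' correlation from the t distribution, with `atanh(r) + r/(2(n-1))` as the
#' approximate mean and `1/sqrt(n-3)` as the SD of the z-transformed sample
#' correlation. Solved by root-finding in continuous n, then rounded up.
#'
#' @param r True correlation (0 < r < 1).
#' @param power Target power.
#' @param alpha Two-sided significance level.
#' @return Required sample size (integer).
#' @examples
#' power_n_correlation(0.10) # 782
#' @export
power_n_correlation <- function(r, power = 0.8, alpha = 0.05) {
  if (!is.numeric(r) || r <= 0 || r >= 1)
    stop("r must lie strictly between 0 and 1", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie strictly between 0 and 1", call. = FALSE)
  pw <- function(n) {
    tcrit <- stats::qt(alpha / 2, df = n - 2, lower.tail = FALSE)
    rcrit <- sqrt(tcrit^2 / (tcrit^2 + n - 2))
    zr <- atanh(r) + r / (2 * (n - 1))
    zc <- atanh(rcrit)
    stats::pnorm((zr - zc) * sqrt(n - 3)) +
      stats::pnorm((-zr - zc) * sqrt(n - 3))
  }
  lo <- 4 + 1e-9
  if (pw(lo) >= power) return(5L)
  hi <- 10
  while (pw(hi) < power && hi < 1e8) hi <- hi * 10
  root <- stats::uniroot(function(n) pw(n) - power, c(lo, hi),
                         tol = 1e-8)$root
  as.integer(ceiling(root - 1e-8))
}

headline_correlations <- function() {
  codes <- cond_codes()
  rbind(
    data.frame(metric = "sw_global", covar = "log_cape_p",
               method = "pearson", stringsAsFactors = FALSE),
    data.frame(metric = paste0("sw_", codes), covar = "log_cape_p",
               method = "pearson"),
    data.frame(metric = c("sensitivity_prior_change", "trial_sw_variance",
                          "subj_lik_var", "subj_prior_var"),
               covar = "cape_p", method = "spearman"),
    data.frame(metric = paste0("subj_prior_var_", codes), covar = "cape_p",
               method = "spearman"),
    data.frame(metric = c("sw_global", "subj_prior_var"),
               covar = "spatial_span", method = "spearman"),
    data.frame(metric = c("sw_global", "subj_lik_var", "subj_prior_var"),
               covar = "cape_n", method = "spearman"),
    data.frame(metric = c("sw_global", "subj_lik_var", "subj_prior_var"),
               covar = "cape_d", method = "spearman"))
}

#' Run the headline group-level correlation battery
#'
#' The ordered battery of trait-metric associations: global and
#' per-condition sensory weights against log-transformed CAPE-P (Pearson);
#' sensitivity to prior change, trial-weight variance, subjective likelihood
#' variance, and subjective prior variance (overall and per condition)
#' against raw CAPE-P (Spearman); plus spatial-span and CAPE subscale
#' correlations when those columns are present. Each row carries a
#' percentile bootstrap CI and a Bonferroni-adjusted p with the fixed
#' four-comparison family. Excluded participants are dropped first; missing
#' metric values are dropped listwise per comparison (with a message).
#'
#' @param metrics Metrics table from [compute_metrics()] / a `coin_fit`.
#' @param participants Participant table sharing `participant_id`.
#' @param n_boot Bootstrap replicates per correlation (`0` to skip CIs).
#' @param seed Seed for the bootstrap streams.
#' @param bonferroni_m Comparison-family size.
#' @param min_n Minimum participants after exclusion.
#' @return Data frame of class `coin_group_results`, one row per comparison.
#' @export
run_headline_analyses <- function(metrics, participants = NULL, n_boot = 1000,
                                  seed = NULL, bonferroni_m = 4,
                                  min_n = 10) {
  if (inherits(metrics, "coin_fit")) {
    participants <- participants %||% metrics$participants
    metrics <- metrics$metrics
  }
  if (is.null(participants))
    stop("a participant table is required", call. = FALSE)
  orphans <- setdiff(metrics$participant_id, participants$participant_id)
  if (length(orphans))
    stop(sprintf("participants missing from the participant table: %s",
                 paste(utils::head(orphans, 5), collapse = ", ")),
         call. = FALSE)
  df <- merge(metrics[!metrics$excluded, , drop = FALSE], participants,
              by = "participant_id")
  if (nrow(df) < min_n)
    stop(sprintf("only %d participants remain after exclusions (need >= %d)",
                 nrow(df), min_n), call. = FALSE)
  df$log_cape_p <- log(df$cape_p)
  plan <- headline_correlations()
  plan <- plan[plan$covar %in% names(df), , drop = FALSE]
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    met <- plan$metric[i]; cov <- plan$covar[i]
    x <- df[[met]]; y <- df[[cov]]
    n_drop <- sum(!stats::complete.cases(x, y))
    if (n_drop > 0)
      message(sprintf("%s ~ %s: dropped %d incomplete pair(s)", met, cov,
                      n_drop))
    res <- correlate(x, y, plan$method[i], n_boot = n_boot,
                     seed = if (is.null(seed)) NULL else
                       participant_seed(seed, paste0(met, cov)),
                     name = paste0(met, "~", cov))
    res
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value, bonferroni_m)
  class(out) <- c("coin_group_results", class(out))
  out
}

#' @export
print.coin_group_results <- function(x, ...) {
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 4)
  df$p_value <- signif(df$p_value, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  df$ci_low <- round(df$ci_low, 4)
  df$ci_high <- round(df$ci_high, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize group results to JSON
#'
#' @param results A `coin_group_results` (or compatible) data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_group_results <- function(results, path) {
  jsonlite::write_json(as.data.frame(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
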