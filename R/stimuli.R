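#' Sample hidden coin positions
#'
#' Coin positions are drawn from the prior
#' \eqn{N(\mu_P, \sigma_P(\mathrm{cond})^2)}. With `clip_positions = TRUE` in
#' the design, draws are clipped to the screen; by default tails are kept so
#' sample moments match the generating SD.
#'
#' @param design A [coin_design()].
#' @param prior_cond `"narrow"` or `"wide"` (the calibration task has no
#'   prior and is handled by [generate_likelihood_only_task()]).
#' @param n Number of draws.
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @return Numeric vector of positions.
#' @export
sample_coin_position <- function(design, prior_cond, n = 1, seed = NULL) {
  sd <- prior_sd(design, prior_cond)
  with_seed(seed, {
    x <- stats::rnorm(n, design$prior_mean, sd)
    clip_to_screen(design, x)
  })
}

#' Sample splash positions around a coin
#'
#' Draws `n_splashes` i.i.d. positions from
#' \eqn{N(\mathrm{coin}, \sigma_{splash}(\mathrm{cond})^2)} for each coin
#' position and returns them together with their centroid \eqn{\mu_L}, the
#' likelihood mean an ideal observer would extract.
#'
#' @inheritParams sample_coin_position
#' @param coin_pos Vector of coin positions (one trial per element).
#' @param lik_cond `"narrow"` or `"wide"`, length 1 or `length(coin_pos)`.
#' @return List with `splashes` (matrix, trials x n_splashes) and `mu_L`.
#' @export
sample_splashes <- function(design, coin_pos, lik_cond, seed = NULL) {
  n <- length(coin_pos)
  sd <- rep_len(splash_sd(design, lik_cond), n)
  k <- design$n_splashes
  with_seed(seed, {
    spl <- matrix(stats::rnorm(n * k, mean = rep(coin_pos, k),
                               sd = rep(sd, k)), nrow = n, ncol = k)
    spl <- clip_to_screen(design, spl)
    list(splashes = spl, mu_L = rowMeans(spl))
  })
}

clip_to_screen <- function(design, x) {
  if (!design$clip_positions) return(x)
  pmin(pmax(x, -design$screen_halfwidth), design$screen_halfwidth)
}

# Balanced-within-block likelihood labels: with an odd block length the spare
# trial goes to the narrow condition in odd blocks and the wide condition in
# even blocks, so session totals stay exactly balanced.
block_lik_labels <- function(trials_per_block, block_index) {
  n_half <- trials_per_block %/% 2
  extra <- trials_per_block - 2L * n_half
  labs <- c(rep("narrow", n_half), rep("wide", n_half))
  if (extra) labs <- c(labs, if (block_index %% 2L == 1L) "narrow" else "wide")
  sample(labs)
}

# List-of-columns trial builders (fast path used by cohort simulation); the
# exported generators wrap them into data frames.
main_task_cols <- function(design, participant_id, block_prior_order) {
  nb <- design$n_blocks
  tpb <- design$trials_per_block
  n <- nb * tpb
  block_index <- rep(seq_len(nb), each = tpb)
  prior_cond <- rep(block_prior_order, each = tpb)
  lik_cond <- unlist(lapply(seq_len(nb), function(b)
    block_lik_labels(tpb, b)), use.names = FALSE)
  coin_pos <- clip_to_screen(design, stats::rnorm(
    n, design$prior_mean, prior_sd(design, prior_cond)))
  spl <- sample_splashes(design, coin_pos, lik_cond)
  c(list(participant_id = rep(participant_id, n),
         task = rep("main", n),
         block_index = block_index,
         trial_index = rep(seq_len(tpb), nb),
         prior_cond = prior_cond,
         lik_cond = lik_cond),
    splash_cols(spl$splashes),
    list(mu_L = spl$mu_L, coin_pos = coin_pos,
         response = rep(NA_real_, n)))
}

likonly_cols <- function(design, participant_id) {
  n <- design$n_likelihood_only_trials
  if (n %% 2L != 0L)
    stop_config("n_likelihood_only_trials",
                "must be even (balanced likelihood conditions)")
  lik_cond <- sample(rep(c("narrow", "wide"), n %/% 2L))
  # Splash-cloud centres are spread uniformly over the central half of the
  # screen; the calibration task imports no prior structure.
  centre <- stats::runif(n, -0.5 * design$screen_halfwidth,
                         0.5 * design$screen_halfwidth)
  spl <- sample_splashes(design, centre, lik_cond)
  c(list(participant_id = rep(participant_id, n),
         task = rep("likelihood_only", n),
         block_index = rep(0L, n),
         trial_index = seq_len(n),
         prior_cond = rep("none", n),
         lik_cond = lik_cond),
    splash_cols(spl$splashes),
    # feedback shows the coin at the true splash centre, so by construction
    # coin_pos == mu_L in this task
    list(mu_L = spl$mu_L, coin_pos = spl$mu_L,
         response = rep(NA_real_, n)))
}

splash_cols <- function(m) {
  out <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(out) <- paste0("splash_", seq_len(ncol(m)))
  out
}

#' Generate one participant's main-task trial table
#'
#' `n_blocks` blocks of `trials_per_block` trials. The prior condition follows
#' `block_prior_order` (throwers alternate between blocks); within each block
#' the likelihood condition is counterbalanced to within one trial and
#' presented in shuffled order, with session totals exactly balanced.
#'
#' @inheritParams sample_coin_position
#' @param participant_id Identifier stored on every row.
#' @param block_prior_order Optional override of the design's block order
#'   (used to counterbalance thrower order across participants).
#' @return A data frame of trial records without responses, columns
#'   `participant_id, task, block_index, trial_index, prior_cond, lik_cond,
#'   splash_1..splash_k, mu_L, coin_pos, response`.
#' @export
generate_main_task <- function(design, participant_id = "p001", seed = NULL,
                               block_prior_order = NULL) {
  ord <- block_prior_order %||% design$block_prior_order
  if (length(ord) != design$n_blocks || !all(ord %in% c("narrow", "wide")))
    stop_config("block_prior_order", "invalid block labels")
  with_seed(seed,
    as.data.frame(main_task_cols(design, participant_id, ord),
                  stringsAsFactors = FALSE))
}

#' Generate one participant's likelihood-only (calibration) task
#'
#' 100 trials by default, half narrow and half wide likelihood in shuffled
#' order and no prior manipulation. The target (`coin_pos`) is always the
#' centre of the displayed splashes, so estimation error in this task isolates
#' sensory noise about the splash centroid.
#'
#' @inheritParams generate_main_task
#' @return A data frame of trial records (see [generate_main_task()]) with
#'   `prior_cond == "none"` and `coin_pos == mu_L`.
#' @export
generate_likelihood_only_task <- function(design, participant_id = "p001",
                                          seed = NULL) {
  with_seed(seed,
    as.data.frame(likonly_cols(design, participant_id),
                  stringsAsFactors = FALSE))
}

trial_columns <- function(n_splashes = 5) {
  c("participant_id", "task", "block_index", "trial_index", "prior_cond",
    "lik_cond", paste0("splash_", seq_len(n_splashes)), "mu_L", "coin_pos",
    "response")
}

#' Read / write trial tables as CSV
#'
#' One row per trial, columns exactly as produced by the generators; positions
#' are printed with 12 significant digits and a missing response is an empty
#' field.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial data frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trial_schema(trials)
  out <- trials
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), "", sprintf("%.12g", x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_trial_schema(df)
  df
}

check_trial_schema <- function(df, what = "trial table") {
  need <- trial_columns(sum(grepl("^splash_", names(df))))
  if (!sum(grepl("^splash_", names(df))))
    stop(sprintf("%s: no splash_* columns found", what), call. = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column '%s'", what, missing[1L]), call. = FALSE)
  invisible(df)
}
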