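#' Coin-task design parameters
#'
#' Encodes the statistical structure of the coin task: on every trial a hidden
#' coin position is drawn from a Gaussian prior centred on the screen centre
#' whose SD alternates between blocks ("throwers" of different accuracy), and
#' five visible splash positions are drawn from a Gaussian likelihood centred
#' on the coin whose SD switches trial-to-trial. Defaults use a screen spanning
#' \eqn{[-0.8, +0.8]} (width 1.6), under which the condition SDs are 6\% and
#' 15\% of the screen width for the splashes (0.096, 0.24) and 2.5\% and 8.5\%
#' for the prior (0.04, 0.136).
#'
#' @param screen_halfwidth Half the screen width in screen units.
#' @param prior_sd_narrow,prior_sd_wide SD of the coin-position prior in the
#'   narrow and wide prior (accurate/inaccurate thrower) blocks.
#' @param splash_sd_narrow,splash_sd_wide SD of individual splash positions
#'   around the coin in the narrow and wide likelihood conditions.
#' @param n_splashes Number of splash dots per trial.
#' @param prior_mean Centre of the prior (the screen centre).
#' @param n_blocks Number of main-task blocks.
#' @param trials_per_block Trials per main-task block.
#' @param n_likelihood_only_trials Trials in the likelihood-only calibration
#'   task (must be even: conditions are balanced).
#' @param net_halfwidth Half-width of the response net, used only for the
#'   gamified trial score, never in analysis.
#' @param coin_radius Radius of the coin for scoring.
#' @param block_prior_order Character vector of length `n_blocks` with values
#'   `"narrow"`/`"wide"`; must alternate (throwers alternate between blocks).
#'   Default starts with the narrow-prior thrower.
#' @param clip_positions If `TRUE`, sampled positions are clipped to the
#'   screen; default keeps Gaussian tails so sample moments match the
#'   generating SDs exactly.
#'
#' @return An object of class `coin_design` (a validated list).
#' @examples
#' d <- coin_design()
#' d$splash_sd_narrow # 0.096 = 6% of the 1.6-unit screen width
#' @export
coin_design <- function(screen_halfwidth = 0.8,
                        prior_sd_narrow = 0.04,
                        prior_sd_wide = 0.136,
                        splash_sd_narrow = 0.096,
                        splash_sd_wide = 0.24,
                        n_splashes = 5,
                        prior_mean = 0,
                        n_blocks = 4,
                        trials_per_block = 75,
                        n_likelihood_only_trials = 100,
                        net_halfwidth = 0.04,
                        coin_radius = 0.01,
                        block_prior_order = NULL,
                        clip_positions = FALSE) {
  design <- list(
    screen_halfwidth = screen_halfwidth,
    prior_sd_narrow = prior_sd_narrow,
    prior_sd_wide = prior_sd_wide,
    splash_sd_narrow = splash_sd_narrow,
    splash_sd_wide = splash_sd_wide,
    n_splashes = n_splashes,
    prior_mean = prior_mean,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    n_likelihood_only_trials = n_likelihood_only_trials,
    net_halfwidth = net_halfwidth,
    coin_radius = coin_radius,
    block_prior_order = block_prior_order %||%
      rep_len(c("narrow", "wide"), n_blocks),
    clip_positions = isTRUE(clip_positions)
  )
  validate_design(design)
}

#' Build a design from a (possibly partial) list of overrides
#'
#' List interface mirroring a JSON design config: unknown keys are rejected.
#'
#' @param overrides Named list of `coin_design()` fields.
#' @return A `coin_design` object.
#' @export
make_design <- function(overrides = list()) {
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == "")))
    stop_config("(overrides)", "all overrides must be named")
  known <- names(formals(coin_design))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop_config(bad[1L], "unknown field")
  do.call(coin_design, overrides)
}

validate_design <- function(design) {
  sds <- c("prior_sd_narrow", "prior_sd_wide", "splash_sd_narrow",
           "splash_sd_wide")
  for (f in sds) {
    v <- design[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_config(f, "must be a single non-negative number")
  }
  if (design$splash_sd_narrow > design$splash_sd_wide)
    stop_config("splash_sd_narrow", "narrow SD must not exceed wide SD")
  if (design$prior_sd_narrow > design$prior_sd_wide)
    stop_config("prior_sd_narrow", "narrow SD must not exceed wide SD")
  for (f in c("screen_halfwidth", "net_halfwidth", "coin_radius"))
    if (!is.numeric(design[[f]]) || design[[f]] < 0)
      stop_config(f, "must be non-negative")
  for (f in c("n_splashes", "n_blocks", "trials_per_block",
              "n_likelihood_only_trials"))
    if (!is_count(design[[f]]) || design[[f]] < 1)
      stop_config(f, "must be a positive integer")
  ord <- design$block_prior_order
  if (length(ord) != design$n_blocks || !all(ord %in% c("narrow", "wide")))
    stop_config("block_prior_order",
                sprintf("must be %d labels in {narrow, wide}", design$n_blocks))
  if (design$n_blocks > 1L && any(ord[-1L] == ord[-length(ord)]))
    stop_config("block_prior_order", "throwers must alternate between blocks")
  structure(design, class = "coin_design")
}

#' @export
print.coin_design <- function(x, ...) {
  cat("Coin task design\n")
  cat(sprintf("  screen: [%g, %g] (width %g)\n", -x$screen_halfwidth,
              x$screen_halfwidth, 2 * x$screen_halfwidth))
  cat(sprintf("  prior SD (narrow/wide):  %g / %g, mean %g\n",
              x$prior_sd_narrow, x$prior_sd_wide, x$prior_mean))
  cat(sprintf("  splash SD (narrow/wide): %g / %g, %d splashes\n",
              x$splash_sd_narrow, x$splash_sd_wide, x$n_splashes))
  cat(sprintf("  main task: %d blocks x %d trials (%s)\n", x$n_blocks,
              x$trials_per_block, paste(x$block_prior_order, collapse = ", ")))
  cat(sprintf("  likelihood-only task: %d trials\n",
              x$n_likelihood_only_trials))
  invisible(x)
}

prior_sd <- function(design, prior_cond) {
  if (any(!prior_cond %in% c("narrow", "wide")))
    stop("prior_cond must be 'narrow' or 'wide' (main task only)", call. = FALSE)
  ifelse(prior_cond == "narrow", design$prior_sd_narrow, design$prior_sd_wide)
}

splash_sd <- function(design, lik_cond) {
  if (any(!lik_cond %in% c("narrow", "wide")))
    stop("lik_cond must be 'narrow' or 'wide'", call. = FALSE)
  ifelse(lik_cond == "narrow", design$splash_sd_narrow, design$splash_sd_wide)
}

#' Score a single trial
#'
#' A point is earned when any part of the coin lies within the net, i.e. when
#' the gap between coin and net centres is at most `net_halfwidth +
#' coin_radius` (closed boundary). The score is gamification only and never
#' enters the analysis.
#'
#' @param design A `coin_design`.
#' @param coin_pos,response Coin and net positions (vectorised).
#' @return Integer 0/1 vector.
#' @export
score_trial <- function(design, coin_pos, response) {
  stopifnot(is.finite(coin_pos), is.finite(response))
  as.integer(abs(coin_pos - response) <= design$net_halfwidth + design$coin_radius)
}

#' Read / write a design config as JSON
#'
#' Unknown keys in the file are rejected, mirroring `make_design()`.
#'
#' @param path File path.
#' @param design A `coin_design`.
#' @return `read_design()` returns a `coin_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_design(as.list(cfg))
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "coin_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
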