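#' Assemble and validate a pipeline run configuration
#'
#' Bundles the design overrides, cohort spec, and analysis settings with a
#' mandatory seed (no silent nondeterminism) for the end-to-end runner.
#'
#' @param design Named list of [coin_design()] overrides.
#' @param cohort Named list of [cohort_spec()] overrides.
#' @param analysis Named list: `n_boot`, `bonferroni_m`,
#'   `optimal_variance_mode` (`"centroid"` or `"literal"`).
#' @param seed Integer session seed (required).
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = list(), cohort = list(),
                       analysis = list(), seed = 1L) {
  if (!is_count(seed)) stop_config("seed", "must be a single integer")
  ana <- utils::modifyList(
    list(n_boot = 1000, bonferroni_m = 4,
         optimal_variance_mode = "centroid"), analysis)
  bad <- setdiff(names(ana), c("n_boot", "bonferroni_m",
                               "optimal_variance_mode"))
  if (length(bad)) stop_config(bad[1L], "unknown analysis field")
  if (!ana$optimal_variance_mode %in% c("centroid", "literal"))
    stop_config("optimal_variance_mode", "must be 'centroid' or 'literal'")
  # validate eagerly so a bad config fails before any file is written
  des <- make_design(design)
  spc <- do.call(cohort_spec, utils::modifyList(cohort,
                                                list(seed = as.integer(seed))))
  structure(list(design = design, cohort = cohort, analysis = ana,
                 seed = as.integer(seed),
                 design_obj = des, cohort_obj = spc),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with optional `design`, `cohort`, `analysis`
#'   sections and a `seed`.
#' @param seed Optional override of the file's seed (CLI flags take
#'   precedence over the config file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), c("design", "cohort", "analysis", "seed"))
  if (length(bad)) stop_config(bad[1L], "unknown config section")
  run_config(design = as.list(cfg$design), cohort = as.list(cfg$cohort),
             analysis = as.list(cfg$analysis),
             seed = seed %||% cfg$seed %||% 1L)
}

coin_log <- function(out_dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(out_dir))
    cat(msg, "\n", sep = "", file = file.path(out_dir, "run.log"),
        append = TRUE)
  invisible(msg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(design = config$design, cohort = config$cohort,
                            analysis = config$analysis, seed = config$seed),
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort to disk
#'
#' Writes `participants.csv`, `trials_main.csv`, `trials_likonly.csv` and a
#' `manifest.json` (seed, config hash, row counts) under `out_dir`. The same
#' configuration always produces byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$cohort_obj, config$design_obj,
                            seed = config$seed)
  utils::write.csv(cohort$participants,
                   file.path(out_dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  write_trials(cohort$trials_main, file.path(out_dir, "trials_main.csv"))
  write_trials(cohort$trials_likonly,
               file.path(out_dir, "trials_likonly.csv"))
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_participants = nrow(cohort$participants),
                   n_trials_main = nrow(cohort$trials_main),
                   n_trials_likonly = nrow(cohort$trials_likonly))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  coin_log(out_dir, "simulated %d participants (seed %d) -> %s",
           manifest$n_participants, config$seed, out_dir)
  invisible(out_dir)
}

#' Compute the metrics table from cohort files
#'
#' Reads the trial tables written by [pipeline_simulate()], validates their
#' schema, runs [compute_metrics()], and logs every exclusion with its
#' participant id.
#'
#' @param in_dir Directory with the cohort CSVs.
#' @param out_file Output CSV path.
#' @param design A [coin_design()] matching the simulated data.
#' @return The metrics data frame, invisibly.
#' @export
pipeline_metrics <- function(in_dir, out_file,
                             design = coin_design()) {
  for (f in c("trials_main.csv", "trials_likonly.csv"))
    if (!file.exists(file.path(in_dir, f)))
      stop(sprintf("missing input file: %s", file.path(in_dir, f)),
           call. = FALSE)
  main <- read_trials(file.path(in_dir, "trials_main.csv"))
  likonly <- read_trials(file.path(in_dir, "trials_likonly.csv"))
  metrics <- compute_metrics(main, likonly, design)
  out_dir <- dirname(out_file)
  for (i in which(metrics$excluded))
    coin_log(out_dir, "excluded %s (%s)", metrics$participant_id[i],
             metrics$exclude_reason[i])
  coin_log(out_dir, "metrics: %d participants, %d outliers excluded",
           nrow(metrics), sum(metrics$excluded))
  write_metrics(metrics, out_file)
  invisible(metrics)
}

#' Group-level analysis from metrics and participant files
#'
#' Runs [run_headline_analyses()] and writes `results.json` plus a
#' human-readable `report.md` containing the four-condition sensory-weight
#' table against the optimal benchmarks and the full correlation battery.
#'
#' @param metrics_file Metrics CSV from [pipeline_metrics()].
#' @param participants_file Participant CSV from [pipeline_simulate()].
#' @param out_dir Output directory.
#' @param config A [run_config()] (analysis settings and seed).
#' @return The group-results data frame, invisibly.
#' @export
pipeline_group <- function(metrics_file, participants_file, out_dir,
                           config = run_config()) {
  metrics <- read_metrics(metrics_file)
  participants <- utils::read.csv(participants_file,
                                  stringsAsFactors = FALSE)
  orphans <- setdiff(metrics$participant_id, participants$participant_id)
  if (length(orphans))
    stop(sprintf("id mismatch; metrics-only participants: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- run_headline_analyses(
    metrics, participants, n_boot = config$analysis$n_boot,
    seed = config$seed, bonferroni_m = config$analysis$bonferroni_m)
  write_group_results(results, file.path(out_dir, "results.json"))
  write_report(metrics, results, config, file.path(out_dir, "report.md"))
  coin_log(out_dir, "group analysis: %d comparisons on %d participants",
           nrow(results), results$n_used[1])
  invisible(results)
}

write_report <- function(metrics, results, config, path) {
  design <- config$design_obj
  bench <- optimal_benchmarks(design, config$analysis$optimal_variance_mode)
  ok <- !metrics$excluded
  lines <- c(
    "# Coin-task cohort report", "",
    sprintf("Participants analysed: %d (of %d; %d excluded)", sum(ok),
            nrow(metrics), sum(!ok)),
    sprintf("Seed: %d", config$seed), "",
    "## Sensory weights by condition", "",
    "| condition | mean sw | sd | optimal sw |",
    "|-----------|---------|----|------------|")
  for (code in cond_codes()) {
    v <- metrics[[paste0("sw_", code)]][ok]
    lines <- c(lines, sprintf("| %s | %.4f | %.4f | %.4f |", code,
                              mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
                              bench$sw_opt[code]))
  }
  lines <- c(lines, "", "## Correlation battery", "",
             "| comparison | estimator | r | p | 95% CI | p (Bonferroni) | n |",
             "|------------|-----------|---|---|--------|----------------|---|")
  for (i in seq_len(nrow(results)))
    lines <- c(lines, sprintf(
      "| %s | %s | %.4f | %.3g | [%.4f, %.4f] | %.3g | %d |",
      results$name[i], results$estimator[i], results$statistic[i],
      results$p_value[i], results$ci_low[i], results$ci_high[i],
      results$p_adjusted[i], results$n_used[i]))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline: simulate, metrics, group analysis
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for all artifacts.
#' @return The group-results data frame, invisibly.
#' @export
pipeline_run <- function(config, out_dir) {
  pipeline_simulate(config, out_dir)
  pipeline_metrics(out_dir, file.path(out_dir, "metrics.csv"),
                   config$design_obj)
  pipeline_group(file.path(out_dir, "metrics.csv"),
                 file.path(out_dir, "participants.csv"), out_dir, config)
}
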