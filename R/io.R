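#' Write a simulated cohort to a directory
#'
#' Tidy CSV interchange: \code{trials.csv} (one row per trial),
#' \code{blocks.csv} (one row per block with the end-of-block SPE),
#' \code{profiles.csv} (one row per participant), and \code{config.json}
#' echoing the resolved configuration, seed and ground-truth parameters.
#'
#' @param cohort A \code{spe_cohort} from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "spe_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$blocks, file.path(dir, "blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort dataset from a directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return A \code{spe_cohort} list (trials, blocks, profiles, config).
#' @export
read_dataset <- function(dir) {
  files <- file.path(dir, c("trials.csv", "blocks.csv", "profiles.csv"))
  if (!all(file.exists(files)))
    stop("dataset directory must contain trials.csv, blocks.csv, profiles.csv")
  cfg_path <- file.path(dir, "config.json")
  structure(list(
    trials = utils::read.csv(files[1], stringsAsFactors = FALSE),
    blocks = utils::read.csv(files[2], stringsAsFactors = FALSE),
    profiles = utils::read.csv(files[3], stringsAsFactors = FALSE),
    config = if (file.exists(cfg_path)) jsonlite::read_json(cfg_path) else NULL),
    class = "spe_cohort")
}

#' Validate cohort tables against the schema
#'
#' Checks the structural invariants the pipeline relies on: known task and
#' phase labels, confidence and SPE inside [0, 1], feedback events only on
#' intervention blocks, and an mh score for every participant.
#'
#' @param trials,blocks,profiles Cohort tables.
#' @return Data frame of issues (\code{table}, \code{row}, \code{message});
#'   zero rows when the dataset is valid.
#' @export
validate_dataset <- function(trials, blocks, profiles) {
  issues <- list()
  flag <- function(table, rows, msg) {
    if (length(rows))
      issues[[length(issues) + 1]] <<- data.frame(
        table = table, row = rows, message = msg, stringsAsFactors = FALSE)
  }
  flag("trials", which(!trials$task %in% c("perception", "memory")),
       "unknown task label")
  flag("trials", which(!trials$phase %in% c("baseline", "intervention", "test")),
       "unknown block phase")
  flag("trials", which(trials$confidence < 0 | trials$confidence > 1),
       "confidence outside [0, 1]")
  flag("trials",
       which(!trials$feedback %in% c("none", "correct_shown", "incorrect_shown")),
       "unknown feedback event")
  flag("trials", which(trials$phase != "intervention" & trials$feedback != "none"),
       "feedback event on a no-feedback block")
  flag("blocks", which(blocks$spe < 0 | blocks$spe > 1),
       "SPE outside [0, 1]")
  flag("blocks", which(!blocks$phase %in% c("baseline", "intervention", "test")),
       "unknown block phase")
  missing_mh <- setdiff(unique(trials$participant_id), profiles$participant_id)
  flag("profiles", match(missing_mh, missing_mh),
       if (length(missing_mh))
         paste("no mh score for participant(s)",
               paste(missing_mh, collapse = ", ")) else character(0))
  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(0), row = integer(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Simulate a cohort and write it to disk
#'
#' Pipeline entry point behind the \code{simulate} subcommand of the
#' bundled command-line script. The config is a named list (or path to a
#' JSON file) with any of: \code{n_participants}, \code{experiment},
#' \code{variant}, \code{params} (arguments to [model_params()]),
#' \code{seed}, \code{exact_quota}, \code{conf_bias_per_mh}.
#'
#' @param config Named list or JSON path.
#' @param out Output directory.
#' @return Invisibly, the cohort.
#' @export
cli_simulate <- function(config = list(), out) {
  cfg <- resolve_config(config, defaults = list(
    n_participants = 16, experiment = "exp1", variant = "D0",
    seed = 1, exact_quota = FALSE, conf_bias_per_mh = -0.005,
    params = list()))
  params <- do.call(model_params, cfg$params)
  cohort <- simulate_cohort(cfg$n_participants, cfg$experiment,
                            params = params,
                            spec = distortion_spec(cfg$variant),
                            seed = cfg$seed, exact_quota = cfg$exact_quota,
                            conf_bias_per_mh = cfg$conf_bias_per_mh)
  write_dataset(cohort, out)
  n_fb <- sum(cohort$trials$feedback != "none")
  message(sprintf(
    "simulated %d participants (%s, %s): %d trials, %d blocks, %d feedback events [seed %d] -> %s",
    cfg$n_participants, cfg$experiment, cfg$variant, nrow(cohort$trials),
    nrow(cohort$blocks), n_fb, cfg$seed, out))
  invisible(cohort)
}

#' Fit one distortion variant to a dataset on disk
#'
#' Reads and validates a dataset directory, fits the requested variant,
#' and writes \code{draws.csv}, \code{summary.csv} and \code{summary.json}
#' (DIC, HDIs, convergence diagnostics, config echo) to \code{out}.
#'
#' @param dataset_dir Directory written by [cli_simulate()].
#' @param variant Distortion variant label.
#' @param profile MCMC profile, \code{"fast"} or \code{"full"}.
#' @param seed Sampler seed.
#' @param out Output directory.
#' @return Invisibly, the \code{spe_fit}.
#' @export
cli_fit <- function(dataset_dir, variant = "D1", profile = "fast",
                    seed = 1, out) {
  ds <- read_dataset(dataset_dir)
  stop_on_issues(validate_dataset(ds$trials, ds$blocks, ds$profiles))
  fit <- fit_model(ds$trials, ds$blocks, ds$profiles,
                   spec = distortion_spec(variant),
                   config = mcmc_config(profile = profile, seed = seed))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$draws), file.path(out, "draws.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$summary, file.path(out, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(variant = fit$variant, dic = fit$dic, p_d = fit$p_d,
         dbar = fit$dbar, converged = fit$converged,
         rhat = as.list(fit$rhat), n_obs = fit$n_obs,
         config = unclass(fit$config)),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!fit$converged)
    message("warning: convergence diagnostics flagged; see summary.json")
  message(sprintf("fit %s: DIC %.2f (p_D %.2f) -> %s", variant, fit$dic,
                  fit$p_d, out))
  invisible(fit)
}

#' Compare distortion variants on a dataset on disk
#'
#' @inheritParams cli_fit
#' @param variants Variant labels to compare.
#' @return Invisibly, the \code{spe_comparison}.
#' @export
cli_compare <- function(dataset_dir, variants = paste0("D", 0:6),
                        profile = "fast", seed = 1, out) {
  ds <- read_dataset(dataset_dir)
  stop_on_issues(validate_dataset(ds$trials, ds$blocks, ds$profiles))
  cmp <- compare_models(ds$trials, ds$blocks, ds$profiles,
                        variants = variants,
                        config = mcmc_config(profile = profile, seed = seed))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(cmp$table, file.path(out, "dic_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(best = cmp$best, decisive_delta = cmp$decisive_delta,
         table = cmp$table),
    file.path(out, "comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message(sprintf("compared %d variants; best: %s -> %s",
                  nrow(cmp$table), cmp$best, out))
  invisible(cmp)
}

#' Run a parameter-recovery sweep and write the report
#'
#' @param config Named list or JSON path of [recovery_grid()] arguments
#'   (plus optional \code{profile}).
#' @param seed Seed for the sweep.
#' @param out Output directory.
#' @return Invisibly, the recovery table.
#' @export
cli_recover <- function(config = list(), seed = 1, out) {
  cfg <- resolve_config(config, defaults = list(
    beta_c = c(-0.03, 0, 0.03), beta_f = 0, beta_a = 0,
    n_participants = 60, n_replicates = 1, profile = "fast"))
  grid <- recovery_grid(beta_c = unlist(cfg$beta_c),
                        beta_f = unlist(cfg$beta_f),
                        beta_a = unlist(cfg$beta_a),
                        n_participants = cfg$n_participants,
                        n_replicates = cfg$n_replicates)
  tab <- run_parameter_recovery(grid,
                                config = mcmc_config(profile = cfg$profile,
                                                     seed = seed))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(tab, file.path(out, "recovery.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(correlations = as.list(attr(tab, "correlations")),
         variant = attr(tab, "variant"), seed = seed),
    file.path(out, "recovery.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message(sprintf("recovery: %d cells -> %s", max(tab$cell), out))
  invisible(tab)
}

#' Model-free diagnostics for a dataset on disk
#'
#' Writes the confidence-quantile SPE summary and the interaction
#' coefficient table as CSVs.
#'
#' @inheritParams cli_fit
#' @param n_boot Bootstrap resamples.
#' @return Invisibly, a list with both tables.
#' @export
cli_diagnose <- function(dataset_dir, n_boot = 500, out) {
  ds <- read_dataset(dataset_dir)
  stop_on_issues(validate_dataset(ds$trials, ds$blocks, ds$profiles))
  qs <- confidence_quantile_summary(ds$trials, ds$blocks, ds$profiles,
                                    n_boot = n_boot)
  it <- interaction_tests(ds$trials, ds$blocks, ds$profiles,
                          n_boot = min(n_boot, 200))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(qs, file.path(out, "quantile_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(it, file.path(out, "interaction_tests.csv"),
                   row.names = FALSE)
  message(sprintf("diagnostics -> %s", out))
  invisible(list(quantile_summary = qs, interaction_tests = it))
}

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

stop_on_issues <- function(issues) {
  if (nrow(issues)) {
    msg <- paste(sprintf("%s row %s: %s", issues$table, issues$row,
                         issues$message), collapse = "\n  ")
    stop("dataset failed schema validation:\n  ", msg)
  }
  invisible(TRUE)
}
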