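#' Define a parameter-recovery grid
#'
#' A grid of ground-truth slope values crossed with replicates. Every cell
#' simulates a cohort under the truth, fits the same variant, and records
#' truth vs estimate. Ground-truth values must keep the effective
#' asymmetries inside (-1, 1) over the symptom range.
#'
#' @param beta_c,beta_f,beta_a Vectors of ground-truth slope values (the
#'   grid is their crossing).
#' @param dlr_f0,dlr_c0 Asymmetry intercepts used for every cell.
#' @param mu0,v0 Initial-belief truth, passed to [model_params()].
#' @param n_participants Cohort size per cell.
#' @param n_replicates Replicate simulations per cell.
#' @param mh_max Upper end of the symptom range used to validate the grid.
#' @return A \code{recovery_grid} data.frame (one row per cell x replicate).
#' @export
recovery_grid <- function(beta_c = 0, beta_f = 0, beta_a = 0,
                          dlr_f0 = 0.1, dlr_c0 = 0.1,
                          mu0 = 0.7, v0 = 0.015,
                          n_participants = 120, n_replicates = 1,
                          mh_max = 21) {
  g <- expand.grid(beta_c = beta_c, beta_f = beta_f, beta_a = beta_a,
                   replicate = seq_len(n_replicates))
  eff_c <- abs(dlr_c0) + abs(g$beta_c) * mh_max
  eff_f <- abs(dlr_f0) + abs(g$beta_f) * mh_max
  if (any(eff_c >= 1 | eff_f >= 1))
    stop("grid invalid: effective asymmetries leave (-1, 1) over the mh range")
  g$cell <- seq_len(nrow(g))
  structure(cbind(g, dlr_f0 = dlr_f0, dlr_c0 = dlr_c0, mu0 = mu0, v0 = v0,
                  n_participants = n_participants),
            class = c("recovery_grid", "data.frame"))
}

# smallest variant whose free slopes include all nonzero truths in the grid
grid_variant <- function(grid) {
  need <- c(beta_c = any(grid$beta_c != 0), beta_f = any(grid$beta_f != 0),
            beta_a = any(grid$beta_a != 0))
  for (v in paste0("D", 0:6)) {
    sp <- distortion_spec(v)
    if (all(sp$free[names(need)] | !need)) return(sp)
  }
  distortion_spec("D4")
}

#' Simulate-and-refit parameter recovery
#'
#' For every grid cell, simulates a cohort from the ground truth, fits the
#' matching distortion variant, and records the posterior mean, 95% and
#' 99% HDIs, coverage and sign calls for each free slope. The
#' truth-estimate correlation per slope (over cells where that slope
#' varies) is attached as \code{attr(, "correlations")}.
#'
#' @param grid A [recovery_grid()].
#' @param config An [mcmc_config()]; the cell index is folded into its seed
#'   so cells are independent but reproducible.
#' @param variant Optional [distortion_spec()]; defaults to the smallest
#'   variant covering the grid's nonzero slopes.
#' @param experiment Study design profile to simulate.
#' @param ... Passed to [simulate_cohort()].
#' @return Data frame with one row per cell and slope (\code{parameter},
#'   \code{truth}, \code{estimate}, HDI bounds, \code{covered95},
#'   \code{sign_correct}, \code{converged}); failed fits are kept as rows
#'   with an \code{error} message.
#' @export
run_parameter_recovery <- function(grid, config = mcmc_config(profile = "fast"),
                                   variant = NULL, experiment = "exp1", ...) {
  stopifnot(inherits(grid, "recovery_grid"))
  spec <- if (is.null(variant)) grid_variant(grid) else variant
  slope_names <- names(spec$free)[spec$free]
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    truth <- model_params(mu0 = g$mu0, v0 = g$v0, dlr_f0 = g$dlr_f0,
                          dlr_c0 = g$dlr_c0, beta_c = g$beta_c,
                          beta_f = g$beta_f, beta_a = g$beta_a)
    cell_seed <- participant_seed(config$seed, 1000 + i)
    res <- tryCatch({
      co <- simulate_cohort(g$n_participants, experiment, params = truth,
                            spec = spec, seed = cell_seed, ...)
      cfg <- config; cfg$seed <- cell_seed
      fit_model(co$trials, co$blocks, co$profiles, spec = spec, config = cfg)
    }, error = function(e) e)
    for (sl in slope_names) {
      tv <- g[[sl]]
      if (inherits(res, "spe_fit")) {
        s <- res$summary[res$summary$parameter == sl, ]
        rows[[length(rows) + 1]] <- data.frame(
          cell = g$cell, replicate = g$replicate, parameter = sl, truth = tv,
          estimate = s$mean, sd = s$sd,
          hdi95_lo = s$hdi95_lo, hdi95_hi = s$hdi95_hi,
          hdi99_lo = s$hdi99_lo, hdi99_hi = s$hdi99_hi,
          covered95 = tv >= s$hdi95_lo & tv <= s$hdi95_hi,
          sign_correct = if (tv == 0) NA else
            (tv < 0 & s$hdi99_hi < 0) | (tv > 0 & s$hdi99_lo > 0),
          converged = res$converged, error = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          cell = g$cell, replicate = g$replicate, parameter = sl, truth = tv,
          estimate = NA_real_, sd = NA_real_, hdi95_lo = NA_real_,
          hdi95_hi = NA_real_, hdi99_lo = NA_real_, hdi99_hi = NA_real_,
          covered95 = NA, sign_correct = NA, converged = NA,
          error = conditionMessage(res), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  cors <- sapply(split(out, out$parameter), function(d) {
    if (length(unique(d$truth)) < 2 || all(is.na(d$estimate))) NA_real_
    else stats::cor(d$truth, d$estimate, use = "complete.obs")
  })
  attr(out, "correlations") <- cors
  attr(out, "variant") <- spec$variant
  out
}

#' Model-recovery confusion matrix
#'
#' Simulates cohorts under each generating variant and records which
#' candidate variant wins the DIC comparison, giving a confusion matrix
#' whose rows are generating models and columns selected models. Rows sum
#' to \code{n_replicates}.
#'
#' @param gen_variants Character vector of generating variant labels
#'   (>= 2).
#' @param candidates Candidate variants fitted to each cohort.
#' @param n_replicates Replicates per generating variant.
#' @param n_participants Cohort size.
#' @param truth_slopes Named list giving the slope values used when a
#'   generating variant frees them.
#' @param config An [mcmc_config()].
#' @param ... Passed to [simulate_cohort()] and [compare_models()].
#' @return List with the \code{confusion} matrix, per-run \code{details},
#'   and the configuration.
#' @export
run_model_recovery <- function(gen_variants = c("D0", "D1"),
                               candidates = paste0("D", 0:6),
                               n_replicates = 5, n_participants = 60,
                               truth_slopes = list(beta_c = -0.03,
                                                   beta_f = -0.02,
                                                   beta_a = -0.003),
                               config = mcmc_config(profile = "fast"), ...) {
  stopifnot(length(gen_variants) >= 2)
  confusion <- matrix(0L, length(gen_variants), length(candidates),
                      dimnames = list(gen_variants, candidates))
  details <- list()
  for (gv in gen_variants) {
    spec <- distortion_spec(gv)
    truth <- model_params(
      dlr_f0 = 0.1, dlr_c0 = 0.1,
      beta_c = if (spec$free["beta_c"]) truth_slopes$beta_c else 0,
      beta_f = if (spec$free["beta_f"]) truth_slopes$beta_f else 0,
      beta_a = if (spec$free["beta_a"]) truth_slopes$beta_a else 0)
    for (r in seq_len(n_replicates)) {
      run_seed <- participant_seed(config$seed,
                                   5000 + 100 * match(gv, gen_variants) + r)
      co <- simulate_cohort(n_participants, params = truth, spec = spec,
                            seed = run_seed, ...)
      cfg <- config; cfg$seed <- run_seed
      cmp <- compare_models(co$trials, co$blocks, co$profiles,
                            variants = candidates, config = cfg)
      confusion[gv, cmp$best] <- confusion[gv, cmp$best] + 1L
      details[[length(details) + 1]] <-
        cbind(generating = gv, replicate = r, cmp$table,
              stringsAsFactors = FALSE)
    }
  }
  list(confusion = confusion, details = do.call(rbind, details),
       n_replicates = n_replicates, candidates = candidates)
}

#' Minimum recoverable response-bias magnitude
#'
#' Scans a grid of \code{beta_a} magnitudes with the recovery harness and
#' returns the smallest magnitude whose 99% HDI excluded zero with the
#' correct sign in every replicate. Serves as the empirical recovery floor
#' against which fitted \code{beta_a} values are judged.
#'
#' @param magnitudes Candidate |beta_a| values, ascending.
#' @param sign Sign applied to the magnitudes.
#' @param ... Passed to [recovery_grid()] / [run_parameter_recovery()].
#' @param config An [mcmc_config()].
#' @return List with the \code{floor} magnitude (Inf if none recovered)
#'   and the underlying recovery \code{table}.
#' @export
beta_a_recovery_floor <- function(magnitudes = c(1e-4, 1e-3, 5e-3),
                                  sign = -1,
                                  config = mcmc_config(profile = "fast"),
                                  ...) {
  grid <- recovery_grid(beta_a = sign * magnitudes, ...)
  tab <- run_parameter_recovery(grid, config = config,
                                variant = distortion_spec("D3"))
  ba <- tab[tab$parameter == "beta_a" & tab$truth != 0, ]
  ok <- tapply(ba$sign_correct, abs(ba$truth), function(z) all(z %in% TRUE))
  mags <- as.numeric(names(ok))
  floor <- if (any(ok)) min(mags[ok]) else Inf
  list(floor = floor, table = tab)
}

#' Flag implausibly small fitted response-bias slopes
#'
#' A fitted \code{beta_a} whose magnitude sits below the recovery floor
#' cannot have been resolved by the design and is flagged as likely
#' spurious even if its HDI excludes zero.
#'
#' @param fit A \code{spe_fit} from a variant that frees \code{beta_a}.
#' @param floor Recovery floor from [beta_a_recovery_floor()].
#' @return List: \code{beta_a} posterior mean, the \code{floor},
#'   \code{hdi99}, and logical \code{spurious}.
#' @export
tiny_beta_a_check <- function(fit, floor) {
  stopifnot(inherits(fit, "spe_fit"))
  if (missing(floor) || is.null(floor))
    stop("recovery floor not yet computed; run beta_a_recovery_floor() first")
  s <- fit$summary[fit$summary$parameter == "beta_a", ]
  if (nrow(s) == 0) stop("fit has no free beta_a (variant ", fit$variant, ")")
  list(beta_a = s$mean, floor = floor,
       hdi99 = c(s$hdi99_lo, s$hdi99_hi),
       excludes_zero = s$hdi99_lo > 0 | s$hdi99_hi < 0,
       spurious = abs(s$mean) < floor)
}
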