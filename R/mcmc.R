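#' MCMC configuration
#'
#' Two stock profiles: \code{"full"} is the full-length setup (3 chains of
#' 2000 samples with the first 1000 discarded as burn-in) and \code{"fast"}
#' is a scaled-down profile (2 chains of 500 with 250 burn-in) for recovery
#' sweeps and tests.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_samples Total iterations per chain.
#' @param n_burnin Iterations discarded (and used for proposal adaptation).
#' @param seed Integer seed; chain c uses \code{seed + c}.
#' @param profile Optional shortcut overriding the three counts.
#' @return An \code{mcmc_config} object.
#' @export
mcmc_config <- function(n_chains = 3, n_samples = 2000, n_burnin = 1000,
                        seed = 1, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "fast"))
    if (profile == "full") {
      n_chains <- 3; n_samples <- 2000; n_burnin <- 1000
    } else {
      n_chains <- 2; n_samples <- 500; n_burnin <- 250
    }
  }
  stopifnot(n_chains >= 2, n_samples > n_burnin, n_burnin >= 0)
  structure(list(n_chains = n_chains, n_samples = n_samples,
                 n_burnin = n_burnin, seed = seed),
            class = "mcmc_config")
}

#' Fit the belief model to a cohort by MCMC
#'
#' Samples the posterior over the group-level parameters (initial-belief
#' mean/variance per task, asymmetry intercepts, and whichever symptom
#' slopes the distortion variant frees) with an adaptive component-wise
#' random-walk Metropolis sampler. Per-participant asymmetries are
#' deterministic functions of the symptom score, so the likelihood is a
#' single vectorised pass over participant-blocks via the closed-form
#' sufficient statistics of the belief recursion. Proposal scales adapt
#' towards a 0.44 acceptance rate during burn-in only, so retained draws
#' come from a fixed kernel.
#'
#' @param trials,blocks,profiles Cohort tables as produced by
#'   [simulate_cohort()] (or read from disk with [read_dataset()]).
#' @param spec A [distortion_spec()] naming the variant to fit.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param asymmetry Asymmetry-intercept structure; one of \code{"zero"},
#'   \code{"shared"}, \code{"split_type"} (default), \code{"split_task"},
#'   \code{"split_both"}.
#' @param reset_per_block,conf_transform Passed to [block_sufstats()].
#' @param prior_only If TRUE the likelihood is dropped and the sampler
#'   draws from the prior (sanity-check mode).
#' @param rhat_threshold Convergence flag threshold for split-chain R-hat.
#' @return A \code{spe_fit} object: matrix \code{draws} (retained samples x
#'   parameters), per-draw \code{loglik}, \code{dic}/\code{p_d}/\code{dbar},
#'   a \code{summary} data.frame (posterior mean, sd, 95% and 99% HDIs,
#'   R-hat), and the echoed configuration.
#' @export
fit_model <- function(trials, blocks, profiles,
                      spec = distortion_spec("D0"),
                      prior = prior_spec(), config = mcmc_config(),
                      asymmetry = "split_type",
                      reset_per_block = FALSE, conf_transform = "none",
                      prior_only = FALSE, rhat_threshold = 1.1) {
  md <- build_model_data(trials, blocks, profiles,
                         reset_per_block = reset_per_block,
                         conf_transform = conf_transform)
  layout <- param_layout(md$tasks, spec, asymmetry)
  ll_fun <- if (prior_only) function(theta) 0
            else function(theta) model_loglik(theta, md, layout)
  lp_fun <- function(theta) prior_logdens(theta, layout, prior)

  n_keep <- config$n_samples - config$n_burnin
  p <- length(layout$names)
  draws <- array(NA_real_, c(n_keep, p, config$n_chains),
                 dimnames = list(NULL, layout$names, NULL))
  loglik <- matrix(NA_real_, n_keep, config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    res <- run_chain(ll_fun, lp_fun, layout, config)
    draws[, , ch] <- res$draws
    loglik[, ch] <- res$loglik
  }

  rhat <- vapply(seq_len(p), function(j) split_rhat(draws[, j, ]), 0)
  names(rhat) <- layout$names
  if (any(rhat > rhat_threshold, na.rm = TRUE))
    warning("possible non-convergence: split-chain R-hat > ", rhat_threshold,
            " for ", paste(layout$names[which(rhat > rhat_threshold)],
                           collapse = ", "))

  flat <- do.call(rbind, lapply(seq_len(config$n_chains),
                                function(ch) draws[, , ch, drop = TRUE]))
  flat <- matrix(flat, ncol = p, dimnames = list(NULL, layout$names))
  ll_flat <- as.vector(loglik)
  theta_hat <- colMeans(flat)
  dic <- compute_dic(-2 * ll_flat, -2 * ll_fun(theta_hat))

  summ <- data.frame(
    parameter = layout$names,
    mean = theta_hat,
    sd = apply(flat, 2, stats::sd),
    hdi95_lo = NA_real_, hdi95_hi = NA_real_,
    hdi99_lo = NA_real_, hdi99_hi = NA_real_,
    rhat = rhat, row.names = NULL, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    h95 <- hdi(flat[, j], 0.95)
    h99 <- hdi(flat[, j], 0.99)
    summ$hdi95_lo[j] <- h95[1]; summ$hdi95_hi[j] <- h95[2]
    summ$hdi99_lo[j] <- h99[1]; summ$hdi99_hi[j] <- h99[2]
  }

  structure(list(draws = flat, draws_by_chain = draws, loglik = ll_flat,
                 dic = dic$dic, p_d = dic$p_d, dbar = dic$dbar,
                 summary = summ, rhat = rhat, variant = spec$variant,
                 layout = layout, config = config,
                 n_obs = length(md$spe), converged = all(rhat <= rhat_threshold)),
            class = "spe_fit")
}

run_chain <- function(ll_fun, lp_fun, layout, config) {
  theta <- init_theta(layout, prior_spec())
  guard <- 0
  while (!is.finite(lp_fun(theta) + ll_fun(theta)) && guard < 200) {
    theta <- init_theta(layout, prior_spec())
    guard <- guard + 1
  }
  p <- length(theta)
  scales <- proposal_scales(layout)
  cur_ll <- ll_fun(theta)
  cur_lp <- lp_fun(theta)
  n_keep <- config$n_samples - config$n_burnin
  out <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, layout$names))
  out_ll <- numeric(n_keep)
  acc <- integer(p)
  batch <- 50L
  nb <- 0L
  for (it in seq_len(config$n_samples)) {
    for (j in seq_len(p)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      lp <- lp_fun(prop)
      if (is.finite(lp)) {
        ll <- ll_fun(prop)
        if (log(stats::runif(1)) < (lp + ll) - (cur_lp + cur_ll)) {
          theta <- prop; cur_ll <- ll; cur_lp <- lp
          acc[j] <- acc[j] + 1L
        }
      }
    }
    if (it <= config$n_burnin && it %% batch == 0L) {
      nb <- nb + 1L
      rate <- acc / batch
      scales <- scales * exp(pmin(1, 2 / sqrt(nb)) * (rate - 0.44))
      acc[] <- 0L
    }
    if (it > config$n_burnin) {
      k <- it - config$n_burnin
      out[k, ] <- theta
      out_ll[k] <- cur_ll
    }
  }
  list(draws = out, loglik = out_ll)
}

#' @export
print.spe_fit <- function(x, ...) {
  cat(sprintf("<spe_fit> variant %s, %d draws (%d chains), %d observations\n",
              x$variant, nrow(x$draws), x$config$n_chains, x$n_obs))
  cat(sprintf("  DIC = %.2f (p_D = %.2f), converged: %s\n",
              x$dic, x$p_d, x$converged))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Deviance information criterion from posterior deviances
#'
#' Classic formulation: \code{DIC = Dbar + p_D} with effective parameter
#' count \code{p_D = Dbar - D(theta_hat)}, where \code{Dbar} is the mean
#' posterior deviance and \code{D(theta_hat)} the deviance at the posterior
#' mean. Lower is better; note DIC's known slight preference for more
#' complex models, which is why [compare_models()] flags small differences
#' as non-decisive.
#'
#' @param deviance Numeric vector of per-draw deviances (-2 log-likelihood).
#' @param deviance_at_mean Deviance evaluated at the posterior mean.
#' @return List with \code{dic}, \code{p_d}, \code{dbar}.
#' @export
compute_dic <- function(deviance, deviance_at_mean) {
  if (length(deviance) < 10) stop("need at least 10 post-burn-in draws")
  dbar <- mean(deviance)
  p_d <- dbar - deviance_at_mean
  list(dic = dbar + p_d, p_d = p_d, dbar = dbar)
}

#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed by sliding a window of \code{ceiling(mass * n)} draws over the
#' order statistics.
#'
#' @param draws Numeric sample (>= 100 draws).
#' @param mass Probability mass in (0, 1).
#' @return Numeric \code{c(lower, upper)}.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  if (length(draws) < 100) stop("need at least 100 draws for an HDI")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

# split-chain potential scale reduction factor
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  half <- floor(nrow(draws) / 2)
  if (half < 2) return(NA_real_)
  chains <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch)
    cbind(draws[seq_len(half), ch], draws[half + seq_len(half), ch])))
  m <- ncol(chains); n <- nrow(chains)
  mu <- colMeans(chains)
  s2 <- apply(chains, 2, stats::var)
  w <- mean(s2)
  b <- n * stats::var(mu)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit and rank distortion variants by DIC
#'
#' Fits a set of distortion variants (default the full D0-D6 space) to the
#' same cohort and tabulates DIC, effective parameters, and the DIC
#' difference to the best variant. Differences smaller than
#' \code{decisive_delta} are flagged non-decisive, acknowledging DIC's
#' slight complexity preference. With \code{space = "base"} the five
#' asymmetry-sharing structures of the no-symptom stage are compared
#' instead (all under D0).
#'
#' @param trials,blocks,profiles Cohort tables.
#' @param variants Character vector of variant labels to fit.
#' @param config An [mcmc_config()].
#' @param space \code{"distortion"} (D-space) or \code{"base"}.
#' @param decisive_delta DIC-difference threshold for a decisive win.
#' @param ... Passed on to [fit_model()].
#' @return A \code{spe_comparison}: data.frame \code{table} (one row per
#'   variant, ranked), \code{best}, and the list of fits.
#' @export
compare_models <- function(trials, blocks, profiles,
                           variants = paste0("D", 0:6),
                           config = mcmc_config(profile = "fast"),
                           space = c("distortion", "base"),
                           decisive_delta = 10, ...) {
  space <- match.arg(space)
  if (space == "base") variants <- base_model_variants()$label
  fits <- vector("list", length(variants))
  names(fits) <- variants
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[i]
    fit <- tryCatch({
      if (space == "distortion")
        fit_model(trials, blocks, profiles, spec = distortion_spec(v),
                  config = config, ...)
      else
        fit_model(trials, blocks, profiles, spec = distortion_spec("D0"),
                  asymmetry = if (v == "zero") "zero"
                              else if (v == "shared") "shared"
                              else if (v == "split_type") "split_type"
                              else if (v == "split_task") "split_task"
                              else "split_both",
                  config = config, ...)
    }, error = function(e) e)
    fits[[i]] <- fit
    ok <- inherits(fit, "spe_fit")
    rows[[i]] <- data.frame(
      variant = v,
      dic = if (ok) fit$dic else NA_real_,
      p_d = if (ok) fit$p_d else NA_real_,
      dbar = if (ok) fit$dbar else NA_real_,
      converged = if (ok) fit$converged else NA,
      error = if (ok) NA_character_ else conditionMessage(fit),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_dic <- tab$dic - min(tab$dic, na.rm = TRUE)
  tab$decisive <- tab$delta_dic > decisive_delta
  tab <- tab[order(tab$dic), ]
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$variant[1], fits = fits,
                 decisive_delta = decisive_delta, space = space),
            class = "spe_comparison")
}

#' @export
print.spe_comparison <- function(x, ...) {
  cat(sprintf("<spe_comparison> %s space, best: %s (non-decisive rivals: %s)\n",
              x$space, x$best,
              paste(x$table$variant[!x$table$decisive & x$table$variant != x$best],
                    collapse = ", ")))
  print(x$table[, c("variant", "dic", "p_d", "delta_dic", "decisive")],
        digits = 6)
  invisible(x)
}
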