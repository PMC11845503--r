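# Internal machinery turning a cohort into a fast likelihood function.
#
# The group-level likelihood is the product over participant-blocks of the
# Beta density of the observed SPE under the block-final belief, where the
# block-final shapes come from the closed-form sufficient statistics
# (block_sufstats). Per-participant asymmetries are deterministic functions
# of the symptom score, so no subject-level latent variables are needed.

# asymmetry structures available for the no-symptom base comparison;
# "split_type" (feedback vs confidence intercepts, shared across tasks) is
# the default structure on which the distortion variants D0-D6 are built
ASYMMETRY_STRUCTURES <- c("zero", "shared", "split_type", "split_task",
                          "split_both")

build_model_data <- function(trials, blocks, profiles,
                             reset_per_block = FALSE,
                             conf_transform = "none") {
  ss <- block_sufstats(trials, reset_per_block = reset_per_block,
                       conf_transform = conf_transform)
  key_ss <- paste(ss$participant_id, ss$block_index)
  key_bl <- paste(blocks$participant_id, blocks$block_index)
  m <- match(key_ss, key_bl)
  if (anyNA(m)) stop("block table is missing SPE rows present in the trials")
  spe_raw <- blocks$spe[m]
  if (any(spe_raw < 0 | spe_raw > 1)) stop("SPE values outside [0, 1]")
  mh <- profiles$mh_score[match(ss$participant_id, profiles$participant_id)]
  if (anyNA(mh)) stop("every participant needs an mh score in 'profiles'")
  list(ss = ss,
       spe = spe_boundary_transform(spe_raw, length(spe_raw)),
       mh = mh,
       tasks = intersect(c("perception", "memory"), unique(ss$task)),
       is_memory = ss$task == "memory")
}

# Free-parameter layout for a given distortion variant and asymmetry
# structure, restricted to the tasks present in the data.
param_layout <- function(tasks, spec, asymmetry = "split_type") {
  asymmetry <- match.arg(asymmetry, ASYMMETRY_STRUCTURES)
  nm <- c(paste0("mu0_", tasks), paste0("v0_", tasks))
  nm <- c(nm, switch(asymmetry,
    zero = character(0),
    shared = "dlr0",
    split_type = c("dlr_f0", "dlr_c0"),
    split_task = paste0("dlr0_", tasks),
    split_both = c(paste0("dlr_f0_", tasks), paste0("dlr_c0_", tasks))))
  if (spec$free["beta_c"]) nm <- c(nm, "beta_c")
  if (spec$free["beta_f"]) nm <- c(nm, "beta_f")
  if (spec$free["beta_a"]) nm <- c(nm, "beta_a")
  list(names = nm, tasks = tasks, asymmetry = asymmetry, spec = spec)
}

# expand a named parameter vector into per-row model quantities
theta_pieces <- function(theta, layout) {
  tasks <- layout$tasks
  g <- function(p, task) {
    v <- theta[paste0(p, "_", task)]
    if (is.na(v)) theta[p] else v
  }
  mu0 <- vapply(tasks, function(tk) unname(theta[paste0("mu0_", tk)]), 0)
  v0 <- vapply(tasks, function(tk) unname(theta[paste0("v0_", tk)]), 0)
  f0 <- c0 <- stats::setNames(numeric(length(tasks)), tasks)
  for (tk in tasks) {
    f0[tk] <- switch(layout$asymmetry,
      zero = 0,
      shared = unname(theta["dlr0"]),
      split_type = unname(theta["dlr_f0"]),
      split_task = unname(theta[paste0("dlr0_", tk)]),
      split_both = unname(theta[paste0("dlr_f0_", tk)]))
    c0[tk] <- switch(layout$asymmetry,
      zero = 0,
      shared = unname(theta["dlr0"]),
      split_type = unname(theta["dlr_c0"]),
      split_task = unname(theta[paste0("dlr0_", tk)]),
      split_both = unname(theta[paste0("dlr_c0_", tk)]))
  }
  list(mu0 = stats::setNames(mu0, tasks), v0 = stats::setNames(v0, tasks),
       f0 = f0, c0 = c0,
       beta_c = if ("beta_c" %in% names(theta)) unname(theta["beta_c"]) else 0,
       beta_f = if ("beta_f" %in% names(theta)) unname(theta["beta_f"]) else 0,
       beta_a = if ("beta_a" %in% names(theta)) unname(theta["beta_a"]) else 0)
}

# total log-likelihood of the SPE observations given a parameter vector
model_loglik <- function(theta, md, layout) {
  pc <- theta_pieces(theta, layout)
  if (any(pc$mu0 <= 0 | pc$mu0 >= 1) ||
      any(pc$v0 <= 0 | pc$v0 >= pc$mu0 * (1 - pc$mu0)))
    return(-Inf)
  k <- pc$mu0 - pc$mu0^2 - pc$v0
  a0t <- pc$mu0 / pc$v0 * k
  b0t <- (1 - pc$mu0) / pc$v0 * k
  ti <- match(md$ss$task, layout$tasks)
  dlr_f <- clip01(pc$f0[ti] + pc$beta_f * md$mh, -0.99, 0.99)
  dlr_c <- clip01(pc$c0[ti] + pc$beta_c * md$mh, -0.99, 0.99)
  a <- a0t[ti] + md$ss$n_fb_cor * (1 + dlr_f) + md$ss$s_conf * (1 + dlr_c)
  b <- b0t[ti] + md$ss$n_fb_inc * (1 - dlr_f) + md$ss$s_inv * (1 - dlr_c)
  if (pc$beta_a != 0) {
    n <- a + b
    m <- clip01(a / n + pc$beta_a * md$mh, 0.001, 0.999)
    a <- m * n
    b <- (1 - m) * n
  }
  sum(stats::dbeta(md$spe, a, b, log = TRUE))
}

#' Prior specification for group-level fitting
#'
#' Deliberately weak priors over the natural supports: \code{mu0} uniform
#' on (0, 1); \code{v0} uniform on (0, 0.24), further truncated by the Beta
#' validity bound \code{v0 < mu0(1 - mu0)}; asymmetry intercepts uniform on
#' (-0.99, 0.99); the regression slopes \code{beta_f}, \code{beta_c}
#' normal(0, 1) (effective asymmetries are clipped to (-0.99, 0.99) inside
#' the likelihood, which bounds their reach); \code{beta_a} normal(0, 0.1).
#' These families are the package's own concretisation of "weak prior
#' information", not facts about any particular dataset.
#'
#' @param v0_max Upper bound of the variance prior.
#' @param beta_sd SD of the normal prior on \code{beta_f}, \code{beta_c}.
#' @param beta_a_sd SD of the normal prior on \code{beta_a}.
#' @return A \code{prior_spec} object.
#' @export
prior_spec <- function(v0_max = 0.24, beta_sd = 1, beta_a_sd = 0.1) {
  structure(list(v0_max = v0_max, beta_sd = beta_sd, beta_a_sd = beta_a_sd),
            class = "prior_spec")
}

prior_logdens <- function(theta, layout, prior) {
  lp <- 0
  for (nm in names(theta)) {
    x <- theta[[nm]]
    lp <- lp + if (startsWith(nm, "mu0_")) {
      if (x <= 0 || x >= 1) -Inf else 0
    } else if (startsWith(nm, "v0_")) {
      if (x <= 0 || x >= prior$v0_max) -Inf else -log(prior$v0_max)
    } else if (startsWith(nm, "dlr")) {
      if (abs(x) >= 0.99) -Inf else -log(1.98)
    } else if (nm == "beta_a") {
      stats::dnorm(x, 0, prior$beta_a_sd, log = TRUE)
    } else {
      stats::dnorm(x, 0, prior$beta_sd, log = TRUE)
    }
  }
  lp
}

# over-dispersed chain initialisation (rejected until inside the support)
init_theta <- function(layout, prior) {
  draw1 <- function(nm) {
    if (startsWith(nm, "mu0_")) stats::runif(1, 0.35, 0.9)
    else if (startsWith(nm, "v0_")) stats::runif(1, 0.004, 0.06)
    else if (startsWith(nm, "dlr")) stats::runif(1, -0.4, 0.4)
    else if (nm == "beta_a") stats::rnorm(1, 0, 0.002)
    else stats::rnorm(1, 0, 0.01)
  }
  stats::setNames(vapply(layout$names, draw1, 0), layout$names)
}

proposal_scales <- function(layout) {
  s <- function(nm) {
    if (startsWith(nm, "mu0_")) 0.04
    else if (startsWith(nm, "v0_")) 0.004
    else if (startsWith(nm, "dlr")) 0.05
    else if (nm == "beta_a") 5e-4
    else 0.004
  }
  stats::setNames(vapply(layout$names, s, 0), layout$names)
}
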