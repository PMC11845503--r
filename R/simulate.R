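#' Default per-task simulation settings
#'
#' Levels are task-native difficulty axes oriented so that higher = easier:
#' the berry-count difference for perception (start 20, step 2, bounds
#' 1-60) and an inverted set-size axis for memory (start 6, step 1, bounds
#' 1-12). The psychometric observers are logistic in level; slopes and
#' thresholds are stand-ins chosen for stable staircase convergence near
#' 71% correct, since the study protocol does not pin them down.
#'
#' @param task \code{"perception"} or \code{"memory"}.
#' @param conf_bias_per_mh Symptom-linked confidence shift passed through
#'   to [observer_params()].
#' @return List with an \code{observer} and a staircase constructor
#'   \code{new_staircase()}.
#' @export
task_defaults <- function(task = c("perception", "memory"),
                          conf_bias_per_mh = -0.005) {
  task <- match.arg(task)
  if (task == "perception")
    list(observer = observer_params(psychometric_slope = 0.18, threshold = 12,
                                    conf_bias_per_mh = conf_bias_per_mh),
         new_staircase = function() staircase_new(20, 2, c(1, 60)))
  else
    list(observer = observer_params(psychometric_slope = 0.5, threshold = 4,
                                    conf_bias_per_mh = conf_bias_per_mh),
         new_staircase = function() staircase_new(6, 1, c(1, 12)))
}

#' Simulate a full behavioural cohort
#'
#' Generates trial-level data with the statistical structure the analysis
#' assumes: participants are assigned round-robin to the eight
#' counterbalanced group designs; accuracy is controlled by per-task
#' 1-up-2-down staircases (initialised by 50 practice trials, with
#' between-block carry-over via the mean of the last five reversals);
#' confidence comes from a noisy logistic observer with a symptom-linked
#' negative bias; intervention-block feedback follows the rigged
#' probabilities of [feedback_probs()]; and end-of-block global SPEs are
#' drawn from the Beta-belief model under the supplied ground-truth
#' parameters and distortion variant.
#'
#' Reproducibility: every participant gets an independent child RNG stream
#' derived deterministically from \code{seed}, so any subset of
#' participants can be regenerated without simulating the rest.
#'
#' @param n_participants Number of participants (>= 8, one per group).
#' @param experiment \code{"exp1"} or \code{"exp2"}.
#' @param params Ground-truth [model_params()].
#' @param spec Ground-truth [distortion_spec()].
#' @param mh_dist Function of n returning symptom scores; default
#'   Uniform(0, 21), the GAD-7 range.
#' @param seed Root integer seed.
#' @param conf_bias_per_mh Observer confidence bias per symptom unit.
#' @param conf_block_sd SD of a slow per-block confidence shift (block-level
#'   "mood" drift); this is what couples block-mean confidence to the
#'   belief-generated SPEs within a participant, as in real data where
#'   confidence varies between blocks, not only between trials.
#' @param exact_quota If TRUE, intervention feedback uses an exact 9 + 1
#'   quota per block instead of per-trial Bernoulli draws (low-variance
#'   mode for tests).
#' @param reset_per_block Passed to the belief model when generating SPEs.
#' @param n_practice Staircase initialisation trials per task (not output).
#' @return List of class \code{spe_cohort} with data.frames \code{trials},
#'   \code{blocks}, \code{profiles} and the echoed \code{config}.
#' @export
simulate_cohort <- function(n_participants, experiment = "exp1",
                            params = model_params(),
                            spec = distortion_spec("D0"),
                            mh_dist = function(n) stats::runif(n, 0, 21),
                            seed = 1, conf_bias_per_mh = -0.005,
                            conf_block_sd = 0.1,
                            exact_quota = FALSE, reset_per_block = FALSE,
                            n_practice = 50) {
  stopifnot(n_participants >= 8)
  designs <- make_group_designs(experiment)
  trials <- vector("list", n_participants)
  blocks <- vector("list", n_participants)
  profiles <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(participant_seed(seed, i))
    gid <- ((i - 1L) %% 8L) + 1L
    mh <- mh_dist(1)
    sim <- simulate_participant(
      pid = i, design = designs[[gid]], mh = mh, params = params,
      spec = spec, conf_bias_per_mh = conf_bias_per_mh,
      conf_block_sd = conf_block_sd, exact_quota = exact_quota,
      reset_per_block = reset_per_block, n_practice = n_practice)
    trials[[i]] <- sim$trials
    blocks[[i]] <- sim$blocks
    profiles[[i]] <- data.frame(participant_id = i, group_id = gid,
                                experiment = experiment, mh_score = mh,
                                stringsAsFactors = FALSE)
  }
  structure(list(trials = do.call(rbind, trials),
                 blocks = do.call(rbind, blocks),
                 profiles = do.call(rbind, profiles),
                 config = list(n_participants = n_participants,
                               experiment = experiment, seed = seed,
                               variant = spec$variant,
                               conf_bias_per_mh = conf_bias_per_mh,
                               conf_block_sd = conf_block_sd,
                               exact_quota = exact_quota,
                               reset_per_block = reset_per_block,
                               params = params_to_list(params))),
            class = "spe_cohort")
}

# JSON-friendly echo of model_params (named vectors become named lists)
params_to_list <- function(params) {
  lapply(unclass(params), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
}

participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483629)
}

#' @export
print.spe_cohort <- function(x, ...) {
  cat(sprintf("<spe_cohort> %s: %d participants, %d trials, %d blocks (%s)\n",
              x$config$experiment, nrow(x$profiles), nrow(x$trials),
              nrow(x$blocks), x$config$variant))
  invisible(x)
}

simulate_participant <- function(pid, design, mh, params, spec,
                                 conf_bias_per_mh, conf_block_sd,
                                 exact_quota, reset_per_block, n_practice) {
  tasks_used <- unique(design$blocks$task)
  ctx <- list()
  for (task in tasks_used) {
    td <- task_defaults(task, conf_bias_per_mh)
    st <- td$new_staircase()
    for (t in seq_len(n_practice)) {
      tr <- simulate_trial(td$observer, st$level, mh)
      st <- staircase_update(st, tr$correct)
    }
    ctx[[task]] <- list(observer = td$observer, staircase = st)
  }
  rows <- vector("list", 6)
  for (b in seq_len(6)) {
    bl <- design$blocks[b, ]
    task <- bl$task
    st <- ctx[[task]]$staircase
    # start each block at the mean of the previous block's last 5 reversals
    st$level <- staircase_carryover_level(st)
    st$reversal_levels <- numeric(0)
    st$consecutive_correct <- 0L
    st$last_direction <- "none"
    n <- bl$n_trials
    block_shift <- stats::rnorm(1, 0, conf_block_sd)
    level <- correct <- confidence <- numeric(n)
    feedback <- character(n)
    for (t in seq_len(n)) {
      level[t] <- st$level
      tr <- simulate_trial(ctx[[task]]$observer, st$level, mh, block_shift)
      correct[t] <- tr$correct
      confidence[t] <- tr$confidence
      feedback[t] <- if (exact_quota) "none"
        else schedule_feedback(bl$feedback_valence, tr$correct)
      st <- staircase_update(st, tr$correct)
    }
    if (exact_quota && bl$feedback_valence != "none") {
      feedback <- exact_quota_feedback(correct == 1, bl$feedback_valence)
    }
    ctx[[task]]$staircase <- st
    rows[[b]] <- data.frame(
      participant_id = pid, group_id = design$group_id, task = task,
      phase = bl$phase, feedback_valence = bl$feedback_valence,
      block_index = b, trial_index = seq_len(n), level = level,
      correct = as.logical(correct), confidence = confidence,
      feedback = feedback, stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  traj <- run_sequence(trials, params, spec, mh,
                       reset_per_block = reset_per_block)
  beta_a <- if (spec$free["beta_a"]) params$beta_a else 0
  spe <- numeric(6)
  for (b in seq_len(6)) {
    st <- bias_shift_belief(belief_state(traj$a[b], traj$b[b]), beta_a, mh)
    spe[b] <- stats::rbeta(1, st$a, st$b)
  }
  acc <- tapply(trials$correct, trials$block_index, mean)
  cm <- tapply(trials$confidence, trials$block_index, mean)
  blocks <- data.frame(
    participant_id = pid, group_id = design$group_id,
    task = design$blocks$task, phase = design$blocks$phase,
    feedback_valence = design$blocks$feedback_valence, block_index = 1:6,
    n_trials = design$blocks$n_trials, spe = clip01(spe, 1e-6, 1 - 1e-6),
    accuracy_mean = as.numeric(acc[as.character(1:6)]),
    confidence_mean = as.numeric(cm[as.character(1:6)]),
    stringsAsFactors = FALSE)
  list(trials = trials, blocks = blocks)
}

# deterministic-count feedback assignment: 9 events on the favoured outcome,
# 1 on the other (fewer if fewer such trials exist)
exact_quota_feedback <- function(correct, valence) {
  n <- length(correct)
  quota_cor <- if (valence == "positive") 9L else 1L
  quota_inc <- if (valence == "positive") 1L else 9L
  fb <- rep("none", n)
  ic <- which(correct); ii <- which(!correct)
  pick <- function(idx, k) if (length(idx) <= k) idx else sample(idx, k)
  fb[pick(ic, quota_cor)] <- "correct_shown"
  fb[pick(ii, quota_inc)] <- "incorrect_shown"
  fb
}
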