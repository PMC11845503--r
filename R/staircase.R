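#' Create a 1-up-2-down staircase state
#'
#' Difficulty is tracked on an abstract "level" axis where higher values
#' make the task easier (for the perception task, the berry-count
#' difference; for the memory task, an inverted set-size axis). Two
#' consecutive correct responses step the level down (harder); every error
#' steps it up (easier). This transformed staircase converges on the
#' accuracy p solving p^2 = 1/2, i.e. about 70.7% correct.
#'
#' @param level Starting difficulty level.
#' @param step Step size (level units) applied at each adjustment.
#' @param bounds Length-2 numeric; the level is clamped to this range.
#' @return A \code{staircase_state} list.
#' @export
staircase_new <- function(level = 20, step = 2, bounds = c(1, 60)) {
  stopifnot(step > 0, length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(level = clip01(level, bounds[1], bounds[2]), step = step,
                 bounds = bounds, consecutive_correct = 0L,
                 n_reversals = 0L, last_direction = "none",
                 reversal_levels = numeric(0)),
            class = "staircase_state")
}

#' Advance a 1-up-2-down staircase by one response
#'
#' An incorrect response raises the level by one step (easier) and resets
#' the consecutive-correct counter. A correct response increments the
#' counter; when it reaches two, the level drops one step (harder) and the
#' counter resets. A reversal is counted whenever the direction of a level
#' move changes; the level at each reversal is recorded, since block
#' starting levels are carried over as the mean of the last five reversals.
#'
#' @param state A \code{staircase_state}.
#' @param correct Logical response correctness.
#' @return The updated \code{staircase_state}.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  dir <- NULL
  if (isTRUE(as.logical(correct))) {
    cc <- state$consecutive_correct + 1L
    if (cc >= 2L) {
      state$level <- max(state$level - state$step, state$bounds[1])
      state$consecutive_correct <- 0L
      dir <- "down"
    } else {
      state$consecutive_correct <- cc
    }
  } else {
    state$level <- min(state$level + state$step, state$bounds[2])
    state$consecutive_correct <- 0L
    dir <- "up"
  }
  if (!is.null(dir)) {
    if (state$last_direction != "none" && dir != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      state$reversal_levels <- c(state$reversal_levels, state$level)
    }
    state$last_direction <- dir
  }
  state
}

# carry-over rule between blocks: mean of the last five reversal levels
# (or fewer if fewer occurred), falling back to the current level
staircase_carryover_level <- function(state, k = 5) {
  rl <- state$reversal_levels
  if (length(rl) == 0) return(state$level)
  mean(utils::tail(rl, k))
}

#' Long-run accuracy of an observer under the staircase
#'
#' Monte-Carlo estimate of the asymptotic proportion correct reached by a
#' simulated observer whose probability correct follows its psychometric
#' function of level. The first fifth of trials is discarded as transient.
#' For any observer whose psychometric function crosses sqrt(1/2) within
#' the level bounds, the estimate should sit near 70.7%.
#'
#' @param observer An [observer_params()] object.
#' @param n_trials Number of simulated trials (>= 2000).
#' @param state Optional starting \code{staircase_state}.
#' @param burn_frac Fraction of initial trials discarded.
#' @return Proportion correct over the retained trials.
#' @export
staircase_convergence <- function(observer, n_trials = 10000,
                                  state = staircase_new(), burn_frac = 0.2) {
  stopifnot(n_trials >= 2000)
  pc <- psychometric(observer, state$bounds)
  pgrid <- pc(seq(state$bounds[1], state$bounds[2], length.out = 50))
  # a flat psychometric function gives the staircase nothing to regulate;
  # the exception is an observer pinned at chance, whose accuracy is simply 0.5
  if (diff(range(pgrid)) < 0.02 && any(abs(pgrid - 0.5) > 0.02))
    stop("degenerate observer: psychometric function is flat over the level bounds")
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    correct[t] <- stats::runif(1) < pc(state$level)
    state <- staircase_update(state, correct[t])
  }
  mean(correct[-seq_len(floor(burn_frac * n_trials))])
}

#' Simulated observer parameters
#'
#' A logistic psychometric observer: probability correct rises from chance
#' (0.5) towards 1 with level as
#' \code{0.5 + 0.5 * plogis(psychometric_slope * (level - threshold))}.
#' Confidence generation adds Gaussian noise (\code{conf_noise}) and a
#' symptom-linked additive shift of \code{conf_bias_per_mh} per raw symptom
#' unit (negative by default: more symptomatic observers report lower
#' confidence on average).
#'
#' @param psychometric_slope Positive slope of the logistic psychometric
#'   function (per level unit).
#' @param threshold Level at which probability correct is 0.75.
#' @param conf_noise SD of additive Gaussian confidence noise.
#' @param conf_bias_per_mh Confidence shift per symptom unit.
#' @param conf_gain Gain mapping signed internal evidence to confidence.
#' @return An \code{observer_params} object.
#' @export
observer_params <- function(psychometric_slope = 0.18, threshold = 12,
                            conf_noise = 0.08, conf_bias_per_mh = -0.005,
                            conf_gain = 0.9) {
  stopifnot(psychometric_slope > 0, conf_noise > 0)
  structure(list(psychometric_slope = psychometric_slope,
                 threshold = threshold, conf_noise = conf_noise,
                 conf_bias_per_mh = conf_bias_per_mh, conf_gain = conf_gain),
            class = "observer_params")
}

psychometric <- function(observer, bounds = c(1, 60)) {
  function(level)
    0.5 + 0.5 * stats::plogis(observer$psychometric_slope *
                                (level - observer$threshold))
}

#' Simulate one trial's outcome and confidence report
#'
#' Correctness is Bernoulli with the observer's psychometric probability at
#' the given level. Confidence is a logistic of signed internal evidence
#' (positive on correct trials, negative on errors, magnitude tied to how
#' easy the level is), plus Gaussian noise and the symptom-linked bias,
#' clipped to [0.001, 0.999].
#'
#' @param observer An [observer_params()] object.
#' @param level Current difficulty level.
#' @param mh Participant symptom score.
#' @param conf_shift Additional additive confidence shift (used for
#'   block-level confidence drift in the cohort simulator).
#' @return List with logical \code{correct} and numeric \code{confidence}.
#' @export
simulate_trial <- function(observer, level, mh = 0, conf_shift = 0) {
  p <- psychometric(observer)(level)
  correct <- stats::runif(1) < p
  # signed evidence: log-odds of being correct at this level, sign by outcome
  strength <- abs(stats::rnorm(1, mean = stats::qlogis(p), sd = 1))
  evid <- (2 * correct - 1) * strength
  conf <- stats::plogis(observer$conf_gain * evid) +
    observer$conf_bias_per_mh * mh + conf_shift +
    stats::rnorm(1, 0, observer$conf_noise)
  list(correct = correct, confidence = clip01(conf, 0.001, 0.999))
}
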