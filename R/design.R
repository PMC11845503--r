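#' Rigged feedback probabilities
#'
#' On intervention blocks an "auditor" delivers trial-wise feedback with
#' probabilities chosen so that, at the staircase's ~71% accuracy, a
#' 40-trial positive block yields on average 9 feedback events on correct
#' trials and 1 on incorrect trials, and a negative block the mirror image:
#' \itemize{
#'   \item positive, correct: 9 / (40 * 0.71) = 0.3169
#'   \item positive, incorrect: 1 / (40 * 0.29) = 0.0862
#'   \item negative, correct: 1 / (40 * 0.71) = 0.0352
#'   \item negative, incorrect: 9 / (40 * 0.29) = 0.7759
#' }
#'
#' @param valence \code{"positive"} or \code{"negative"}.
#' @return Named numeric \code{c(correct = , incorrect = )} of per-trial
#'   feedback probabilities.
#' @export
feedback_probs <- function(valence = c("positive", "negative")) {
  valence <- match.arg(valence)
  if (valence == "positive")
    c(correct = 9 / (40 * 0.71), incorrect = 1 / (40 * (1 - 0.71)))
  else
    c(correct = 1 / (40 * 0.71), incorrect = 9 / (40 * (1 - 0.71)))
}

#' Draw the feedback event for one trial
#'
#' @param valence Block feedback valence: \code{"none"}, \code{"positive"}
#'   or \code{"negative"}. No-feedback blocks always return \code{"none"}.
#' @param correct Logical; the trial's true correctness (feedback, when
#'   shown, is veridical).
#' @param exact_quota Optional low-variance mode: a function is not used
#'   here, see [simulate_cohort()]'s \code{exact_quota} flag.
#' @return \code{"none"}, \code{"correct_shown"} or \code{"incorrect_shown"}.
#' @export
schedule_feedback <- function(valence, correct) {
  if (valence == "none") return("none")
  p <- feedback_probs(valence)[[if (correct) "correct" else "incorrect"]]
  if (stats::runif(1) < p) {
    if (correct) "correct_shown" else "incorrect_shown"
  } else "none"
}

#' Expected feedback-event counts for a block
#'
#' @param n_trials Number of trials in the block.
#' @param p_correct Expected accuracy (0 < p < 1).
#' @param valence \code{"positive"} or \code{"negative"}.
#' @return Named numeric \code{c(correct_shown = , incorrect_shown = )} of
#'   expected event counts. A 40-trial positive block at 71% accuracy gives
#'   (9, 1); a negative block (1, 9).
#' @export
expected_feedback_counts <- function(n_trials, p_correct, valence) {
  stopifnot(n_trials >= 0, p_correct > 0, p_correct < 1)
  p <- feedback_probs(valence)
  c(correct_shown = n_trials * p_correct * p[["correct"]],
    incorrect_shown = n_trials * (1 - p_correct) * p[["incorrect"]])
}

#' Counterbalanced block orders for the eight participant groups
#'
#' Each group's sequence has six main blocks: two feedback-free baseline
#' blocks, then two intervention blocks (with rigged feedback of opposite
#' valences) each followed by a feedback-free test block. In experiment 1
#' the eight groups cross intervention task (perception/memory) x transfer
#' type (test blocks on the same task or the other task) x feedback order
#' (positive or negative intervention first); same-task groups use a single
#' task throughout, while transfer groups get one baseline block per task.
#' In experiment 2 test blocks are always the opposite task and are
#' shortened to 20 trials; the eight groups cross intervention task x
#' feedback order x word-set order (the last carried as metadata only).
#'
#' @param experiment \code{"exp1"} or \code{"exp2"}.
#' @return List of 8 \code{group_design} objects, each with fields
#'   \code{group_id}, \code{experiment}, metadata flags and a data.frame
#'   \code{blocks} (columns \code{block_index}, \code{task}, \code{phase},
#'   \code{feedback_valence}, \code{n_trials}).
#' @export
make_group_designs <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  tasks <- c("perception", "memory")
  orders <- c("positive_first", "negative_first")
  designs <- list()
  gid <- 0L
  if (experiment == "exp1") {
    for (itask in tasks) for (transfer in c(FALSE, TRUE)) for (ord in orders) {
      gid <- gid + 1L
      ttask <- if (transfer) setdiff(tasks, itask) else itask
      v1 <- if (ord == "positive_first") "positive" else "negative"
      v2 <- setdiff(c("positive", "negative"), v1)
      base_tasks <- if (transfer) c(itask, ttask) else c(itask, itask)
      blocks <- data.frame(
        block_index = 1:6,
        task = c(base_tasks, itask, ttask, itask, ttask),
        phase = c("baseline", "baseline", "intervention", "test",
                  "intervention", "test"),
        feedback_valence = c("none", "none", v1, "none", v2, "none"),
        n_trials = rep(40L, 6),
        stringsAsFactors = FALSE)
      designs[[gid]] <- group_design(gid, experiment, blocks,
                                     intervention_task = itask,
                                     transfer = transfer,
                                     feedback_order = ord)
    }
  } else {
    for (itask in tasks) for (ord in orders) for (wset in c("AB", "BA")) {
      gid <- gid + 1L
      ttask <- setdiff(tasks, itask)
      v1 <- if (ord == "positive_first") "positive" else "negative"
      v2 <- setdiff(c("positive", "negative"), v1)
      blocks <- data.frame(
        block_index = 1:6,
        task = c(itask, ttask, itask, ttask, itask, ttask),
        phase = c("baseline", "baseline", "intervention", "test",
                  "intervention", "test"),
        feedback_valence = c("none", "none", v1, "none", v2, "none"),
        n_trials = c(40L, 40L, 40L, 20L, 40L, 20L),
        stringsAsFactors = FALSE)
      designs[[gid]] <- group_design(gid, experiment, blocks,
                                     intervention_task = itask,
                                     transfer = TRUE,
                                     feedback_order = ord,
                                     word_set_order = wset)
    }
  }
  designs
}

group_design <- function(group_id, experiment, blocks, ...) {
  stopifnot(nrow(blocks) == 6)
  iv <- blocks$feedback_valence[blocks$phase == "intervention"]
  stopifnot(sort(iv) == c("negative", "positive"),
            all(blocks$feedback_valence[blocks$phase != "intervention"] == "none"),
            all(blocks$n_trials %in% c(20L, 40L)))
  structure(c(list(group_id = group_id, experiment = experiment,
                   blocks = blocks), list(...)),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("<group_design> %s group %d (%s intervention, %s)\n",
              x$experiment, x$group_id, x$intervention_task, x$feedback_order))
  print(x$blocks)
  invisible(x)
}
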