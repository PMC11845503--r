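#' Run the belief model over one participant's trial stream
#'
#' Applies the Beta-belief recursion trial by trial: a feedback update
#' ([update_feedback()]) on trials where a feedback event occurred, a
#' confidence update ([update_confidence()]) otherwise. Beliefs are kept
#' separately per task, initialised from the task's \code{(mu0, v0)}, and by
#' default carried over across blocks of the same task;
#' \code{reset_per_block = TRUE} reinitialises at every block start.
#'
#' @param trials Data frame of one participant's trials, ordered by
#'   \code{block_index} then \code{trial_index}, with columns \code{task},
#'   \code{block_index}, \code{correct}, \code{confidence}, \code{feedback}
#'   (\code{"none"}, \code{"correct_shown"} or \code{"incorrect_shown"}).
#' @param params A [model_params()] object.
#' @param spec A [distortion_spec()]; defaults to no distortion.
#' @param mh Participant's symptom score.
#' @param reset_per_block Reinitialise the task belief at each block start?
#' @param conf_transform \code{"none"} (use raw slider confidence) or
#'   \code{"rank"} (within-participant rank transform to (0, 1) before
#'   updating).
#' @return Data frame with one row per block: \code{block_index},
#'   \code{task}, block-final shapes \code{a}, \code{b}, belief mean
#'   \code{mu}, and \code{spe_pred} (mean after any report bias).
#' @export
run_sequence <- function(trials, params, spec = distortion_spec("D0"), mh = 0,
                         reset_per_block = FALSE,
                         conf_transform = c("none", "rank")) {
  conf_transform <- match.arg(conf_transform)
  check_trial_order(trials)
  if (!all(trials$task %in% c("perception", "memory")))
    stop("unknown task label in trial stream")
  conf <- if (conf_transform == "rank") rank_to_unit(trials$confidence)
          else trials$confidence

  beliefs <- list()
  blocks <- unique(trials$block_index)
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    idx <- which(trials$block_index == blocks[k])
    task <- trials$task[idx[1]]
    if (is.null(beliefs[[task]]) || reset_per_block)
      beliefs[[task]] <- init_belief(params$mu0[[task]], params$v0[[task]])
    dlr <- effective_asymmetries(params, spec, mh, task)
    st <- beliefs[[task]]
    for (i in idx) {
      st <- if (trials$feedback[i] != "none")
        update_feedback(st, trials$feedback[i] == "correct_shown", dlr[["dlr_f"]])
      else
        update_confidence(st, conf[i], dlr[["dlr_c"]])
    }
    beliefs[[task]] <- st
    out[[k]] <- data.frame(block_index = blocks[k], task = task,
                           a = st$a, b = st$b, mu = belief_mean(st),
                           spe_pred = predicted_spe(st, params, spec, mh),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

check_trial_order <- function(trials) {
  o <- order(trials$block_index, trials$trial_index)
  if (is.unsorted(o) || any(o != seq_along(o)))
    stop("trials must be ordered by block_index then trial_index")
  invisible(TRUE)
}

rank_to_unit <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)

#' Block-end sufficient statistics of the belief recursion
#'
#' The belief recursion is linear in its increments, so the block-final
#' shapes have closed form:
#' \deqn{a_n = a_0 + N^{fb+} (1 + \Delta LR_f) + S_c (1 + \Delta LR_c)}
#' \deqn{b_n = b_0 + N^{fb-} (1 - \Delta LR_f) + S_{1-c} (1 - \Delta LR_c)}
#' where \eqn{N^{fb\pm}} count shown-correct / shown-incorrect feedback
#' events and \eqn{S_c}, \eqn{S_{1-c}} sum confidence and its complement over
#' no-feedback trials, accumulated per task up to each block end. This
#' reduces one likelihood evaluation for a whole cohort to a vectorised
#' computation over participant-blocks; it is the workhorse behind
#' [fit_model()]. Exact agreement with the trial-by-trial [run_sequence()]
#' is part of the test suite.
#'
#' @param trials Cohort trial table (multiple participants allowed).
#' @param reset_per_block Accumulate within blocks only?
#' @inheritParams run_sequence
#' @return Data frame keyed by (\code{participant_id}, \code{block_index})
#'   with columns \code{task}, \code{n_fb_cor}, \code{n_fb_inc},
#'   \code{s_conf}, \code{s_inv}.
#' @export
block_sufstats <- function(trials, reset_per_block = FALSE,
                           conf_transform = c("none", "rank")) {
  conf_transform <- match.arg(conf_transform)
  conf <- trials$confidence
  if (conf_transform == "rank") {
    for (pid in unique(trials$participant_id)) {
      i <- trials$participant_id == pid
      conf[i] <- rank_to_unit(conf[i])
    }
  }
  fb <- trials$feedback != "none"
  inc_acor <- as.numeric(fb & trials$feedback == "correct_shown")
  inc_binc <- as.numeric(fb & trials$feedback == "incorrect_shown")
  inc_sc <- ifelse(fb, 0, conf)
  inc_si <- ifelse(fb, 0, 1 - conf)

  key <- interaction(trials$participant_id, trials$block_index, drop = TRUE,
                     lex.order = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, sum))
  idx1 <- match(levels(key), as.character(key))  # first trial of each block
  out <- data.frame(
    participant_id = trials$participant_id[idx1],
    block_index = trials$block_index[idx1],
    task = trials$task[idx1],
    n_fb_cor = agg(inc_acor),
    n_fb_inc = agg(inc_binc),
    s_conf = agg(inc_sc),
    s_inv = agg(inc_si),
    stringsAsFactors = FALSE)

  if (!reset_per_block) {
    sp <- split(seq_len(nrow(out)), out$participant_id)
    for (rows in sp) {
      tk <- split(rows, out$task[rows])
      for (rr in tk) {
        out$n_fb_cor[rr] <- cumsum(out$n_fb_cor[rr])
        out$n_fb_inc[rr] <- cumsum(out$n_fb_inc[rr])
        out$s_conf[rr] <- cumsum(out$s_conf[rr])
        out$s_inv[rr] <- cumsum(out$s_inv[rr])
      }
    }
  }
  rownames(out) <- NULL
  out
}
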