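#' Baseline-correct block-level measures
#'
#' Subtracts each participant's baseline-block mean (per task) from the
#' block SPE, mean confidence and mean accuracy, yielding zero-centred
#' columns \code{spe_bc}, \code{confidence_bc}, \code{accuracy_bc} bounded
#' in [-1, 1].
#'
#' @param blocks Block table with \code{participant_id}, \code{task},
#'   \code{phase}, \code{spe}, \code{confidence_mean}, \code{accuracy_mean}.
#' @return The block table with the three corrected columns appended.
#' @export
baseline_correct <- function(blocks) {
  need <- c("participant_id", "task", "phase", "spe", "confidence_mean",
            "accuracy_mean")
  stopifnot(all(need %in% names(blocks)))
  key <- paste(blocks$participant_id, blocks$task)
  base <- blocks$phase == "baseline"
  if (!all(key %in% unique(key[base])))
    stop("missing baseline blocks for some participant/task combinations")
  bmean <- function(v) {
    m <- tapply(v[base], key[base], mean)
    as.numeric(m[key])
  }
  blocks$spe_bc <- blocks$spe - bmean(blocks$spe)
  blocks$confidence_bc <- blocks$confidence_mean - bmean(blocks$confidence_mean)
  blocks$accuracy_bc <- blocks$accuracy_mean - bmean(blocks$accuracy_mean)
  blocks
}

#' Within-participant z-scoring
#'
#' Standardises a measure to mean 0, SD 1 within each participant.
#' Participants with fewer than two distinct values cannot be standardised;
#' their values are set to NA, their ids recorded in
#' \code{attr(, "degenerate_participants")}, and a warning is raised (they
#' are flagged, never silently zeroed).
#'
#' @param x Numeric vector (e.g. confidence).
#' @param participant Parallel vector of participant ids.
#' @return Numeric vector of z-scores with the degenerate-participant
#'   attribute.
#' @export
zscore_within <- function(x, participant) {
  stopifnot(length(x) == length(participant))
  out <- x
  degenerate <- character(0)
  for (pid in unique(participant)) {
    i <- participant == pid
    if (length(unique(x[i])) < 2) {
      out[i] <- NA_real_
      degenerate <- c(degenerate, as.character(pid))
    } else {
      out[i] <- (x[i] - mean(x[i])) / stats::sd(x[i])
    }
  }
  if (length(degenerate))
    warning("constant values for participant(s) ",
            paste(degenerate, collapse = ", "), "; set to NA")
  attr(out, "degenerate_participants") <- degenerate
  out
}

#' Global SPE by confidence quantile and symptom tertile
#'
#' Mirrors the construction behind the headline descriptive figure:
#' confidence is z-scored within participant and split into k quantile
#' bins per participant; each trial inherits the SPE of its block; mean
#' SPEs are summarised per symptom-score tertile x confidence quantile,
#' with cluster-bootstrap CIs (resampling participants). Quantile centres
#' are the within-quantile mean z-scored confidence averaged across
#' participants. Rank-based binning makes the summary invariant to any
#' strictly monotone within-participant transform of confidence.
#'
#' @param trials,blocks,profiles Cohort tables.
#' @param k Number of within-participant confidence quantiles.
#' @param tertiles Which tertiles to keep (default lowest and highest).
#' @param n_boot Bootstrap resamples for the CIs.
#' @param conf_level CI level.
#' @return Data frame: \code{mh_tertile}, \code{quantile}, \code{center}
#'   (mean z-scored confidence), \code{mean_spe}, \code{ci_lo},
#'   \code{ci_hi}, \code{n_participants}.
#' @export
confidence_quantile_summary <- function(trials, blocks, profiles, k = 4,
                                        tertiles = c(1, 3), n_boot = 1000,
                                        conf_level = 0.95) {
  d <- quantile_trial_frame(trials, blocks, profiles, k)
  if (length(unique(d$participant_id)) < 3)
    stop("need at least 3 participants to form symptom tertiles")
  pids <- unique(d$participant_id)
  cell_means <- function(dd) {
    agg <- stats::aggregate(cbind(spe, confz) ~ mh_tertile + quantile,
                            data = dd, FUN = mean)
    agg
  }
  full <- cell_means(d)
  alpha <- (1 - conf_level) / 2
  boot <- array(NA_real_, c(n_boot, nrow(full)))
  split_p <- split(seq_len(nrow(d)), d$participant_id)
  for (bidx in seq_len(n_boot)) {
    take <- sample(pids, length(pids), replace = TRUE)
    dd <- d[unlist(split_p[as.character(take)], use.names = FALSE), ]
    bm <- cell_means(dd)
    m <- match(paste(full$mh_tertile, full$quantile),
               paste(bm$mh_tertile, bm$quantile))
    boot[bidx, ] <- bm$spe[m]
  }
  np <- tapply(d$participant_id, d$mh_tertile,
               function(z) length(unique(z)))
  out <- data.frame(
    mh_tertile = full$mh_tertile, quantile = full$quantile,
    center = full$confz, mean_spe = full$spe,
    ci_lo = apply(boot, 2, stats::quantile, alpha, na.rm = TRUE),
    ci_hi = apply(boot, 2, stats::quantile, 1 - alpha, na.rm = TRUE),
    n_participants = as.numeric(np[as.character(full$mh_tertile)]),
    stringsAsFactors = FALSE)
  out[out$mh_tertile %in% tertiles, ]
}

# trial frame with confz, within-participant quantile bin, block SPE and
# participant mh tertile
quantile_trial_frame <- function(trials, blocks, profiles, k = 4) {
  confz <- zscore_within(trials$confidence, trials$participant_id)
  spe <- blocks$spe[match(paste(trials$participant_id, trials$block_index),
                          paste(blocks$participant_id, blocks$block_index))]
  mh <- profiles$mh_score[match(trials$participant_id,
                                profiles$participant_id)]
  qs <- stats::quantile(profiles$mh_score, c(1 / 3, 2 / 3))
  tert <- 1L + (mh > qs[1]) + (mh > qs[2])
  d <- data.frame(participant_id = trials$participant_id, confz = confz,
                  spe = spe, correct = as.numeric(trials$correct),
                  mh = mh, mh_tertile = tert)
  d <- d[!is.na(d$confz), ]
  d$quantile <- NA_integer_
  for (pid in unique(d$participant_id)) {
    i <- d$participant_id == pid
    r <- rank(d$confz[i], ties.method = "first")
    d$quantile[i] <- as.integer(ceiling(r * k / sum(i)))
  }
  d
}

#' Slope of SPE over the high-confidence quantiles, per symptom tertile
#'
#' Least-squares slope of trial-level block SPE on the z-scored confidence
#' quantile centre, restricted to quantiles whose centre is positive (the
#' high-confidence side, where blunting is expected to show).
#'
#' @inheritParams confidence_quantile_summary
#' @return Named numeric of slopes, one per requested tertile.
#' @export
high_confidence_slopes <- function(trials, blocks, profiles, k = 4,
                                   tertiles = c(1, 3)) {
  d <- quantile_trial_frame(trials, blocks, profiles, k)
  centers <- stats::aggregate(confz ~ quantile, data = d, FUN = mean)
  d$center <- centers$confz[match(d$quantile, centers$quantile)]
  out <- stats::setNames(numeric(length(tertiles)), paste0("tertile", tertiles))
  for (i in seq_along(tertiles)) {
    dd <- d[d$mh_tertile == tertiles[i] & d$center > 0, ]
    out[i] <- stats::coef(stats::lm(spe ~ center, data = dd))[["center"]]
  }
  out
}

#' Fixed-effects interaction diagnostics
#'
#' Simplified fixed-effects analogues of the study's two key mixed-model
#' tests, with participant fixed effects absorbed by within-participant
#' demeaning and cluster-bootstrap CIs over participants:
#' \enumerate{
#'   \item \code{confz ~ spe * mh + accuracy} on trials with z-scored
#'     confidence > 0: the \code{spe:mh} coefficient is the
#'     confidence-distortion diagnostic (negative under blunting).
#'   \item \code{spe_z ~ feedback * mh} on blocks, contrasting positive
#'     (and separately negative) feedback blocks against no-feedback
#'     blocks: the \code{feedback:mh} coefficients are the
#'     feedback-distortion diagnostics.
#' }
#' These are deliberate approximations of the random-effects originals;
#' they preserve the interaction contrasts but not the exact standard
#' errors of a mixed model.
#'
#' @param trials,blocks,profiles Cohort tables.
#' @param n_boot Cluster-bootstrap resamples.
#' @param conf_level CI level.
#' @return Data frame with \code{term}, \code{estimate}, \code{ci_lo},
#'   \code{ci_hi}.
#' @export
interaction_tests <- function(trials, blocks, profiles, n_boot = 200,
                              conf_level = 0.95) {
  d <- quantile_trial_frame(trials, blocks, profiles)
  d <- d[d$confz > 0, ]
  conf_est <- function(dd) {
    y <- demean_by(dd$confz, dd$participant_id)
    x1 <- demean_by(dd$spe, dd$participant_id)
    x2 <- demean_by(dd$spe * dd$mh, dd$participant_id)
    x3 <- demean_by(dd$correct, dd$participant_id)
    stats::coef(stats::lm(y ~ 0 + x1 + x2 + x3))[["x2"]]
  }

  bz <- blocks
  bz$mh <- profiles$mh_score[match(bz$participant_id,
                                   profiles$participant_id)]
  bz$spe_z <- zscore_within(bz$spe, bz$participant_id)
  fb_est <- function(bb, valence) {
    dd <- bb[bb$feedback_valence %in% c("none", valence), ]
    dd$fb <- as.numeric(dd$feedback_valence == valence)
    y <- demean_by(dd$spe_z, dd$participant_id)
    x1 <- demean_by(dd$fb, dd$participant_id)
    x2 <- demean_by(dd$fb * dd$mh, dd$participant_id)
    stats::coef(stats::lm(y ~ 0 + x1 + x2))[["x2"]]
  }

  ests <- c(spe_x_mh = conf_est(d),
            fb_pos_x_mh = fb_est(bz, "positive"),
            fb_neg_x_mh = fb_est(bz, "negative"))
  boot <- matrix(NA_real_, n_boot, 3)
  pids <- unique(profiles$participant_id)
  dsplit <- split(seq_len(nrow(d)), d$participant_id)
  bsplit <- split(seq_len(nrow(bz)), bz$participant_id)
  for (bidx in seq_len(n_boot)) {
    take <- as.character(sample(pids, length(pids), replace = TRUE))
    di <- d[unlist(dsplit[take], use.names = FALSE), ]
    # resampled participants must stay distinct clusters for demeaning
    di$participant_id <- rep(seq_along(take),
                             lengths(dsplit[take]))
    bi <- bz[unlist(bsplit[take], use.names = FALSE), ]
    bi$participant_id <- rep(seq_along(take), lengths(bsplit[take]))
    boot[bidx, ] <- tryCatch(
      c(conf_est(di), fb_est(bi, "positive"), fb_est(bi, "negative")),
      error = function(e) rep(NA_real_, 3))
  }
  alpha <- (1 - conf_level) / 2
  data.frame(
    term = names(ests), estimate = unname(ests),
    ci_lo = apply(boot, 2, stats::quantile, alpha, na.rm = TRUE),
    ci_hi = apply(boot, 2, stats::quantile, 1 - alpha, na.rm = TRUE),
    stringsAsFactors = FALSE)
}

demean_by <- function(x, g) {
  m <- tapply(x, g, mean)
  x - as.numeric(m[as.character(g)])
}
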