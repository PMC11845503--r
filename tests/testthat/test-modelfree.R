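test_that("baseline correction zero-centres each participant's task baseline", {
  bl <- data.frame(
    participant_id = rep(1:2, each = 3),
    task = "perception",
    phase = rep(c("baseline", "baseline", "intervention"), 2),
    spe = c(0.6, 0.8, 0.8, 0.2, 0.4, 1.0),
    confidence_mean = c(0.5, 0.5, 0.7, 0.6, 0.6, 0.6),
    accuracy_mean = c(0.7, 0.7, 0.7, 0.75, 0.65, 0.9),
    stringsAsFactors = FALSE)
  out <- baseline_correct(bl)
  expect_equal(out$spe_bc[3], 0.8 - 0.7)
  # baseline rows average to zero within each participant
  expect_equal(as.numeric(tapply(out$spe_bc[out$phase == "baseline"],
                                 out$participant_id[out$phase == "baseline"],
                                 mean)),
               c(0, 0))
  expect_true(all(out$spe_bc >= -1 & out$spe_bc <= 1))
  # extreme case: SPE 1.0 against a 0.0 baseline stays inside the bounds
  bl2 <- bl
  bl2$spe <- c(0, 0, 1, 0, 0, 1)
  expect_equal(baseline_correct(bl2)$spe_bc[3], 1)
  bl$phase <- "test"
  expect_error(baseline_correct(bl), "baseline")
})

test_that("within-participant z-scores have mean zero and unit variance", {
  z <- zscore_within(c(0.2, 0.4, 0.6), rep(1, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  x <- stats::runif(30)
  z <- zscore_within(x, rep(1:3, each = 10))
  for (g in 1:3) {
    expect_equal(mean(z[rep(1:3, each = 10) == g]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z[rep(1:3, each = 10) == g]), 1, tolerance = 1e-12)
  }
  # constant participants are flagged and excluded, not silently zeroed
  expect_warning(
    z2 <- zscore_within(c(0.5, 0.5, 0.1, 0.9), c(1, 1, 2, 2)),
    "constant")
  expect_true(all(is.na(z2[1:2])))
  expect_equal(attr(z2, "degenerate_participants"), "1")
})

test_that("confidence quantiles are balanced within participant", {
  co <- tiny_cohort()
  d <- betaspe:::quantile_trial_frame(co$trials, co$blocks, co$profiles, k = 4)
  for (pid in unique(d$participant_id)) {
    tab <- table(d$quantile[d$participant_id == pid])
    expect_equal(length(tab), 4L)
    expect_lt(diff(range(tab)), 2)  # equal-probability bins up to rounding
  }
  # 8 values per participant with k = 4 gives exactly 2 per bin
  toy_tr <- data.frame(participant_id = rep(1:3, each = 8),
                       block_index = rep(1:4, 6),
                       confidence = stats::runif(24),
                       correct = TRUE)
  toy_bl <- expand.grid(participant_id = 1:3, block_index = 1:4)
  toy_bl$spe <- stats::runif(nrow(toy_bl))
  toy_pf <- data.frame(participant_id = 1:3, mh_score = c(2, 10, 20))
  d2 <- betaspe:::quantile_trial_frame(toy_tr, toy_bl, toy_pf, k = 4)
  expect_true(all(table(d2$participant_id, d2$quantile) == 2))
})

test_that("quantile summary is invariant to monotone confidence transforms", {
  co <- tiny_cohort()
  s1 <- confidence_quantile_summary(co$trials, co$blocks, co$profiles,
                                    n_boot = 10)
  tr2 <- co$trials
  tr2$confidence <- tr2$confidence^3  # strictly monotone distortion
  s2 <- confidence_quantile_summary(tr2, co$blocks, co$profiles, n_boot = 10)
  expect_equal(s1$mean_spe, s2$mean_spe, tolerance = 1e-12)
  expect_equal(s1$n_participants, s2$n_participants)
})

test_that("bootstrap CIs bracket the cell means and shrink with participants", {
  co <- d1_cohort()
  set.seed(41)
  s <- confidence_quantile_summary(co$trials, co$blocks, co$profiles,
                                   n_boot = 200)
  expect_true(all(s$ci_lo <= s$mean_spe & s$mean_spe <= s$ci_hi))
  expect_true(all(s$mh_tertile %in% c(1, 3)))
  expect_equal(nrow(s), 8L)

  set.seed(42)
  co_big <- simulate_cohort(96, seed = 2,
                            params = model_params(dlr_f0 = 0.1, dlr_c0 = 0.1,
                                                  beta_c = -0.03),
                            spec = distortion_spec("D1"))
  s_big <- confidence_quantile_summary(co_big$trials, co_big$blocks,
                                       co_big$profiles, n_boot = 200)
  expect_lt(mean(s_big$ci_hi - s_big$ci_lo), mean(s$ci_hi - s$ci_lo))
})

test_that("interaction diagnostics are near zero without planted interactions", {
  co <- simulate_cohort(60, seed = 51, conf_bias_per_mh = 0,
                        params = model_params(dlr_f0 = 0.1, dlr_c0 = 0.1))
  set.seed(52)
  it <- interaction_tests(co$trials, co$blocks, co$profiles, n_boot = 120)
  expect_equal(nrow(it), 3L)
  for (i in 1:3) {
    expect_lte(it$ci_lo[i], 0)
    expect_gte(it$ci_hi[i], 0)
  }
})
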