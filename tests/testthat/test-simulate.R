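test_that("cohort simulation is a pure function of its seed", {
  a <- simulate_cohort(8, seed = 123)
  b <- simulate_cohort(8, seed = 123)
  expect_identical(a$trials, b$trials)
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$profiles, b$profiles)
  c2 <- simulate_cohort(8, seed = 124)
  expect_false(identical(a$trials$confidence, c2$trials$confidence))
})

test_that("participant child streams make subsets reproducible", {
  big <- simulate_cohort(16, seed = 9)
  small <- simulate_cohort(8, seed = 9)
  expect_identical(small$trials,
                   big$trials[big$trials$participant_id <= 8, ])
  expect_identical(small$profiles$mh_score, big$profiles$mh_score[1:8])
})

test_that("simulated cohorts respect the design invariants", {
  co <- tiny_cohort()
  expect_true(all(co$trials$feedback[co$trials$phase != "intervention"]
                  == "none"))
  expect_true(all(co$trials$confidence >= 0 & co$trials$confidence <= 1))
  expect_true(all(co$blocks$spe > 0 & co$blocks$spe < 1))
  expect_true(all(co$profiles$mh_score >= 0 & co$profiles$mh_score <= 21))
  expect_equal(sort(unique(co$profiles$group_id)), 1:8)
  counts <- table(co$trials$participant_id)
  expect_true(all(counts == 240))
  ex2 <- simulate_cohort(8, experiment = "exp2", seed = 10)
  expect_true(all(table(ex2$trials$participant_id) == 200))
  expect_equal(nrow(validate_dataset(co$trials, co$blocks, co$profiles)), 0L)
})

test_that("exact-quota mode plants 9 + 1 feedback events per intervention block", {
  co <- simulate_cohort(8, seed = 31, exact_quota = TRUE)
  iv <- co$trials[co$trials$phase == "intervention", ]
  key <- paste(iv$participant_id, iv$block_index)
  for (k in unique(key)) {
    blk <- iv[key == k, ]
    ncs <- sum(blk$feedback == "correct_shown")
    nis <- sum(blk$feedback == "incorrect_shown")
    if (blk$feedback_valence[1] == "positive") {
      expect_equal(ncs, min(9, sum(blk$correct)))
      expect_equal(nis, min(1, sum(!blk$correct)))
    } else {
      expect_equal(ncs, min(1, sum(blk$correct)))
      expect_equal(nis, min(9, sum(!blk$correct)))
    }
  }
})

test_that("cohort accuracy tracks the staircase target", {
  co <- d1_cohort()
  acc <- mean(co$trials$correct)
  expect_gt(acc, 0.67)
  expect_lt(acc, 0.75)
})

test_that("pooled expected intervention feedback counts scale with the samples", {
  # two intervention blocks of 40 trials, 10 expected events each
  per_block <- sum(expected_feedback_counts(40, 0.71, "positive"))
  expect_equal(per_block, 10, tolerance = 1e-12)
  expect_equal(230 * 2 * per_block, 4600)
  expect_equal(278 * 2 * per_block, 5560)
})

test_that("confidence declines with symptom load through the bias pathway", {
  co <- simulate_cohort(60, seed = 17)
  m <- tapply(co$trials$confidence, co$trials$participant_id, mean)
  mh <- co$profiles$mh_score[match(names(m), co$profiles$participant_id)]
  expect_lt(cor(mh, m), -0.5)
})

test_that("a null model plants no SPE-symptom association beyond confidence bias", {
  co <- simulate_cohort(60, seed = 18, conf_bias_per_mh = 0)
  m <- tapply(co$blocks$spe, co$blocks$participant_id, mean)
  mh <- co$profiles$mh_score[match(names(m), co$profiles$participant_id)]
  expect_gt(stats::cor.test(mh, m)$p.value, 0.01)
})
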