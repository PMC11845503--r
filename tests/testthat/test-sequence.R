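make_block <- function(task, block, n, conf, correct, feedback) {
  data.frame(participant_id = 1, task = task, block_index = block,
             trial_index = seq_len(n), correct = correct, confidence = conf,
             feedback = feedback, stringsAsFactors = FALSE)
}

test_that("all-feedback blocks reduce to Beta-Bernoulli conjugacy", {
  set.seed(5)
  correct <- stats::runif(30) < 0.7
  tr <- make_block("perception", 1, 30, conf = 0.5, correct = correct,
                   feedback = ifelse(correct, "correct_shown",
                                     "incorrect_shown"))
  p <- model_params(mu0 = 0.6, v0 = 0.02)
  st0 <- init_belief(0.6, 0.02)
  out <- run_sequence(tr, p)
  expect_equal(out$a, st0$a + sum(correct))
  expect_equal(out$b, st0$b + sum(!correct))
  expect_equal(out$mu,
               (st0$a + sum(correct)) / (st0$a + st0$b + 30), tolerance = 1e-12)
})

test_that("constant-confidence no-feedback blocks pull the mean to the confidence", {
  cval <- 0.8
  tr <- make_block("memory", 1, 4000, conf = cval, correct = TRUE,
                   feedback = "none")
  out <- run_sequence(tr, model_params(mu0 = 0.4, v0 = 0.02))
  expect_equal(out$mu, cval, tolerance = 0.005)
})

test_that("the symmetric special case reproduces the baseline recursion exactly", {
  co <- tiny_cohort()
  p <- model_params(mu0 = 0.7, v0 = 0.015)
  st0 <- init_belief(0.7, 0.015)
  for (pid in c(1, 4, 7)) {
    tr <- co$trials[co$trials$participant_id == pid, ]
    out <- run_sequence(tr, p, distortion_spec("D0"), mh = 9)
    # oracle accumulates unit/confidence pseudo-counts per task
    for (task in unique(tr$task)) {
      ref <- baseline_oracle(tr[tr$task == task, ], st0$a, st0$b)
      last <- max(out$block_index[out$task == task])
      expect_equal(out$a[out$block_index == last], unname(ref["a"]))
      expect_equal(out$b[out$block_index == last], unname(ref["b"]))
    }
  }
})

test_that("block-final mean rises with both asymmetries (finite differences)", {
  set.seed(6)
  conf <- stats::runif(40, 0.2, 0.9)
  correct <- stats::runif(40) < 0.7
  fb <- ifelse(seq_len(40) %% 4 == 0,
               ifelse(correct, "correct_shown", "incorrect_shown"), "none")
  tr <- make_block("perception", 1, 40, conf, correct, fb)
  mu_at <- function(f0, c0) {
    p <- model_params(dlr_f0 = f0, dlr_c0 = c0)
    run_sequence(tr, p)$mu
  }
  for (d in seq(-0.8, 0.7, by = 0.3)) {
    expect_gt(mu_at(d + 0.1, 0), mu_at(d, 0))
    expect_gt(mu_at(0, d + 0.1), mu_at(0, d))
  }
})

test_that("closed-form sufficient statistics match the trial-by-trial recursion", {
  co <- d1_cohort()
  p <- model_params(mu0 = c(perception = 0.65, memory = 0.72),
                    v0 = c(perception = 0.02, memory = 0.012),
                    dlr_f0 = 0.25, dlr_c0 = -0.15)
  for (reset in c(FALSE, TRUE)) {
    ss <- block_sufstats(co$trials, reset_per_block = reset)
    for (pid in c(2, 9, 16)) {
      tr <- co$trials[co$trials$participant_id == pid, ]
      out <- run_sequence(tr, p, reset_per_block = reset)
      ssp <- ss[ss$participant_id == pid, ]
      ssp <- ssp[order(ssp$block_index), ]
      for (i in seq_len(nrow(ssp))) {
        task <- ssp$task[i]
        st0 <- init_belief(p$mu0[[task]], p$v0[[task]])
        a <- st0$a + ssp$n_fb_cor[i] * (1 + 0.25) + ssp$s_conf[i] * (1 - 0.15)
        b <- st0$b + ssp$n_fb_inc[i] * (1 - 0.25) + ssp$s_inv[i] * (1 + 0.15)
        expect_equal(out$a[out$block_index == ssp$block_index[i]], a,
                     tolerance = 1e-10)
        expect_equal(out$b[out$block_index == ssp$block_index[i]], b,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("rank-transformed confidence agrees between the two routes", {
  co <- tiny_cohort()
  # participant 1 sits in the all-perception group, so block 6 is perception
  tr <- co$trials[co$trials$participant_id == 1, ]
  p <- model_params(dlr_c0 = 0.2)
  out <- run_sequence(tr, p, conf_transform = "rank")
  ss <- block_sufstats(co$trials, conf_transform = "rank")
  ssp <- ss[ss$participant_id == 1, ]
  st0 <- init_belief(p$mu0[["perception"]], p$v0[["perception"]])
  i <- which(ssp$block_index == 6)
  expect_equal(out$a[out$block_index == 6],
               st0$a + ssp$n_fb_cor[i] * 1 + ssp$s_conf[i] * 1.2,
               tolerance = 1e-10)
})

test_that("unordered or mislabelled trial streams are rejected", {
  tr <- make_block("perception", 1, 5, 0.5, TRUE, "none")
  expect_error(run_sequence(tr[5:1, ], model_params()), "ordered")
  tr$task <- "gustation"
  expect_error(run_sequence(tr, model_params()), "task")
})

test_that("positivity holds along admissible update paths", {
  set.seed(8)
  for (rep in 1:5) {
    st <- init_belief(stats::runif(1, 0.1, 0.9), 0.01)
    dlr_f <- stats::runif(1, -0.98, 0.98)
    dlr_c <- stats::runif(1, -0.98, 0.98)
    for (i in 1:50) {
      st <- if (stats::runif(1) < 0.3)
        update_feedback(st, stats::runif(1) < 0.5, dlr_f)
      else
        update_confidence(st, stats::runif(1), dlr_c)
      expect_gt(st$a, 0)
      expect_gt(st$b, 0)
    }
  }
})
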