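test_that("initial belief maps mean/variance to Beta shapes and back", {
  st <- init_belief(0.5, 0.05)
  expect_equal(st$a, 2)
  expect_equal(st$b, 2)

  # algebraic round trip over a grid of admissible (mu0, v0)
  for (mu0 in c(0.2, 0.5, 0.7, 0.9)) {
    for (v0 in c(0.25, 0.6) * mu0 * (1 - mu0)) {
      st <- init_belief(mu0, v0)
      m <- st$a / (st$a + st$b)
      v <- st$a * st$b / ((st$a + st$b)^2 * (st$a + st$b + 1))
      expect_equal(m, mu0, tolerance = 1e-12)
      expect_equal(v, v0, tolerance = 1e-12)
      expect_gt(st$a, 0)
      expect_gt(st$b, 0)
    }
  }

  expect_error(init_belief(0.5, 0.3), "bound")
  expect_error(init_belief(0.5, 0.25), "bound")
  expect_error(init_belief(1, 0.01), "inside")
})

test_that("feedback updates increment one shape by an asymmetric unit", {
  st <- belief_state(1, 1)
  expect_equal(unclass(update_feedback(st, TRUE, 0))[c("a", "b")],
               list(a = 2, b = 1))
  expect_equal(unclass(update_feedback(st, TRUE, 0.5))[c("a", "b")],
               list(a = 2.5, b = 1))
  expect_equal(unclass(update_feedback(st, FALSE, 0.5))[c("a", "b")],
               list(a = 1, b = 1.5))
  expect_error(update_feedback(st, TRUE, 1), "-1, 1")
})

test_that("confidence updates split an asymmetry-weighted pseudo-count", {
  st <- belief_state(1, 1)
  up <- update_confidence(st, 0.75, 0)
  expect_equal(c(up$a, up$b), c(1.75, 1.25))
  up <- update_confidence(st, 0.5, 0.4)
  expect_equal(c(up$a, up$b), c(1.7, 1.3))
  expect_error(update_confidence(st, 1.2, 0), "0, 1")

  # total increment identity: delta(a) + delta(b) = 1 + dlr_c * (2c - 1)
  for (conf in c(0, 0.25, 0.8, 1)) {
    for (dlr in c(-0.6, 0, 0.3)) {
      up <- update_confidence(st, conf, dlr)
      expect_equal((up$a - st$a) + (up$b - st$b),
                   1 + dlr * (2 * conf - 1), tolerance = 1e-12)
    }
  }
})

test_that("belief mean and biased SPE prediction behave as a Beta mean", {
  expect_equal(belief_mean(belief_state(9, 3)), 0.75)
  for (a in c(0.5, 2, 40)) expect_equal(belief_mean(belief_state(a, a)), 0.5)
  expect_gt(belief_mean(belief_state(5, 3)), belief_mean(belief_state(4, 3)))
  expect_lt(belief_mean(belief_state(5, 4)), belief_mean(belief_state(5, 3)))

  p <- model_params(beta_a = -0.005)
  st <- belief_state(6, 4)  # mean 0.6
  expect_equal(predicted_spe(st, p, distortion_spec("D3"), mh = 20), 0.5)
  expect_equal(predicted_spe(st, p, distortion_spec("D0"), mh = 20), 0.6)
  # clipping keeps the prediction a proportion
  expect_gt(predicted_spe(st, model_params(beta_a = -0.1),
                          distortion_spec("D3"), mh = 21), 0)
})

test_that("SPE log-likelihood is a proper Beta log-density", {
  expect_equal(spe_loglik(0.3, belief_state(1, 1)), 0)
  expect_equal(spe_loglik(0.9, belief_state(1, 1)), 0)
  # symmetric belief: maximised at 0.5
  ll <- spe_loglik(seq(0.05, 0.95, by = 0.05), belief_state(4, 4))
  expect_equal(which.max(ll), 10L)
  # integrates to 1 (quadrature oracle, independent of dbeta's normaliser)
  dens <- function(x) exp(spe_loglik(x, belief_state(3.7, 1.9)))
  expect_equal(stats::integrate(dens, 0, 1)$value, 1, tolerance = 1e-6)
  expect_error(spe_loglik(1, belief_state(2, 2)), "boundary")
})

test_that("boundary transform compresses proportions into (0, 1)", {
  x <- c(0, 0.25, 1)
  y <- spe_boundary_transform(x)
  expect_true(all(y > 0 & y < 1))
  expect_equal(y, (x * 2 + 0.5) / 3)
  # large n leaves interior values nearly untouched
  expect_equal(spe_boundary_transform(0.4, n = 1e6), 0.4, tolerance = 1e-5)
})

test_that("symptom regressions gate slopes by distortion variant", {
  p <- model_params(dlr_f0 = 0.1, dlr_c0 = 0.2, beta_c = -0.03, beta_f = 0.01)
  d1 <- effective_asymmetries(p, distortion_spec("D1"), mh = 10)
  expect_equal(unname(d1["dlr_c"]), 0.2 - 0.3)
  expect_equal(unname(d1["dlr_f"]), 0.1)  # beta_f forced to zero under D1
  d0 <- effective_asymmetries(p, distortion_spec("D0"), mh = 17)
  expect_equal(unname(d0), c(0.1, 0.2))
  # negative slope: strictly decreasing in mh until the clip
  vals <- vapply(0:21, function(m)
    effective_asymmetries(p, distortion_spec("D1"), m)[["dlr_c"]], 0)
  expect_true(all(diff(vals) < 0))
  expect_true(all(abs(vals) < 1))
  # clipping engages for extreme slopes
  px <- model_params(beta_c = -0.2)
  expect_equal(
    effective_asymmetries(px, distortion_spec("D1"), 21)[["dlr_c"]], -0.99)
})

test_that("distortion variants free the documented slope sets", {
  frees <- t(vapply(paste0("D", 0:6),
                    function(v) distortion_spec(v)$free, logical(3)))
  expect_equal(rowSums(frees), c(D0 = 0, D1 = 1, D2 = 1, D3 = 1, D4 = 2,
                                 D5 = 2, D6 = 2))
  expect_true(frees["D1", "beta_c"] && !frees["D1", "beta_f"])
  expect_true(frees["D2", "beta_f"] && !frees["D2", "beta_c"])
  expect_true(frees["D3", "beta_a"])
  expect_error(distortion_spec("D7"))
})

test_that("base-model space enumerates the five sharing structures", {
  bm <- base_model_variants()
  expect_equal(nrow(bm), 5L)
  expect_equal(bm$n_dlr[bm$label == "split_both"], 4L)
  expect_equal(bm$n_dlr[bm$label == "zero"], 0L)
  expect_equal(sort(bm$n_dlr), c(0L, 1L, 2L, 2L, 4L))
})
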