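# Shared small fixtures, built once per test run.

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- simulate_cohort(8, seed = 1)
  .fixture_env$tiny
}

# 24 participants, D1 ground truth; reused by inference/modelfree tests
d1_cohort <- function() {
  if (is.null(.fixture_env$d1))
    .fixture_env$d1 <- simulate_cohort(
      24, seed = 2,
      params = model_params(dlr_f0 = 0.1, dlr_c0 = 0.1, beta_c = -0.03),
      spec = distortion_spec("D1"))
  .fixture_env$d1
}

.fixture_env <- new.env(parent = emptyenv())

# independent trial-by-trial oracle for the symmetric baseline updates:
# unit pseudo-counts on feedback trials, confidence pseudo-counts otherwise
baseline_oracle <- function(trials, a0, b0) {
  a <- a0; b <- b0
  for (i in seq_len(nrow(trials))) {
    if (trials$feedback[i] == "correct_shown") a <- a + 1
    else if (trials$feedback[i] == "incorrect_shown") b <- b + 1
    else {
      a <- a + trials$confidence[i]
      b <- b + (1 - trials$confidence[i])
    }
  }
  c(a = a, b = b)
}
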