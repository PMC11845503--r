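# betaspe

Beta-belief modelling of **global self-performance estimates (SPEs)** —
how people judge "how well did I do on that block?" from their
trial-by-trial local confidence and from occasional, valence-rigged
performance feedback, and how anxious-depression symptom load distorts
that judgement.

The package is aimed at computational-psychiatry and metacognition
researchers who want a fully simulatable, fittable and testable version
of this pipeline: a study-design simulator, the generative belief model,
group-level Bayesian fitting with model comparison, recovery harnesses,
and model-free diagnostics.

## The model

Each task carries a Beta(a, b) belief over expected success, initialised
from a mean and variance (μ₀, v₀):

    a₀ = (μ₀ / v₀)(μ₀ − μ₀² − v₀),   b₀ = ((1 − μ₀) / v₀)(μ₀ − μ₀² − v₀).

On feedback trials the belief updates asymmetrically by valence
(ΔLR_f ∈ (−1, 1)):

    shown correct:    a ← a + (1 + ΔLR_f)
    shown incorrect:  b ← b + (1 − ΔLR_f)

On no-feedback trials the local confidence report conf ∈ [0, 1] stands in
for the outcome, with its own asymmetry ΔLR_c:

    a ← a + conf·(1 + ΔLR_c),   b ← b + (1 − conf)·(1 − ΔLR_c)

and the end-of-block SPE is a draw from the block-final belief,
SPE_B ~ Beta(a_n, b_n). A symptom score MH enters through regressions

    ΔLR_f = ΔLR_f0 + β_f·MH,  ΔLR_c = ΔLR_c0 + β_c·MH,  SPE_B = μ_n + β_a·MH,

and the variants **D0–D6** cross which of β_c (confidence distortion),
β_f (feedback distortion), β_a (response bias) are free. A negative β_c
— blunted updating from one's own high-confidence moments — is the
mechanism of interest for persistent underconfidence.

Fitting is group-level MCMC (adaptive random-walk Metropolis over
closed-form sufficient statistics of the belief recursion), with DIC
model comparison, highest-density intervals and split-chain R-hat
diagnostics.

## Worked example

Simulate a 60-participant cohort whose ground truth is a confidence
distortion (β_c = −0.03 per symptom unit on a 0–21 scale), refit it, and
compare variants:

```r
library(betaspe)

truth  <- model_params(dlr_f0 = 0.1, dlr_c0 = 0.1, beta_c = -0.03)
cohort <- simulate_cohort(60, seed = 42, params = truth,
                          spec = distortion_spec("D1"))
cohort
#> <spe_cohort> exp1: 60 participants, 14400 trials, 360 blocks (D1)

fit <- fit_model(cohort$trials, cohort$blocks, cohort$profiles,
                 spec = distortion_spec("D1"),
                 config = mcmc_config(profile = "full", seed = 1))
fit
#> <spe_fit> variant D1, 3000 draws (3 chains), 360 observations
#>   DIC = -1217.93 (p_D = 6.43), converged: TRUE
#>        parameter     mean       sd hdi95_lo hdi95_hi  hdi99_lo hdi99_hi  rhat
#> 1 mu0_perception  0.70328 0.070923  0.59153  0.87027  0.565683  0.90024 1.029
#> 2     mu0_memory  0.70114 0.059761  0.58915  0.81486  0.578405  0.86967 1.013
#> 3  v0_perception  0.01600 0.003048  0.01101  0.02254  0.009837  0.02457 1.016
#> 4      v0_memory  0.01594 0.002886  0.01052  0.02145  0.010051  0.02548 1.010
#> 5         dlr_f0  0.12281 0.084610 -0.02470  0.29989 -0.078374  0.32789 1.010
#> 6         dlr_c0  0.08581 0.016779  0.05487  0.12108  0.039553  0.13371 1.048
#> 7         beta_c -0.02920 0.001209 -0.03150 -0.02691 -0.032814 -0.02568 1.031
```

The generating values (μ₀ = 0.7, v₀ = 0.015, intercepts 0.1,
β_c = −0.03) sit inside the posterior intervals, and the 99% HDI of β_c
([−0.0328, −0.0257]) is decisively negative. DIC comparison recovers the
generating family:

```r
cmp <- compare_models(cohort$trials, cohort$blocks, cohort$profiles,
                      variants = c("D0", "D1", "D3"),
                      config = mcmc_config(profile = "full", seed = 1))
cmp
#> <spe_comparison> distortion space, best: D1 (non-decisive rivals: D3)
#>   variant       dic        p_d delta_dic decisive
#> 1      D1 -1217.927  6.4317401   0.00000    FALSE
#> 2      D3 -1216.859  5.9793024   1.06767    FALSE
#> 3      D0  -359.613 -0.0665883 858.31427     TRUE
```

The null model D0 is ruled out by ~858 DIC points. The response-bias
model D3 mimics the mean-level effect at this cohort size and is only
separated at larger n — `run_model_recovery()` quantifies exactly this,
and DIC differences below the decisive threshold (10 by default) are
flagged non-decisive.

Model-free diagnostics mirror the descriptive analyses
(`confidence_quantile_summary()`, `interaction_tests()`), and
`run_parameter_recovery()` / `run_model_recovery()` provide the
simulation-based validation harness. A thin command-line wrapper lives at
`inst/scripts/betaspe-tool.R` (subcommands `simulate`, `fit`, `compare`,
`recover`, `diagnose`).

## Package layout

| Area | Functions |
|---|---|
| Belief model | `init_belief`, `update_feedback`, `update_confidence`, `run_sequence`, `spe_loglik` |
| Distortions | `distortion_spec`, `model_params`, `effective_asymmetries`, `base_model_variants` |
| Simulator | `simulate_cohort`, `make_group_designs`, `staircase_update`, `schedule_feedback` |
| Inference | `fit_model`, `compare_models`, `hdi`, `compute_dic`, `mcmc_config`, `prior_spec` |
| Recovery | `run_parameter_recovery`, `run_model_recovery`, `beta_a_recovery_floor`, `tiny_beta_a_check` |
| Diagnostics | `baseline_correct`, `zscore_within`, `confidence_quantile_summary`, `interaction_tests` |
| I/O | `write_dataset`, `read_dataset`, `validate_dataset`, `cli_*` |

See `vignettes/belief-model-methods.Rmd` for the model's assumptions,
the simulator's design choices and known limitations.
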