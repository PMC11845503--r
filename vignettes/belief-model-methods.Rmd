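---
title: "Modelling global self-performance estimates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global self-performance estimates: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaspe)
```

## The scientific problem

People hold two kinds of confidence about a task: *local* confidence in a
single decision ("I'm 80% sure that answer was right") and *global*
self-performance estimates, SPEs ("I got about two thirds of that block
right"). betaspe models how the global estimate is assembled from the
local signals and from occasional external feedback, and how that assembly
is distorted in people with higher anxious-depression symptom load — the
candidate computational origin of the persistent underconfidence seen in
those groups.

## The generative belief model

Each task (a perceptual discrimination and a visual working-memory task)
carries a Beta-distributed belief over expected success with shape
parameters $(a, b)$. The initial belief is parameterised by its mean
$\mu_0$ and variance $v_0$:

$$a_0 = \frac{\mu_0}{v_0}\left(\mu_0 - \mu_0^2 - v_0\right), \qquad
  b_0 = \frac{1 - \mu_0}{v_0}\left(\mu_0 - \mu_0^2 - v_0\right),$$

valid whenever $0 < v_0 < \mu_0(1 - \mu_0)$. On a trial with explicit
feedback the belief updates like a Beta–Bernoulli posterior, but with a
valence asymmetry $\Delta LR_f \in (-1, 1)$:

$$a_{t+1} = a_t + (1 + \Delta LR_f)\ \text{if shown correct}, \qquad
  b_{t+1} = b_t + (1 - \Delta LR_f)\ \text{if shown incorrect}.$$

On a trial without feedback the local confidence report $conf_t \in [0,1]$
stands in for the unobserved outcome, with its own asymmetry
$\Delta LR_c$:

$$a_{t+1} = a_t + conf_t\,(1 + \Delta LR_c), \qquad
  b_{t+1} = b_t + (1 - conf_t)\,(1 - \Delta LR_c).$$

With both asymmetries at zero this reduces exactly to the symmetric
belief-updating account of global confidence formation (unit pseudo-counts
from feedback, confidence pseudo-counts otherwise); the test suite asserts
this reduction and the all-feedback conjugacy limit to machine precision.
The reported SPE at the end of block $B$ is modelled as a draw from the
block-final belief, $SPE_B \sim \mathrm{Beta}(a_n^B, b_n^B)$.

Symptom scores $MH_i$ enter through linear regressions on the asymmetries
and, optionally, a report bias on the Beta mean
$\mu_n^B = a_n^B / (a_n^B + b_n^B)$:

$$\Delta LR_f = \Delta LR_{f0} + \beta_f MH_i, \quad
  \Delta LR_c = \Delta LR_{c0} + \beta_c MH_i, \quad
  SPE_B = \mu_n^B + \beta_a MH_i.$$

The seven distortion variants D0–D6 cross which of $\beta_c$ (confidence
distortion), $\beta_f$ (feedback distortion) and $\beta_a$ (response bias)
are free; `distortion_spec()` encodes the crossing. A negative $\beta_c$
is the "blunted sensitivity to high local confidence" mechanism: the more
symptomatic the participant, the less a high-confidence trial pushes the
global belief upward.

### Numerical choices

* **Effective asymmetries** are hard-clipped to $(-0.99, 0.99)$ inside the
  likelihood so every increment stays positive and the Beta shapes remain
  valid for any slope the sampler visits.
* **Report bias under the Beta likelihood.** $\beta_a MH_i$ shifts the
  Beta *mean* while preserving total concentration $a+b$ (shapes are
  re-derived from the shifted mean, clipped to $(0.001, 0.999)$), keeping
  the SPE likelihood a proper Beta density.
* **Boundary SPEs.** Observed proportions are mapped off $\{0,1\}$ by the
  standard compression $(x(N-1)+0.5)/N$ with $N$ the number of SPE
  observations.
* **Block carry-over.** Whether beliefs persist across blocks of a task or
  reset each block is not pinned down by the task structure; the default
  is carry-over (continuous accumulation), with `reset_per_block = TRUE`
  available, and both paths share one code route that is tested against
  the closed-form sufficient statistics.
* **Confidence scale.** Updates consume the raw 0–1 slider value by
  default. A within-participant rank transform to (0, 1)
  (`conf_transform = "rank"`) is provided for analyses that need to
  equate confidence distributions across participants; it is off by
  default because the simulator generates SPEs from raw confidence, and a
  fitter that silently transforms its input would not be
  parameter-consistent with the generator. (A raw z-score cannot enter the
  update equations, whose confidence argument must live in $[0,1]$.)

## Likelihood and sampler

Because the recursion is linear in its increments, the block-final shapes
collapse to closed-form sufficient statistics — counts of shown-correct
and shown-incorrect feedback events and sums of confidence and its
complement, accumulated per task to each block end (`block_sufstats()`).
One cohort likelihood evaluation is therefore a vectorised pass over
participant-blocks, and exact agreement between this route and the
trial-by-trial recursion is asserted in the tests.

All free parameters are group-level; per-participant asymmetries are
deterministic functions of the symptom score, so there are no subject
random effects. `fit_model()` samples the posterior with a component-wise
random-walk Metropolis sampler whose proposal scales adapt towards a 0.44
acceptance rate during burn-in only (retained draws come from a fixed
kernel). Two stock profiles exist: `"full"` (3 chains × 2000 with 1000
burn-in, the full-length setup) and `"fast"` (2 × 500 with 250) for
recovery sweeps. Convergence is monitored by split-chain
$\hat R$; values above 1.1 raise a warning and mark the fit unconverged
rather than failing silently.

Priors are deliberately weak and are the package's own concretisation of
"weak prior information": $\mu_0 \sim U(0,1)$; $v_0 \sim U(0, 0.24)$
truncated by the validity bound; asymmetry intercepts $\sim U(-0.99,
0.99)$; $\beta_f, \beta_c \sim N(0, 1)$ (their reach is bounded by the
effective-asymmetry clip); $\beta_a \sim N(0, 0.1)$. A prior-only sampling
mode verifies the sampler reproduces these margins.

Model comparison uses the deviance information criterion with the
classic effective-parameter count, $p_D = \bar D - D(\hat\theta)$. DIC's
slight preference for complex models is handled by flagging differences
below a configurable threshold (default 10) as non-decisive: on
null-generated data the richer variants routinely edge out the true model
by a few DIC points, which is exactly the pattern the threshold is meant
to absorb.

## The cohort simulator

`simulate_cohort()` generates the full study design so every downstream
stage is testable without any data download:

* **Eight group designs** per experiment (`make_group_designs()`): six
  main blocks — two feedback-free baselines, then two intervention blocks
  with opposite feedback valences, each followed by a feedback-free test
  block. Experiment 1 crosses intervention task × transfer type ×
  feedback order; experiment 2 always transfers (test blocks are the
  other task, shortened to 20 trials) and carries word-set order as
  metadata. The per-group task assignment is the package's reconstruction
  of the published block-order figure.
* **Staircase.** Each task's difficulty follows a 1-up-2-down transformed
  staircase, which converges on the accuracy $p$ solving $p^2 = 1/2$
  (≈70.7%). Step sizes, starting levels and the logistic psychometric
  observers are stand-ins — the protocol does not publish them — chosen
  once for stable convergence: perception on a berry-count-difference
  axis (start 20, step 2, bounds 1–60), memory on an inverted set-size
  axis (start 6, step 1, bounds 1–12). Fifty practice trials initialise
  each staircase and blocks start at the mean of the previous block's
  last five reversals. Monte-Carlo checks hold both tasks inside 69–73%
  accuracy.
* **Feedback scheduler.** On intervention blocks feedback is drawn
  per-trial Bernoulli with probabilities $9/(40 \cdot 0.71)$,
  $1/(40 \cdot 0.29)$, $1/(40 \cdot 0.71)$, $9/(40 \cdot 0.29)$, i.e. an
  expected 9 + 1 events per 40-trial block favouring the block's valence.
  An exact-quota mode plants exactly those counts for low-variance tests.
* **Confidence generator.** Confidence is a logistic of signed internal
  evidence plus Gaussian noise, clipped to $[0.001, 0.999]$ — the
  simplest monotone generator that makes confidence higher on correct
  than incorrect trials — shifted by `conf_bias_per_mh` (default −0.005
  per symptom unit, so more symptomatic observers report lower
  confidence) and by a per-block drift (`conf_block_sd`, default 0.1).
  The block drift emulates the slow motivational variation in real data;
  without it, block-mean confidence barely varies once the staircase
  stabilises, and the coupling between confidence and SPEs that the
  descriptive analyses visualise would be invisible.
* **Symptom scores** are Uniform(0, 21) by default — the range of a
  common 7-item anxiety questionnaire — and configurable.
* **SPEs** are drawn from the belief model itself under the supplied
  ground-truth parameters and distortion variant.
* **Reproducibility.** Each participant gets a child RNG stream derived
  from the root seed, so any subset of participants regenerates
  identically.

What the generator does *not* emulate: response times, learning or
fatigue trends in accuracy, sequential confidence dependencies, feedback
effects on local confidence, and item-level structure. Passing tests
therefore demonstrate internal consistency of the pipeline under the
model's own assumptions, not fidelity to every feature of human data.

## Recovery harnesses and their scale

`run_parameter_recovery()` simulates cohorts over a grid of ground-truth
slopes, refits, and reports truth-versus-estimate tables;
`run_model_recovery()` builds a DIC confusion matrix over generating
variants. The shipped checks run at desk scale: 120 participants per cell
for the $\beta_c$ grid (five points spanning ±0.03 per symptom unit), 80
participants and ten replicates for model recovery, with the fast MCMC
profile. At these sizes $\beta_c$ recovers with truth–estimate
correlation above 0.99 and decisive sign calls, and confidence-distortion
cohorts are separated from null cohorts by DIC. Response-bias slopes
$\beta_a$ of very small magnitude are *not* recoverable by design;
`beta_a_recovery_floor()` estimates the minimal recoverable magnitude and
`tiny_beta_a_check()` flags fitted values below it as likely spurious.

## Model-free diagnostics

The descriptive layer mirrors the study's key checks in simplified
fixed-effects form: baseline correction subtracts each participant's
per-task baseline-block means; confidence is z-scored within participant
and split into four within-participant quantiles;
`confidence_quantile_summary()` tabulates mean SPE per symptom-tertile ×
confidence quantile with cluster-bootstrap CIs; and
`interaction_tests()` estimates the SPE × symptom interaction on
high-confidence trials and the feedback × symptom interactions on block
SPEs, absorbing participant fixed effects by within-participant demeaning
with cluster-bootstrap CIs. Replacing the original random-slope mixed
models with fixed effects plus cluster bootstrap is a deliberate
simplification: it preserves the interaction contrasts while avoiding a
re-implementation of REML machinery, at the cost of not reproducing the
original standard errors. Bayes-factor evidence for nulls is out of
scope; CI-based statements stand in.

A confidence-distorted cohort ($\beta_c < 0$) reproduces the qualitative
signature that motivates the D1 mechanism: the SPE slope over the
high-confidence quantiles is smaller in the top symptom tertile than in
the bottom one, while the feedback × symptom interactions stay consistent
with zero. Two honest caveats, both visible in the simulations: the
signature is small relative to sampling noise at modest cohort sizes (the
demonstration uses 150 participants and five replicate cohorts, and a
slope magnitude of 0.04 per symptom unit so the pattern is clearly
visible), and the confidence-distortion mechanism mechanically induces a
*small* positive feedback × symptom coupling through its effect on the
belief mean — a genuine model property that stays within the CI-includes-
zero reading at these sample sizes, echoing how the corresponding
empirical tests read as null.

## Open design points, resolved

* **D-variant labelling.** The variant labels follow the model-comparison
  convention in which D1 is the confidence distortion and D2 the feedback
  distortion.
* **Intercept sharing.** Whether asymmetry intercepts are shared or split
  across tasks is exposed (`asymmetry = "split_type"` by default, with
  `"zero"`, `"shared"`, `"split_task"`, `"split_both"` completing the
  five-way base-model comparison in `compare_models(space = "base")`).
* **Symptom scale.** Raw questionnaire units enter the regressions; any
  cross-study rescaling of coefficients (e.g. dividing by the ratio of
  questionnaire ranges) is a reporting step, not a model change.

## Problem sizes used by the shipped checks

Simulated cohorts of 8–150 participants; staircase checks at 10,000
trials; recovery grids of 5 cells × 120 participants; model recovery at
2 × 10 replicates × 80 participants with 7 candidate variants; bootstrap
CIs from 120–1000 resamples. These sizes were chosen so the full suite
runs comfortably on a single CPU while keeping every conclusion's
uncertainty visibly smaller than the effect it checks.
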