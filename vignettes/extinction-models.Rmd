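---
title: "Associative models of compound-cue extinction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associative models of compound-cue extinction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extinctr)
```

This vignette documents the models implemented in `extinctr`, the numerical
and design decisions behind them, and what the package's simulation suites
do and do not establish.

## The task and its design

Each simulated participant completes 179 trials in five phases. Acquisition
(144 trials, context `A:`) presents nine trial types four times per block
over four blocks: cues A and B partially reinforced with outcome X (3 X,
1 Z per block), K and L partially reinforced with Y, C continuously
reinforced with Y, G with X, D and E never reinforced, and the KL compound
continuously reinforced with Y as a cue-additivity demonstration. Two
extinction phases (8 blocks of 2 trials, context `B:`) then extinguish the
target: the control group receives A→Z in both phases, the
deepened-extinction group A→Z then AB→Z, and the super-extinction group
AB→Z in both; every group also receives C→Y in each block so that
reinforcement does not vanish abruptly. A two-trial summation test (G→Z,
context `B:`) probes contextual inhibition, and a single recovery trial
(A→Z) in the novel context `C:` probes renewal.

Trial order is randomised independently within each block from one
participant-level stream (`set.seed(seed)` once, blocks consumed in
experiment order), so a design is reproducible bit-exactly from its seed.
The two summation trials are emitted consecutively: nothing in the task
description requires interleaving and, at two trials, order cannot matter to
any of the models. Stimulus identities are abstract labels; the food images,
screen backgrounds and happy/sad counterbalancing of the original task are
cosmetic under all three models, which are symmetric in outcome identity.

## The three learning models

All three models share the error-correction update ΔV = αβ(λ − ΣV), applied
separately to the two reinforced outcome dimensions X and Y, with λ_k ∈
{0, 1} indicating whether outcome k occurred. They differ in what carries
the association:

* **Elemental Rescorla–Wagner (`rw`)**: one unit per context and one per
  cue; the prediction is the sum of the present units' strengths. Contexts
  and cues have separate learning rates (α_ctx, α_cue).
* **Configural Rescorla–Wagner (`crw`)**: additionally one conjunction unit
  per unordered pair of co-present base units (a single-cue trial has three
  units, a two-cue trial six), learning at its own rate α_cfg. Conjunction
  identity is stable across the experiment.
* **Pearce configural (`pearce`)**: the whole pattern (context + cues) is
  one configuration; the prediction is the similarity-weighted sum over all
  configurations encountered so far, S(a,b) = (n_ab/(√n_a √n_b))^d, and only
  the current configuration updates. A configuration first seen on the
  current trial is registered at strength 0, which leaves that trial's
  prediction unchanged — the natural reading of "all configurations known
  to the system", and numerically neutral.

Two decisions deserve emphasis because the underlying procedure could be
read either way:

* **β selection.** The outcome learning rate β_us applies to dimension k
  when outcome k occurred on the trial and β_~us otherwise
  (`beta_mode = "dimension"`, the default). The alternative — β chosen once
  per trial by whether *any* reinforcement occurred — is available as
  `beta_mode = "trial"` throughout the API; the two coincide on Z trials
  and for β_us = β_~us.
* **The response option Z.** λ is defined only for the occurrence of the
  two reinforced outcome types, so "no outcome" is not a learnable
  dimension: V_Z ≡ 0. This reproduces the guessing limit (g → 0 gives 1/3
  per option) and means the models can never *strongly* prefer withholding
  — a structural property discussed under Limitations.

All strengths start at exactly 0, forcing a uniform prediction on trial 1.

## Response rule and likelihood

Strengths map to choice probabilities by SoftMax with sensitivity
g ∈ [0.0001, 15]: P(R_r) = exp(g V_r)/Σ_k exp(g V_k), V_Z = 0. Probabilities
and log-likelihood contributions are computed through a log-sum-exp shift,
because g·V can reach magnitudes where the raw exponentials overflow or the
probability of an observed response underflows. The participant-level fit
minimises L = −Σ ln P(R_i) over the 179 trials with one-step lookahead: the
prediction for trial n uses learning through trial n−1, and the state is
updated from the *scheduled* outcome — observed responses never feed back
into learning. The trial loop is compiled (Rcpp); a plain-R reference
implementation in the test suite serves as an independent oracle for it.

## Fitting

Parameters are box-constrained — all learning rates in [0.0001, 0.75],
g in [0.0001, 15], d in [0.0001, 20] — via an invertible logistic
reparameterisation to an unconstrained space, so the Nelder–Mead simplex
never evaluates an infeasible point. Each fit uses three starts: the best
of 64 seeded Latin-hypercube samples of the box (a cheap exploratory
search), the conventional point (all parameters 0.1, g = 2), and a seeded
uniform draw. Convergence is a relative tolerance of 1e−6 on L with at most
2000 iterations per start; non-convergence is reported, never an error, and
ties between starts go to the lowest start id. A divergent parameter region
(very high joint learning rates can make strengths oscillate unboundedly)
returns a large finite penalty rather than NaN.

## Model comparison

AICc = 2L + 2V + 2V(V+1)/(n−V−1) per participant (n = 179). Akaike weights,
the group AIC (the product over participants of each model's weight ratio
against the guessing baseline) and the Dirichlet analysis
(α_i = 1 + Σ_j w_ij, P(best_i) = α_i/Σα) are all computed in log space,
with a 1e−300 floor applied only at exponentiation: weight ratios across
174 participants reach e^10000 and are meaningless in linear arithmetic.
Cohort-level AICc is reported under **two labelled conventions** —
`aicc_pooled` (the correction applied to the pooled likelihood with
V = parameters × participants, n = trials × participants) and `aicc_sum`
(the sum of per-participant AICc) — because the pooled correction is not
uniquely defined and the two differ by a few units; the guessing row
(V = 0) is identical under both. Census ties break by the canonical order
guessing < RW < configural RW < Pearce.

## The synthetic cohort

`simulate_cohort()` emulates the study's structure: three groups (the
analysed human sample was 174 participants, 58 per group), per-participant
designs with independent trial orders, and responses sampled trial-by-trial
from a generating model through the SoftMax rule. Generating parameters are
either fixed or drawn uniformly inside each parameter's box, and are
retained as ground truth. Data generation samples the full X/Y/Z
categorical distribution; a `bernoulli_x` mode draws only the X/not-X
indicator, matching the Bernoulli-deviate traces used when overlaying model
predictions on response curves. Seeds derive from one master seed by a
fixed affine rule (`derive_seed`), so cohorts are reproducible and
sub-streams (design, parameters, responses, fits) never collide.

What the generator does *not* emulate: reaction times, missed-response
windows, attention shifts, or any behaviour outside the model family. A
green recovery suite therefore shows that the pipeline recovers what this
model family generates — not that human data satisfy the models.

## Numerical choices

* Similarity is computed as (n_ab²/(n_a·n_b))^(d/2) — algebraically the
  standard form, but exact in floating point for even d (the half-overlap
  case at d = 2 gives exactly 0.5, identical sets exactly 1).
* The fixed-point procedure analysis (`asymptotic_test_strength`) iterates
  the update rule on the simplified two-cue procedures (A+, B+ training,
  then the group's extinction schedule, no context) with αβ = 0.1 until the
  largest per-pass change is below 1e−10 (cap 10^6 iterations), then reads
  out the test strength of A. It reproduces the hand-derived fixed points:
  super-extinction leaves A at 0 (RW), 1/3 (configural RW) and 1/2 (Pearce,
  d = 2); deepened-extinction drives A to −1/2, −1/3 and −1/4.
* The inclusion filter's rank-sum test is evaluated by exact permutation
  enumeration with midranks (C(16,4) = 1820 arrangements) — at 4-vs-12
  binary samples the normal approximation is unreliable; that approximation
  remains available behind `method = "normal"`.

## Problem sizes in the shipped suites

The test and acceptance suites run at sizes chosen to estimate each
quantity stably while keeping a full run in the minutes range on one CPU:
parameter recovery at 50 simulated participants per model (generating
values: learning rates 0.3, g = 5, and d = 2 — the region the fitted human
means occupy — rather than the literal midpoint of the d box, which would
abolish generalisation); model recovery at 60-participant cohorts per
generating model averaged over 5 seeds; sensitivity over a 9-participant
fitted cohort with ±1%, ±2.5% and ±5% perturbations; recovery-rate
contrasts over 200 simulated participants per cell.

## Limitations and honest failures

* **β–g ridge.** The SoftMax sensitivity g multiplies the strengths that
  the βs scale, so the likelihood is nearly flat along a g-versus-β ridge
  at n = 179; the maximum-likelihood point frequently sits away from the
  generating parameters (with *lower* L than the truth — verified by
  multi-restart). Median learning-rate recovery error lands around
  0.14–0.16, at the edge of the 0.15 yardstick used in the acceptance
  suite; for the Pearce model it falls just outside. This is a property of
  the model-plus-design, not of the optimiser.
* **Model mimicry.** On this design the Pearce model tracks configural-RW
  trajectories closely; with one parameter fewer it wins AICc on
  crw-generated cohorts at mid-range generating values. rw- and
  pearce-generated cohorts are recovered correctly.
* **Inclusion ceiling.** Because V_Z ≡ 0, even a perfectly trained model
  responds X on roughly a third of D/E distractor trials, capping the
  inclusion pass rate for simulated learners near 0.83 — unlike human
  learners, who actively withhold. The filter's job — decisive separation
  of learners from guessers — holds regardless.
* **Recovery contrast in the full design.** At the extinction asymptote the
  configural models leave positive strength on A only after
  super-extinction. In the *full* 16-trial design the extinction context
  and its conjunctions/configurations protect A in the single-cue groups
  too, so the configural models predict parity between super and control
  at the recovery test, while the elemental model predicts a clear deficit
  after super-extinction. The package asserts that contrast, and the strict
  super > control ordering only in the asymptotic analysis.
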