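---
title: "A latent-mixture model of individual fear-generalization mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latent-mixture model of individual fear-generalization mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genmix)
```

## Scope and data

`genmix` models trial-level US-expectancy ratings from fear-conditioning
experiments in which circle diameter is the manipulated dimension. Two
canonical protocols are built in: a simple-conditioning design
(`build_exp1_design()`: one CS+, 14 acquisition trials at 50%
reinforcement, 4 generalization blocks, 174 generalization trials) and a
differential-conditioning design (`build_exp2_design()`: CS+ and CS−, 24
acquisition trials at 83% CS+ reinforcement, 3 blocks, 156 generalization
trials). The stimulus grid runs from 50.80 mm to 119.416 mm in steps of
7.624 mm; the maximum CS-to-stimulus distance is 68.616 mm (printed
68.62). Arbitrary variants can be built with `build_design()` and
`build_stimulus_set()`.

Two measurements per trial enter the model: the expectancy rating
`y` (VAS, 1–10) is the response variable; the size estimate (VAS, 0–200 mm)
defines each participant's percept stream. Startle responses are out of
scope.

## The generative model

Four latent groups, indexed by `m`:

1. **Non-Learner** — no associative learning; the response is the sigmoid
   baseline plus noise.
2. **Overgeneralizer** — learns, but similarity decays so slowly
   (λ ≤ λ* = 0.0052 mm⁻¹) that at least 70% of the learned response
   survives even at the largest protocol distance.
3. **Physical Generalizer** — learns and generalizes over physical
   distance (λ > λ*).
4. **Perceptual Generalizer** — learns and generalizes over the distance
   between the current percept and the running mean of CS percepts
   (λ > λ*).

Within a trial sequence, excitatory strength `v+` (and inhibitory `v−`
under differential conditioning) follows the Rescorla–Wagner rule, updated
only on CS trials; the response on trial *j* uses the strength *entering*
the trial, and the trial's outcome updates the strength for trial *j+1*.
Similarity is `exp(-lam * d)` (1 when no learning occurred or strength is
zero), generalized strength is `v+ s+` (+ `v− s−`), and the sigmoid with
floor 1 and ceiling 10 produces the mean rating; ratings are Gaussian
around it, *not* truncated to the scale — posterior predictive replicates
legitimately exceed 1–10.

### Priors

All Table-style priors are collected in `prior_spec()` and sampled by
`sample_hyperpriors()` / `sample_participant()`. Noteworthy choices:

* Normal distributions are parameterized internally by the **standard
  deviation**. The hyperprior on the generalization-rate spread is uniform
  on (10⁻⁹, 1) *on the sd scale*; a precision-parameterized
  re-implementation must convert accordingly.
* The response-noise scales are group-level only: one learner scale
  uniform on (10⁻⁹, 1.5) and one Non-Learner scale uniform on (1.5, 3).
* The Gamma shape and rate of the scaling parameter `w1` both carry
  Half-Cauchy(0, 2) hyperpriors (scale 2, support (0, ∞)).
* λ's truncation boundary λ* = `round(-log(0.7)/68.62, 4)` = 0.0052 is a
  single source of truth (`lambda_star()`), shared by the priors, the
  cohort generator and the sampler. In the fitted model the upper bound
  for generalizer λ is +∞; the 0.3022 cap appears only in the synthetic
  generating rules.

### Resolved modelling ambiguities

Design questions that the behavioural description leaves open were decided
once, as follows:

* **Initial strengths** are v₀⁺ = v₀⁻ = 0, the standard convention; it
  also makes the Non-Learner state coincide with the pre-learning state.
* **CS− outcome coding** is r = −1 on every CS− trial. A constant-0 coding
  would make inhibitory learning impossible; driving `v−` towards −1 gives
  the differential summation `v+s+ + v−s−` its intended range [−1, 1].
* **The cumulative CS-percept mean includes the current trial's percept**
  when the current stimulus is a CS. A misperceived CS then produces a
  nonzero within-CS perceptual distance, which is required for attenuated
  responding on misperceived CS trials.
* Overgeneralizers use **physical** distance; with λ ≤ λ* the similarity
  exceeds 0.7 everywhere, so the distinction is immaterial.
* **Missing size estimates** leave the cumulative mean unchanged and the
  physical size stands in for the percept on that trial; **missing
  ratings** are dropped from the likelihood. Before the first CS percept
  exists the perceptual distance falls back to the physical distance —
  inhibitory/excitatory strength is still zero there, so the value cannot
  reach the likelihood.
* In the differential paradigm the CS− percept mean is **continuous across
  phases** (no reset at the generalization phase).
* Generalization-phase CS+ trials are reinforced at the nominal
  reinforcement rate per block (`round(rate × n)`), consistent with the
  reacquisition runs that protect against extinction.

## Synthetic cohorts

`simulate_cohort()` is the package's generative twin of the model and the
basis of the recovery study. Its defaults *are* the study conditions: 50
participants per group (N = 200) on the differential protocol, one shared
trial schedule (mirroring a recovery study built on a single participant's
experimental structure), and the generating rules of `default_sim_rules()`:
α = 0 (group 1) or Beta(1,1); λ = 0, N(0.0026, 0.001)T(0, 0.0052), or
N(0.1537, 0.1)T(0.0052, 0.3022); σ = 2.5 (group 1) or 0.5; w0 ~ N(0, 5)
(group 1) or N(−2, 1); w1 ~ Gamma(10, 1). The second Normal argument is
read as an sd throughout, consistent with the prior parameterization.

Percepts are a synthetic stand-in: size estimates are drawn as
Normal(true size, `percept_noise_sd`) clipped to [0, 200]. The default of
5 mm (about two thirds of one grid step) produces occasional
one-step misperceptions — enough for the perceptual pathway to be
identifiable without flattening its gradient entirely; the noise level is
a config knob. What the generator does *not* emulate: systematic
perceptual warping (compression/expansion of the dimension), trial-order
effects on perception, drifting response criteria. Passing recovery tests
therefore show that the inference machinery works under the model's own
assumptions, not that real perception is well described by unbiased
Gaussian noise.

## Posterior sampling

`fit()` samples the joint posterior by Gibbs and adaptive
Metropolis-within-Gibbs updates (Rcpp):

* membership `m_i`: exact draw from its full conditional by enumerating
  the (3 or 4) groups;
* mixture weights: conjugate Dirichlet update;
* per-participant continuous parameters: random-walk Metropolis on
  unconstrained transforms (logit for α, log for w1, raw within the
  truncated λ supports). The two truncated λ copies — (0, λ*] and
  (λ*, ∞) — exist for every participant; the copy not selected by the
  current membership is refreshed from its prior (standard mixture
  augmentation), which both respects the group-conditional truncations and
  lets membership moves propose fresh parameter values. Label switching is
  structurally absent because the components have disjoint constraints.
* hyperparameters: conjugate update for the baseline mean; random-walk
  Metropolis elsewhere, including a joint rescaling move along the
  Gamma shape/rate ridge of (a_w1, b_w1);
* truncated normals are drawn by inverse-CDF on the truncated support.

Proposal scales adapt towards 0.44 acceptance during burn-in only
(Robbins–Monro), so the post-burn-in chain has the correct invariant
distribution. Chains are seeded deterministically from the configuration
seed; identical configurations give identical draws.

The reference preset is 4 chains × 100,000 iterations, 75,000 burn-in,
thinning 10 (2,500 retained per chain, 10,000 total). The test preset
(4 × 4,000 / 2,000 / 2) is used throughout the test suite; at these
settings a 40-participant fit takes well under a minute on one CPU.
Convergence is summarized by split-chain R-hat (`rhat_table()`), with
R-hat < 1.05 flagged "converged" (configurable). Non-convergence is
reported, never raised. Scale parameters tied to borderline participants
(e.g. the Non-Learner noise when one participant's membership is genuinely
ambiguous) can remain multimodal across chains; location hyperparameters
converge quickly.

With an empty data set the sampler runs with no likelihood terms and its
draws reproduce the hyperpriors — this limit is exploited as a test of
every hyperparameter update against `sample_hyperpriors()`.

An independent translation of the identical model into the BUGS language,
sampled with JAGS, serves as a cross-check oracle in the test suite; the
two implementations agree on membership probabilities, rates, baselines
and noise scales on a small cohort.

## Classification, checks and ablations

`allocate()` assigns the modal posterior group when at least 75% of
membership draws agree (the threshold comparison is inclusive; ties are
Unknown), and `sensitivity()` re-allocates across thresholds — the Unknown
count is monotone in the threshold. Cohort composition is reported both as
the empirical share of allocated labels and as credible intervals of the
mixture weights π; these are distinct quantities and both are returned.

`posterior_predictive()` pairs each replicate with a single joint
posterior draw; `ppc_quantiles()` compares observed per-stimulus means and
the 10/30/50/70/90% quantiles (linear-interpolation estimator, recorded in
the report) against central 95% bands over replicates. The reference
replicate count is 5,000; the tests use 100–200.

Two simplified variants quantify what ignoring a mechanism costs:

* **simplified1** removes the perceptual pathway (three-group mixture, all
  generalization over physical distance). It recovers physically-grounded
  groups well but must compensate for percept-driven generalization with
  *smaller* λ, biasing Perceptual Generalizers' rates downward.
* **simplified2** removes learning. Its construction is not uniquely
  determined by a verbal description; here associative strength is fixed
  at its asymptote (v⁺ ≡ 1, v⁻ ≡ −1) from the first trial and the
  learning rate is removed. The alternative — estimating a static
  strength per participant — is noted but not implemented. Because real
  strengths build up gradually, the fixed-asymptote model must again
  shrink λ to mimic early weak responding, biasing λ downward for all
  learner groups.

Both biases are verified by sign tests on synthetic cohorts.

## Problem sizes used in the tests

The test suite runs the recovery study at 10 participants per group with
the test MCMC preset (the full 50-per-group, reference-preset study is the
same code path via `preset = "reference"` and is left as a long-running job);
ablation fits use 10-participant single-group cohorts with 2 × 3,000
iteration chains; the JAGS cross-check uses 6 participants on a shortened
differential design. These sizes were chosen so that each check exercises
the full hierarchy while completing in seconds to tens of seconds.

## Known limitations

* The likelihood is an untruncated Gaussian; censoring at the scale ends
  is not modelled.
* Only the Rescorla–Wagner rule is implemented (no Pearce–Hall-style
  attention dynamics), and generalization is purely similarity-based (no
  rule-based extrapolation).
* The percept generator is an unbiased-noise stand-in (above).
* Real-data column layouts vary; `read_trials()` exposes an explicit
  column-mapping dialect rather than guessing external schemas.
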