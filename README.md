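# genmix

Bayesian multilevel mixture modelling of fear-generalization behaviour.

## The problem

In fear-conditioning experiments, people learn that one stimulus (the CS+,
e.g. a circle of a particular diameter) predicts an aversive outcome (the
US, an electric shock) and — in differential protocols — that another (the
CS−) predicts its absence. Novel test stimuli (TSs) along the same physical
dimension then evoke *generalized* fear responses, measured here as US
expectancy ratings on a 1–10 visual-analogue scale. The classical group
gradient hides qualitatively different individual mechanisms: some
participants never learn the contingency, some generalize almost everything
they learned, and the rest generalize according to stimulus distance —
measured either on the physical dimension or on their own trial-by-trial
*perception* of the stimuli (a size-estimation VAS, 0–200 mm).

`genmix` implements a generative, hierarchical mixture model that assigns
each participant *i* to one of four latent groups *m<sub>i</sub>* —
**Non-Learner**, **Overgeneralizer**, **Physical Generalizer**,
**Perceptual Generalizer** — while simultaneously estimating the
person-specific learning and generalization parameters.

## The model

Associative strength follows the Rescorla–Wagner error-driven rule on CS
trials (*k<sub>ij</sub>* = 1):

> v<sub>i,j+1</sub> = v<sub>ij</sub> + α<sub>i</sub> (r<sub>ij</sub> − v<sub>ij</sub>) k<sub>ij</sub>,  with v ≡ 0 for Non-Learners,

with outcome coding r ∈ {0, 1} for the CS+ and r = −1 for the CS−
(inhibitory learning). Similarity decays exponentially with stimulus
distance (Shepard's law), s<sub>ij</sub> = exp(−λ<sub>i</sub> d<sub>ij</sub>),
where d<sub>ij</sub> is the *physical* distance |x<sup>CS</sup> −
x<sub>j</sub><sup>TS</sup>| for Physical Generalizers and Overgeneralizers,
and the *perceptual* distance |cum-mean(CS percepts up to j) −
percept<sub>ij</sub>| for Perceptual Generalizers. The generalized strength
g<sub>ij</sub> = v⁺s⁺ (+ v⁻s⁻ under differential conditioning) is mapped
onto the rating scale by a sigmoid with floor A = 1 and ceiling K = 10,

> θ<sub>ij</sub> = A + (K − A) / (1 + exp(−(w0<sub>i</sub> + w1<sub>i</sub> g<sub>ij</sub>))),

and ratings are y<sub>ij</sub> ~ Normal(θ<sub>ij</sub>, σ²<sub>m_i</sub>)
(untruncated). Overgeneralizers are defined by the boundary λ* =
−ln(0.7)/68.62 ≈ 0.0052 mm⁻¹: their similarity stays above 70% even at the
maximum CS-to-stimulus distance of the protocol (68.62 mm). Group
membership has a categorical prior with Dirichlet(1,1,1,1) weights; all
person-level parameters have hierarchical priors (see `prior_spec()`).

Inference is by MCMC — exact Gibbs draws for membership and mixture
weights, adaptive Metropolis-within-Gibbs for the continuous parameters —
implemented in C++ for speed, with split R-hat convergence diagnostics.
Participants whose modal membership is supported by fewer than 75% of the
posterior draws are reported as **Unknown**.

## Worked example

Simulate a small cohort with known ground truth (5 participants per latent
group on the differential-conditioning protocol), fit the mixture, and
allocate:

```r
library(genmix)
co <- simulate_cohort(cohort_spec(n_per_group = c(5L, 5L, 5L, 5L), seed = 42))
ps <- fit(co$trials, fit_config("full", preset = "test", seed = 43))
al <- allocate(ps, threshold = 0.75)
print(al)
#> Allocation at threshold 0.75 (n = 20):
#>      NonLearner Overgeneralizer        Physical      Perceptual         Unknown
#>            0.25            0.20            0.25            0.25            0.05
rec <- recovery_report(ground_truth(co), ps, al)
allocation_accuracy(rec)
#> [1] 0.95
rec$metrics[1:2, ]
#>  parameter                       subset  n         bias       rmse  rank_cor
#>        lam                     learners 15 -0.000104984 0.02803944 0.9214286
#>        lam correctly allocated learners 14 -0.006722429 0.01518843 0.9692308
```

19 of 20 synthetic participants are returned to their true latent group
(one borderline Overgeneralizer lands in Unknown), and the posterior-median
generalization rates track the true rates with rank correlation ≈ 0.97
among correctly allocated learners. `posterior_predictive()` +
`ppc_quantiles()` compare observed per-stimulus means and 10/30/50/70/90%
quantiles against replicate bands; `fit_simplified()` fits the two ablation
variants (no perceptual pathway; no learning process) used to demonstrate
how ignoring either mechanism biases the inferred generalization rate
downward.

A thin command-line pipeline is available at `inst/cli/genmix.R`
(`simulate`, `fit`, `classify`, `ppc`, `recover`).

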