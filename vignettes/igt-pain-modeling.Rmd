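---
title: "Modeling Iowa Gambling Task behavior in chronic pain: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Iowa Gambling Task behavior in chronic pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`igtbayes` implements a complete analysis pipeline for Iowa Gambling Task
(IGT) behavior in two-group (clinical vs control) designs: the task
environment, four reinforcement-learning models of sequential choice,
hierarchical Bayesian estimation per group, one-step-ahead predictive model
comparison, group contrasts via highest-posterior-density (HDI) intervals,
Brief Pain Inventory–Short Form (BPI-SF) scoring, and parameter–pain
correlation. Since raw clinical trial logs are usually not shareable, the
package ships a synthetic cohort generator that produces every input the
pipeline consumes, with known ground truth, so estimation and comparison
properties can be validated end to end. This vignette documents the models,
the estimation machinery, the defaults, and the design decisions taken where
the design was genuinely open.

## Task environment

The four-deck payoff structure is deterministic in its marginals: per 10-pick
cycle, decks A/B pay €100 per pick and lose €1250 (spread over 5 trials for A,
concentrated in 1 for B); decks C/D pay €50 and lose €250 (5 vs 1 loss
trials). Net per cycle is −€250 for A/B and +€250 for C/D. Sessions start at a
€2000 endowment and run 100 trials.

Published descriptions of the task fix these cycle marginals but not the
positions of loss trials within a cycle. **Decision:** loss positions are a
uniformly random, seeded permutation within each 10-draw cycle, each loss
trial carrying an equal share of the cycle's total loss. This preserves the
marginal structure exactly (every complete cycle conserves the scheduled
loss — a property the test suite fuzzes across seeds) without asserting an
unpublished fixed schedule. Decks never deplete; cycles repeat indefinitely.
Money is stored as exact euro amounts; the division by the outcome scale
(below) happens only inside the models, so trial logs are bit-exact and
scale-free.

Behavioral summaries follow the standard conventions: total gain (endowment
plus cumulative net), and 5 non-overlapping blocks of 20 trials with per-block
good-deck counts (C, D), learning scores (good minus bad) and good-deck
proportions. Trial and block indices are 1-based.

## Cognitive models

All four models map a history of choices and net outcomes `x(t)` (reward
minus loss, divided by the outcome scale) to trial-wise choice probabilities
through a softmax over per-deck values. All latent vectors start at zero, so
the first trial is uniform — this is forced by symmetry, not a tuning choice.

**Outcome scaling.** Net outcomes are divided by 100 before entering utility
and learning (configurable via `scale`). This keeps `x^α` and softmax
arguments numerically tame and matches the modeling convention for this task's
€-denominated payoffs.

**PVL-Delta / PVL-Decay.** Prospect utility
`u = x^α` (gains) / `−λ·|x|^α` (losses) with `α ∈ (0,1)`, `λ ∈ (0,10)`.
Delta rule: only the chosen deck moves, `E_c ← E_c + A(u − E_c)`, `A ∈ [0,1]`.
Decay rule: all decks decay, `E ← A·E`, and the chosen deck adds `u`.
Softmax sensitivity is trial-independent, `θ = 3^c − 1`, `c ∈ [0,5]`.

**VPP.** Adds a perseverance trace to PVL-Delta: `P ← K·P` with `K ∈ [0,1]`,
then the chosen deck gains `ε_p` if the net outcome was non-negative, else
`ε_n` (both unbounded). Deck value `V = w·E + (1−w)·P`, `w ∈ (0,1)`. The
bound `K ∈ [0,1]` is assumed where published parameter lists leave it
unstated; it matches the trace's role as a forgetting factor.

**ORL.** Tracks expected value and win frequency separately with
valence-specific learning rates: after outcome `x` on chosen deck `c`, with
`A = A+` if `x ≥ 0` else `A−`,

```
EV_c ← EV_c + A (x − EV_c)
EF_c ← EF_c + A (sgn(x) − EF_c)
EF_j ← EF_j + A' (−sgn(x)/3 − EF_j)      for unchosen j
PS_c ← 1 / (1 + K),  PS_j ← PS_j / (1 + K),   K = 3^K' − 1,  K' ∈ [0,5]
V = EV + β_F·EF + β_P·PS                 softmax sensitivity 1
```

Two conventions here are genuinely underdetermined in the published
formulations and are explicit package decisions:

- *Fictive learning rate `A'`.* The original ORL formulation updates unchosen
  decks' frequencies with the opposite-valence rate (`A−` after gains, `A+`
  after losses). That is the default; `orl_fictive = "same"` switches to the
  same-rate reading for sensitivity analyses.
- *The `x = 0` branch.* Rate selection and the VPP gain impact treat zero as
  a gain (`x ≥ 0`), consistent with the utility function's gain branch, while
  `sgn(0) = 0` in the frequency targets.

The compiled likelihood and the generative agent share one state-update
routine, so simulation and estimation cannot drift apart. The test suite
checks every model against independent scalar reimplementations (to 1e−10 on
random sessions) and verifies the nested reductions: VPP with `w = 1` and zero
impacts is exactly PVL-Delta, and ORL with zero weights and equal rates is a
delta rule on the raw scaled outcome.

## Hierarchical estimation

Each group is fitted separately with its own prior — two independent
single-group fits rather than one joint model with a group covariate — so the
group contrast is constructed exactly as a draw-wise difference of independent
posteriors.

On the unconstrained scale, individual parameters are non-centered:
`θ_u = μ + σ·z`, `z ~ N(0,1)`, with `μ ~ N(0,1)` and `σ ~ half-N(1)` per
parameter (both scales configurable through `prior_spec()`). Bounded
parameters map to their range by a scaled probit link `U·Φ(θ_u)` (`U` = 1 for
rates and weights in (0,1), 10 for loss aversion, 5 for consistency and the
ORL decay `K'`); the unbounded impact/weight parameters use the identity.
Pushing any prior draw through the links cannot leave the parameter bounds — a
property the suite fuzzes with 10,000 draws.

The sampler is an adaptive Metropolis-within-Gibbs scheme written in C++:

- scalar random-walk updates of each subject's `z` components;
- a joint adaptive-Metropolis move per subject whose proposal covariance is
  learned from that subject's own warmup draws (Cholesky of the running
  covariance, scale `2.38/√P`), to traverse posteriorly correlated parameter
  pairs;
- group-level updates by centered/non-centered interweaving: holding the
  individual unconstrained values fixed, `μ` has a conjugate normal Gibbs
  update and `log σ` a Metropolis update, both free of likelihood
  evaluations, after which `z` is recomputed. This combination mixes well both
  when subjects are data-rich (where pure non-centered group moves crawl) and
  when `σ` is small.

Proposal scales adapt in batches of 25 during warmup only (targets 0.44 for
scalar moves, 0.28 for the joint move) and are frozen afterwards, so the
post-warmup chain is valid MCMC. Defaults: 4 chains, 1000 warmup + 1000
retained draws per chain, optional thinning. Split-R-hat is computed for every
group-level quantity; any value above 1.05 attaches a convergence warning to
the fit object — reported, never dropped. Reproducibility: all chains are
driven by R's RNG from the `seed` argument.

**Known limitation.** The ORL decay `K'` and perseverance weight `β_P`
jointly control the perseverance contribution and form a curved posterior
ridge; their group-level chains mix the slowest and can flag split-R-hat
warnings at default lengths. The learning-rate and weight parameters — the
quantities the group contrasts and pain correlations in this package's
analyses rest on — mix at split-R-hat ≈ 1.00–1.02. Longer warmup plus
thinning (`mcmc_config(thin = )`) brings the remaining quantities down.

Per-subject maximum-likelihood fits (`ml_fit_subjects()`) provide the
unshrunk baseline for demonstrating hierarchical shrinkage. The likelihood
surface has a flat region at zero consistency where gradient methods stall,
so starts are screened by objective value before L-BFGS-B optimisation.

## Model comparison

A "point" is one trial's choice (one-step-ahead prediction), not one subject.
`pointwise_elpd()` computes leave-one-out expected log predictive densities by
Pareto-smoothed importance sampling: per point, the largest importance ratios
(the smaller of 20% or `3√S`) are replaced by expected order statistics of a
generalized Pareto distribution fitted to the tail by the Zhang–Stephens
profile-posterior method, with the usual weakly informative shrinkage of the
shape toward 0.5. Points with shape diagnostic `k > 0.7` are flagged in the
result, never silently refitted. The machinery is verified against a
conjugate-normal toy problem with analytic leave-one-out densities (agreement
within 0.05) and against the identities `LOOIC = −2·elpd` and
`elpd ≤ in-sample lpd`.

`looic_table()` assembles per-group LOOIC, its standard error, the summed
LOOIC and the ascending rank; every model must be fitted to every group.

## Pain assessment and statistics

BPI-SF scoring: severity is the mean of the four intensity items; the seven
interference items average into the total, with the affective subdimension
REM (relations, enjoyment, mood) and activity subdimension WASW (walking,
general activity, sleep, work) defined as sub-means, so
`interference = (3·REM + 4·WASW)/7` identically. Items must be present and in
0–10; there is no imputation.

Group comparisons use the pooled-variance two-sample t test with Cohen's d on
the pooled SD; correlations are Pearson with Fisher-z 95% intervals.
`parameter_pain_report()` correlates each individual-level posterior-mean
parameter with each pain measure over the pooled sample (both groups
together). **Decision:** no multiplicity adjustment by default — matching the
single-test reporting convention of the analyses this package mirrors — with
Benjamini–Hochberg available via `adjust = "BH"`; a Bayes-factor column is
reserved in the output schema but not computed.

## The synthetic cohort generator

`default_regimes()` defines two ORL-driven cohorts (a VPP pair is available):
25 healthy controls and 20 chronic-pain subjects. The groups differ in
exactly two generating parameters — reward learning rate (0.15 healthy vs
0.45 symptomatic: the symptomatic group is more reward-driven) and
perseverance weight (1.25 vs −0.75: the symptomatic group switches more) —
with all other parameters shared. These locations are SYNTHETIC package
constants (so labelled in every study manifest): they produce realistic group
separation and 0–10 pain scores, and encode only the *directions* of the
group differences this kind of study reports, not estimates from any
empirical cohort.

Individual parameters are drawn on the unconstrained scale around the regime
locations (spread 0.4 for probit-linked parameters, 0.8 for the unbounded
weights) and mapped through the links, guaranteeing bounds. Pain is generated
at item level so the scoring path is exercised: a latent subscore per subject
(severity intercept 1.0 + 8·A_rew, noise SD 1.2; REM/WASW intercept 0.8 +
8·A_rew − 0.3·β_P, noise SD 1.5) plus item-level noise (SD 0.8), rounded and
clipped to 0–10 integers. With the default regimes this yields group severity
means near 2 vs 4.5 on the 0–10 scale — the range typical of control vs
chronic-pain samples — and a recoverable positive severity–learning-rate
linkage.

What the generator deliberately does **not** emulate: real response-time
structure, dropout/attrition, device or browser artifacts of web-based
administration, within-session non-stationarity, and any departure of real
choice behavior from the generating model class. Passing recovery tests on
these cohorts therefore demonstrates that the estimation and comparison
machinery works when the model class is correct; it cannot certify the models
against real chronic-pain data.

## Problem sizes and numerical choices

- HDI: the narrowest contiguous interval containing `⌈mass·n⌉` sorted draws.
- Group contrasts pair draws after an independent seeded shuffle per fit
  (the fits are independent); unequal draw counts are down-sampled, seeded.
- The test suite and the acceptance script run reduced-but-adequate sizes
  chosen as package defaults for validation work: parameter recovery at 30
  subjects × 100 trials (2 chains, 600 + 600), model recovery on 12 + 12
  subject cohorts over 5 seeded replicates (2 chains, 300 + 300), and
  end-to-end group-contrast/pain-linkage checks on 10 seeded replicates of
  the full 45-subject design (2 chains, 400 + 400). The analysis drivers use
  2 chains with 1500 warmup and 500 retained draws at thinning 3.
- Degenerate inputs fail loudly: unknown decks, non-divisible block sizes,
  missing BPI-SF items, zero-variance correlation inputs, and mismatched
  subject IDs are errors, not warnings.

## Limitations

Beyond the sampler note above: LOOIC standard errors are reported but the
comparison table does not propagate them into the ranking; the Expectancy–
Valence model and trial-dependent sensitivity variants are out of scope; and
single-subject Bayesian fits are not provided (the ML baseline exists only
for the shrinkage diagnostic).
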