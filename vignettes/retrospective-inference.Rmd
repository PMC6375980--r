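---
title: "Dual-system learning with retrospective inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system learning with retrospective inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostrl)
```

## The task

`ghostrl` simulates and models a dual-outcome restless-bandit task built on a
fixed transition structure: four choice objects each open a unique pair of
four outcome rooms, every room is opened by exactly two objects, and each room
pays one treasure point with a probability that drifts across trials. The
object-room incidence graph satisfying these constraints is, up to labels, a
single 8-node cycle, so `build_task_structure()` constructs the canonical
cycle (object *i* opens rooms *i* and *i* + 1 mod 4) and randomizes only the
labels per participant.

A session has 7 blocks of 72 trials. Two of every three trials are *standard
trials*: two room-sharing objects are offered, the chosen object's unique room
opens first, then the shared (common) room. Every third trial is an
*uncertainty trial*: two disjoint room-sharing object pairs are offered, and
after the participant picks a pair, a hidden fair coin (the "ghost") nominates
which member is executed. The pair's common room opens first — uninformative
about the nominee — and the nominee's unique room opens second, allowing an
observer who knows the transition structure to infer the nomination with
certainty after the fact. The trial after each uncertainty trial is a
follow-up standard trial of one of three types: *repeat* (the nominee vs. the
other-pair object sharing its informative room), *switch* (the rejected
object vs. its other-pair room-sharer) or *clash* (the previously chosen
pair). Offer counts are balanced globally across the session: 42 per standard
pair, 84 per uncertainty pairing, 56 per follow-up label.

Room reward probabilities follow independent Gaussian-increment random walks
with per-trial standard deviation 0.025 and reflecting boundaries at 0 and 1.
The walks' starting values are not dictated by the task description; we draw
them uniformly from [0.25, 0.75], which keeps early trials informative and
avoids boundary pile-up, and expose both the range and explicit starting
values as arguments. Reflection is an iterated fold (`x > 1 -> 2 - x`,
`x < 0 -> -x`), which is exact for the default step size and remains correct
for arbitrarily large configured steps.

## The learning models

All models cache a model-free (MF) value `Q_MF` per object, initialized to 1
(the expected two-room total under a 0.5 reward prior). Pair values are member
means. On standard trials only the chosen object learns, moving toward the
total trial reward (0-2 points) with rate `lr_standard`. On uncertainty
trials both chosen-pair members learn from the total reward — the
ghost-nominated object with `lr_ghost_nom`, the rejected one with
`lr_ghost_rej`. Unequal rates are only possible if the learner resolves the
nomination retrospectively; this asymmetry is the scientific quantity of
interest.

Two model-based (MB) formulations are implemented. The *room-value* family
caches `Q_MB` per room (initialized to 0.5), updates each observed room
toward its own reward with rate `lr_mb`, and evaluates an object on demand as
the sum of its two rooms' values. The *object-value* family caches `Q_MB` per
object, gives the executed object a full update toward the total reward, and
gives each of the two objects sharing exactly one observed room a half update
`Q <- Q + lr_mb * (room_reward - 0.5 Q)`. The object-value cache is
initialized to 1.0, mirroring the MF initialization at the 0.5 room prior
(the natural symmetric choice; it is configurable in code).

Choice combines the systems: `Q_net = w_mb * Q_MB + (1 - w_mb) * Q_MF +
persev * 1[last chosen]`, fed through a softmax with inverse temperature
`beta`. The perseverance indicator marks the option (or pair) containing the
previously selected object. After an uncertainty trial the "previously
selected object" is ambiguous in principle; we default to the ghost's nominee
(the executed object) and provide `persev_after_ghost = "either"` as the
alternative, under which both pair members carry the bonus.

Two pure-MF eligibility-trace models serve as falsification controls. Each
object carries a trace `e`, initialized to 0, decayed by `lam` at the start
of every trial, and incremented for the chosen object(s) — `e <- 1 + e`
(accumulating) or `e <- 1` (replacing); on ghost trials both chosen-pair
members' traces are incremented. All four objects then move toward the total
reward with effective rate `(1 - lam) * lr_mf * e` (accumulating) or
`lr_mf * e` (replacing). These models spread credit over recent choices
without any inference, so they cannot produce a repeat-vs-switch asymmetry in
how the informative outcome drives follow-up choice; the test suite confirms
exactly that. Perseverance is retained in these models (only the MB choice
contribution and `lr_mb` are silenced).

Nested sub-models of the hybrid families: `pure_MB` (`w_mb = 1`, all MF rates
0), `pure_MF_action` (`w_mb = 0`, `lr_mb = 0`; MB inference of the nominee
still guides MF learning), `non_inference` (`lr_ghost_nom = lr_ghost_rej`,
one shared rate) and `no_ghost_rej` (`lr_ghost_rej = 0`).

## Likelihood and fitting

`session_neg_loglik()` replays a logged session, accumulating the negative
log-probability of each observed choice under the evolving state. The ghost's
nominee is always re-inferred from the recorded second room rather than read
from a log column, so fits never trust an unverifiable field. Missing-response
trials (supported for ingested data; the simulator never emits them)
contribute no likelihood term and no learning update. The likelihood is
implemented twice — a compiled core used for fitting and a readable R path
assembled from the exported per-operation update functions — and the suite
holds them together at 1e-10, alongside a third, deliberately naive trace
oracle kept in the tests.

`fit_participant()` runs bounded `L-BFGS-B` from uniform-random starting
points within the bounds: rates, `w_mb` and `lam` in [0, 1]; `beta` in
[1e-3, 20]; `persev` in [-5, 5]. These bounds cover the behaviorally
plausible range without flat-likelihood plateaus; the starting-point
distribution is uniform within them. The full-scale default is 200 starts;
bootstrap refits use documented reduced-start presets (see below) and may be
warm-started at the generating parameters via `fit_options(init = )`.
Convergence is governed by `factr` (1e8 by default, about 1e-8 relative
change in the objective).

## Model comparison

`bglrt_individual()` implements the bootstrap generalized likelihood-ratio
test: the nested sub-model is fitted to the session, `n_boot` synthetic
sessions are simulated from it at the ML parameters on novel trial sequences
(fresh plans and walks, the participant's own object-room mapping), both
models are refitted to each, and the empirical twice log-likelihood
improvement is ranked within the synthetic improvements. The p-value counts
synthetic improvements at least as large as the empirical one; a count of
zero is reported as 0 with resolution bound `1/n_boot`. The group test
(`bglrt_group()`) sums one uniformly drawn null statistic per participant,
10,000 times by default, and ranks the summed empirical statistic. A single
pool of `n_boot` null statistics per participant feeds both levels.

`pbcm()` classifies the two non-nested MB formulations by parametric
bootstrap cross-fitting: per participant and per generating model, synthetic
sessions are refitted with both models, group distributions of the mean twice
log-likelihood difference are resampled, and the empirical group difference
is classified against a criterion of 0 (positive favors the room-value
family). `bh_fdr()` applies the Benjamini-Hochberg step-up rule via
`stats::p.adjust`.

Bootstrap iterations use per-iteration derived seeds (`derive_seed()`), so
results are independent of execution order and reproducible from one global
seed.

## Behavioral analyses

`build_regression_rows()` codes the five trial-transition analyses. Outcomes
are coded +0.5 (reward) / -0.5 (non-reward). For standard-to-standard
transitions whose focal offer contains the previous choice, the probability
of repeating is regressed on the previous trial's common-room (C) and
unique-room (U) outcomes, both defined relative to the focal offer. For
transitions excluding the previous choice, generalization (choosing the
room-sharer of the previous choice) is regressed on C and the common room's
centered reward probability P, read from the stored generative walk as the
experimenters did; sessions ingested without walks cannot support this
analysis and fail with a clear error. For uncertainty-to-standard
transitions, the follow-up's outcome (choice of the nominee on repeat and
clash trials, of the rejected object on switch trials) is regressed on the
non-informative (N, first) and informative (I, second) outcomes.

`hier_logit()` fits participants as random effects with an unconstrained
covariance (via `lme4::glmer`); when that fit fails to converge it falls back
to summary statistics — per-participant unregularized logistic fits and
across-participant t-tests — and records the mode. The two modes agree at the
sign/significance level, which is the surface on which conclusions rest.
`informative_contrast_test()` compares, by a paired two-sided t-test, the
per-participant informative-outcome contrasts on repeat vs. switch
follow-ups. `lr_comparison()` tests the three fitted MF learning rates; with
one rate per participant per context the random-effects regression on
context indicators is degenerate, so the equivalent repeated-measures form is
used (within-participant ANOVA plus paired contrasts); when the context sum
of squares is numerically zero the omnibus statistic is reported as exactly
0. `wmb_lrdiff_correlation()` correlates `w_mb` with
`lr_ghost_nom - lr_ghost_rej` across participants, with a one-sided
permutation test (10,000 shuffles by default — the permutation count is our
choice — or exhaustive enumeration for up to 8 participants).
`calibrated_null_correlation()` is the parametric-bootstrap control for that
correlation: learning-rate estimation noise grows with model-basedness, which
shuffling destroys, so the null is instead built from full-model refits of
non-inference simulations. `bootstrap_lr_interval()` summarizes a
participant's learning-rate difference by the narrowest interval holding 50%
of the parametric-bootstrap mass, conditional on containing the empirical
difference; ties between windows are broken toward the window centered
closest to it.

## The synthetic-data generator as study conditions

`sample_cohort_params()` draws heterogeneous cohorts with `w_mb` uniform on
[0.2, 0.8], `beta` on [3, 8], perseverance on [0, 0.3], `lr_mb` on
[0.2, 0.5], `lr_standard` on [0.3, 0.6], and preferential ghost learning
pinned at `lr_ghost_nom = 0.5` vs. `lr_ghost_rej = 0.1`. These ranges emulate
a cohort with mixed MB/MF reliance and moderately deterministic choice. The
generator reproduces the task's structural properties exactly (counts, offer
balance, outcome ordering, walk statistics) but not every feature of real
behavior: no reaction times or response deadline (timeouts enter only as a
`missing` flag for ingested data), no practice/learning phases, no lapses or
attention drift, and parameters that are stationary within a session. Tests
passing on synthetic cohorts therefore establish that the pipeline recovers
what the models generate — not that human data will show these effects.

A scale note on the repeat-vs-switch contrast: it is computed in probability
units, while the learning models act on the value/logistic scale. Because the
perseverance bonus raises the baseline probability of re-choosing the nominee
on repeat trials, equal ghost learning rates produce equal *logistic* effects
but a slightly *smaller* probability-scale contrast on repeat than on switch
trials (a ceiling effect). Equal-rate and eligibility-trace learners
therefore show a small negative repeat-minus-switch difference rather than
an exact zero. What distinguishes genuine preferential credit assignment is
a clearly positive difference, and the signature tests are phrased that way:
inference-guided models must exceed a positive margin, control models must
stay below it.

## Numerical choices and problem sizes

Softmax probabilities and log-probabilities are computed through stable
logistic/`log1p` forms; Q-values need no clipping because every update is a
convex combination for rates in [0, 1] and rewards in [0, 2], except the
object-value half update, whose fixed point is twice the room mean and which
therefore stays within [0, 4]. The compiled likelihood and simulator are
exact mirrors of the R reference paths (bitwise for the simulator, 1e-10 for
the likelihood).

The test suite runs the statistical studies at desk scale, chosen to finish
in minutes while keeping the checks meaningful: parameter recovery uses 20
synthetic participants with 20 optimizer starts; BGLRT calibration uses 20
replications of 10 participants with 99 bootstrap sessions each, single
warm-started refits for bootstrap iterations and 10-start fits for the
empirical statistics; the qualitative signature checks use 40 participants
per model family; PBCM and the group tests are verified against exhaustive
enumeration on 2-participant instances. Full study scale (200 starts, 1001
bootstrap sessions, 10,000 group resamples, 100 PBCM simulations) is the
default of the corresponding functions.

## Known limitations

The `non_inference` and `full` models are nested on a boundary-free interior
tie, so the classical chi-squared reference for the likelihood-ratio
statistic would be approximately valid here; the bootstrap procedure is kept
regardless because other sub-models (`pure_MB`, `no_ghost_rej`) pin
parameters at bounds where the asymptotic reference fails. Reduced-start
refits introduce a small amount of optimizer noise into bootstrap null
distributions; warm starts keep empirical and synthetic fit quality
comparable, and the calibration test bounds the residual effect. The
random-effects logistic mode can fail to converge on small or separated
datasets, in which case results come from the documented summary-statistics
fallback; coefficients are then comparable at the sign/significance level
but not numerically identical to a mixed-model fit.
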