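# ghostrl

Dual-system reinforcement learning with retrospective state inference:
simulation, model fitting, bootstrap model comparison and behavioral analysis
for a dual-outcome restless-bandit task with latent "ghost" nominations.

## The problem

In many choice settings the state that produced an outcome is only revealed —
if at all — after the outcome itself. This package implements the complete
computational apparatus for studying that situation in a controlled bandit
task. Four objects each open a fixed pair of four treasure rooms (each room
shared by exactly two objects), and room reward probabilities drift as
reflected Gaussian random walks (step SD 0.025 per trial). On *uncertainty
trials* the agent picks one of two object pairs and a hidden fair coin
nominates which member is executed; the pair's common room opens first
(uninformative about the nominee) and the nominee's unique room second, so an
agent with a model of the transition structure can infer the nomination
retrospectively. The scientific question is whether model-free (MF) credit
assignment is guided by that model-based (MB) inference: does the
ghost-nominated object learn at a higher rate than the ghost-rejected one?

The models are hybrid Q-learners. Each object carries a cached MF value
updated toward the total trial reward — `lr_standard` on standard trials,
`lr_ghost_nom` / `lr_ghost_rej` for the nominated/rejected pair members on
uncertainty trials. The MB system either caches room values and scores an
object as the sum of its two rooms (room-value family) or caches object
values updated through the transition structure (object-value family).
Choices follow a softmax over
`Q_net = w_MB Q_MB + (1 - w_MB) Q_MF + p · 1[last chosen]`.
Pure-MF eligibility-trace variants (accumulating and replacing) serve as
falsification controls. Inference on fitted models uses multi-start maximum
likelihood, bootstrap generalized likelihood-ratio tests (individual and
group), parametric bootstrap cross-fitting for the non-nested family
comparison, and Benjamini-Hochberg FDR control; model-agnostic analyses
regress trial-to-trial repetition/generalization on coded outcomes with
participants as random effects.

It is intended for computational cognitive scientists who want to simulate
the task, fit and compare the models on simulated or deposited data, or reuse
the bootstrap machinery.

## Worked example

Simulate a small cohort whose generating parameters prefer the
ghost-nominated object (`lr_ghost_nom = 0.5` vs `lr_ghost_rej = 0.1`), fit
the full room-value model, and inspect the recovered asymmetry:

```r
library(ghostrl)

pars <- sample_cohort_params(6, seed = 1)
sessions <- simulate_cohort(pars, model_spec("mb_room"), seed = 2)
fits <- lapply(seq_along(sessions), function(i)
  fit_participant(sessions[[i]], model_spec("mb_room", "full"),
                  fit_options(n_starts = 20, seed = derive_seed(3, i))))
fits[[1]]
#> Fit (mb_room/full) participant sim01: -logL = 168.747, 7 free params
#>         w_mb         beta       persev        lr_mb  lr_standard lr_ghost_nom
#>       0.3673       6.4208       0.1727       0.4396       0.3782       0.3485
#> lr_ghost_rej
#>       0.1020

mean(sapply(fits, function(f)
  f$params[["lr_ghost_nom"]] - f$params[["lr_ghost_rej"]]))
#> [1] 0.3246
```

The fitted learning-rate difference is positive for the cohort, recovering
the generating 0.4 gap up to estimation noise. The model-agnostic route shows
the same structure — on repeat follow-ups, choice of the previously nominated
object depends on the uncertainty trial's outcomes:

```r
rows <- build_regression_rows(sessions, "unc_repeat")
hier_logit(rows, c("N", "I"), mode = "summary_stats")
#> Hierarchical logistic fit (summary_stats mode, 336 rows, 6 participants)
#>          term estimate    se statistic df      p
#> 1 (Intercept)    4.229 1.531      2.76  5 0.0397
#> 2           N    7.418 2.734      2.71  5 0.0421
#> 3           I    3.298 1.562      2.11  5 0.0884
#> 4         N:I    4.650 3.938      1.18  5 0.2910
```

Here `N` and `I` are the non-informative (first) and informative (second)
outcomes coded ±0.5; positive coefficients mean rewarded outcomes raise the
repetition probability. At 40 participants (the scale used in the test
suite) the informative-outcome effect and the repeat-vs-switch contrast
asymmetry are reliably significant; `informative_contrast_test()` computes
the latter.

Model comparison at study scale, for one participant:

```r
r <- bglrt_individual(session, model_spec("mb_room", "full"),
                      model_spec("mb_room", "non_inference"),
                      n_boot = 1001, options = fit_options(n_starts = 200))
r$p_individual   # proportion of bootstrap improvements >= the empirical one
```

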