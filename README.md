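# lbarena

Simulation and hierarchical Bayesian analysis of decision-making in timed
competitions, built around the Linear Ballistic Accumulator (LBA).

## The problem

In a timed competition — two players earning a point for every correct
perceptual decision and losing one for every error, racing a deadline —
behavior can shift along two distinct axes: **strategy** (how much evidence
a player demands before responding; the LBA threshold) and **effort** (how
fast correct evidence accumulates; the correct-response drift rate).
`lbarena` is for researchers in computational cognitive modeling who want
to simulate such competitions and estimate, decision by decision, how
threshold and drift move with the player's momentary score difference and
the time remaining.

The core model: each decision is a race between two independent linear
accumulators with uniform start points on `[0, A]`, normal drift rates
(sd fixed to 1), raw threshold `b = A + B`, and nondecision time `t0`.
For participant *i* on decision *j*,

    B_ij      = b0 + b1·score_diff + b2·time_remaining + b3·(interaction)
    v_corr_ij = b4 + b5·score_diff + b6·time_remaining + b7·(interaction)

with standardized covariates — 11 free parameters per participant (`A`,
`t0`, the incorrect drift, and the eight regression coefficients),
pooled across participants by normal / truncated-normal population
distributions. Effects are reported as posterior estimates with 95%
credible intervals, Savage–Dickey Bayes factors, conventional evidence
labels, and split R-hat diagnostics. A companion module fits Bayesian
mixed-effects polynomial regressions of accuracy (logit) and response
time (log ms) directly on the covariates.

Everything stochastic is seeded; the likelihood conditions each observed
decision on completing before the episode deadline (see the methods
vignette for why that matters).

## A worked example

```r
library(lbarena)

ds   <- simulate_dataset(2, seed = 42)      # 2 participants x 52 episodes
prep <- prepare_decisions(ds$decisions, scaling = ds$truth$scaling)
summarize_behavior(prep, ds$episodes)$overall
#>   n_decisions  accuracy mean_rt_ms  win_rate
#> 1         920 0.7673913   1073.144 0.3173077
```

920 decisions survive the exclusion screens (response times at or under
250 ms or at or over 5 s, practice episodes, participants under 55%
accuracy); the simulated cohort shows the ~77% accuracy and ~1.05 s mean
response time typical of this task, against an opponent calibrated to
score 8 points per 20 s. Evidence for an effect is summarized the way the
reports print it:

```r
draws <- rnorm(5e4, 0.12, 0.03)                      # posterior for a slope
bf <- savage_dickey_bf(draws, function(x) dnorm(x, 0, 0.2))
c(bf10 = round(as.numeric(bf), 1), label = classify_evidence(bf))
#>     bf10    label
#> "1148.5" "extreme"
```

The full analysis is a sequence of numbered drivers over the package
functions:

```sh
Rscript analysis/01_simulate.R    # synthetic cohort -> results/data/
Rscript analysis/02_prepare.R     # exclusions + standardized covariates
Rscript analysis/03_behavior.R    # descriptives + accuracy/log-RT mixed models
Rscript analysis/04_fit_lba.R     # MLE route + hierarchical regression LBA
Rscript analysis/05_recovery.R    # estimates vs the generating truth
```

`analysis/04_fit_lba.R` writes the per-effect evidence table (estimate,
95% CI, BF10, label, R-hat) for the six regression slopes — threshold and
correct drift against score difference, time remaining, and their
interaction.

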