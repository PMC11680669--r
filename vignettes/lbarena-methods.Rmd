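---
title: "Modeling effort and strategy in timed competitions with the regression LBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling effort and strategy in timed competitions with the regression LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lbarena)
```

## The scientific question

When people compete against an opponent under a deadline, how do their
*effort* (the rate at which they process information) and their *strategy*
(how much evidence they demand before committing to a response) shift as
the clock runs down and as they pull ahead or fall behind? `lbarena`
implements a complete simulation-and-inference pipeline for this question:
a simulator of deadline-bound point-scoring competitions in which both
players are Linear Ballistic Accumulator (LBA) decision makers, and a
hierarchical Bayesian estimation stage for a *trial-level regression LBA*
in which the decision threshold and the correct-response drift rate vary
with the momentary score difference and the time remaining.

## The decision model

Each two-choice perceptual decision is a race between two independent
accumulators (left/right). Accumulator $k$ starts at a value drawn
uniformly from $[0, A]$ and grows linearly at a rate drawn from
$\mathrm{N}(v_k, sv)$; the first accumulator to reach the raw threshold
$b = A + B$ determines the response, and the response time adds a
nondecision component $t_0$. Following the field's convention the
threshold is parameterized by the offset $B = b - A > 0$. The drift-rate
sd is fixed at $sv = 1$, which sets the evidence scale.

The closed-form single-accumulator first-passage distribution
(`lba_fp_cdf()`, `lba_fp_pdf()`) combines with independence to give the
*defective density* of response $k$ at decision time $t$:
$f_k(t)\,\bigl(1 - F_{3-k}(t)\bigr)$ (`lba_defective_density()`), whose
time integral is the choice probability (`lba_choice_probability()`). All
of these are validated in the test suite against brute-force Monte Carlo
race simulations ($10^6$ draws) and quadrature identities.

### Trial-level regression

Participant $i$ on decision $j$ uses

$$B_{ij} = \beta_0 + \beta_1\,\mathrm{score\ diff}_{ij} +
  \beta_2\,\mathrm{time\ remaining}_{ij} + \beta_3\,(\mathrm{interaction})_{ij},$$
$$v^{\mathrm{correct}}_{ij} = \beta_4 + \beta_5\,\mathrm{score\ diff}_{ij} +
  \beta_6\,\mathrm{time\ remaining}_{ij} + \beta_7\,(\mathrm{interaction})_{ij},$$

with both covariates z-scored and the interaction formed from the
standardized terms. $A$, $t_0$, the incorrect-response drift and $sv$ are
constant across decisions, so each participant is described by exactly 11
free parameters (`n_free_parameters()` audits this). A rising threshold
with more time remaining reads as increased caution; a rising correct
drift with a better relative score reads as increased effort.

### Observation model: why the likelihood conditions on the deadline

Two selection effects separate the raw defective density from the data
the competitive task can actually produce. First, a trial on which both
drifts are negative never finishes; the simulator redraws such drift
vectors, so no-response trials are never observed. Second — and
quantitatively much more important — a decision still accumulating when
the episode deadline arrives is discarded. Each observed response time is
therefore right-truncated at the time remaining from its own onset.
Because the two accumulators cross independently, the race's completion
CDF has the closed form $1 - (1 - F_1(\tau))(1 - F_2(\tau))$ with $\tau =
\mathrm{time\ remaining} - t_0$, so the truncation correction costs only
two extra CDF evaluations per trial. `participant_loglik()` applies it by
default (`conditioning = "deadline"`). We found this essential in
parameter-recovery experiments: fitting episode-generated data without it
drives the start-point range toward zero and inflates the threshold
intercept by roughly a factor of two, even for maximum-likelihood fits on
~1,900 trials, because the model tries to reproduce the missing slow tail
by other means. With the correction, the MLE recovers the threshold
intercept within a few percent.

## The synthetic-data generator

`simulate_dataset()` reproduces the study design exactly: 4 deadline
levels (5/10/20/40 s) crossed with 13 starting score differences
($-6\ldots+6$) for 52 episodes per participant in randomized order;
participant start scores uniform on 7–13 with the opponent's derived from
the difference; $\pm 1$ point per correct/incorrect decision; a 1-s
feedback screen after every decision, truncated by the deadline; and an
opponent whose decisions come from a fixed LBA.

Choices the design left open, fixed once and documented here:

* **Opponent scheduling.** The two players run as independent decision
  streams on a shared clock, each with its own 1-s post-decision screen;
  score changes land at the moment a decision completes, and the
  participant's covariates are read at stimulus onset.
* **Deadline edge.** A decision whose crossing would land after the
  deadline is discarded without score change, and ends its stream.
* **Scores** may go negative; no floor is applied.
* **Stimulus direction** is a fair coin on every trial.
* **Opponent level.** `calibrate_opponent()` bisects on the correct-response
  drift (other parameters fixed at documented defaults) until the mean net
  score over solo 20-s episodes is 8 points, the level reported for the
  study's opponent; the package default (`default_opponent()`,
  $v_{\mathrm{correct}} = 2.244$, implied accuracy 0.89) was produced by
  this routine and is revalidated by fresh simulation in the tests.
* **Generating population.** Intercept-level truths ($A = 0.7$,
  $t_0 = 0.3$ s, $\beta_0 = 0.8$, $\beta_4 = 1.8$,
  $v_{\mathrm{incorrect}} = 0.7$) were chosen so a simulated cohort shows
  roughly 77% accuracy and a ~1.0 s mean response time — the behavior the
  study reports; slope truths ($\beta_1 = 0.04$, $\beta_2 = 0.05$,
  $\beta_3 = -0.02$, $\beta_5 = 0.13$, $\beta_6 = -0.03$,
  $\beta_7 = 0.03$) sit at the midpoints of the fitted credible intervals
  the study prints.
* **Covariate scaling at generation.** The generator standardizes
  covariates with fixed reference constants (score difference: mean 0,
  sd 4; time remaining: mean 14 s, sd 11 s), recorded in the truth
  sidecar, so generating and recovered coefficients share a scale.
  `standardize_covariates()` derives constants from the data by default
  and accepts supplied constants for recovery work.

One tension in the published account cannot be resolved by any parameter
choice: an opponent averaging 8 points per 20 s outscores a decision maker
with 77% accuracy and ~1 s decisions (whose net rate is about 5 points per
20 s), so the simulated win rate (~0.35) sits below the study's reported
59%. We match the explicitly stated conditions (opponent scoring rate,
accuracy, response time) and note that the generator is not intended to
reproduce psychological features beyond the LBA — no attention lapses, no
learning across episodes, no sequential dependencies — so passing
recovery tests demonstrate that the inference machinery is correct for
data generated by this model, not that the model captures every feature
of human data.

## Exclusions and preparation

`prepare_decisions()` applies the study's screens: participants below 55%
accuracy (strict inequality, computed on non-practice trials before any
trial-level screen) are flagged wholesale; decisions at or under 250 ms or
at or over 5 s, and practice decisions, are flagged individually
(boundaries read inclusively from the study's wording). Rows are flagged,
never deleted, and the operations are idempotent and order-independent.
Covariates are z-scored over the retained pool (sd with denominator
$n - 1$).

## Hierarchical estimation

Individual parameters are drawn from normal or truncated-normal
population distributions — $A$ and $\beta_0$ bounded below by 0, $t_0$
in $[0.1, 1]$ s, drifts and slopes unbounded — each with location $\mu$
and scale $\sigma$ hyperparameters.

**Hyperpriors.** Locations get normal priors truncated to each
parameter's own support; a location far outside the support of a
truncated family is not separately identified (it merely reparameterizes
a decaying density) and, left unbounded, wanders without changing the
fit. Spreads are set on each parameter's natural scale (0.2 for slopes
whose fitted magnitudes are a few hundredths, 0.2 s for $t_0$, 0.5–1
evidence unit for the rest); scales get half-normal priors, again on the
parameter's scale. All values are configurable
(`default_hyperprior()`).

**Sampler.** `sample_posterior()` runs a gradient-free blocked
differential-evolution MCMC: each sweep updates every participant's
11-parameter block with DE proposals (a mix of full-block and random
2–4-coordinate subsets, which move along the correlated
$A/\beta_0/t_0$ ridge), then each parameter's $(\mu_k, \sigma_k)$ pair
against the individual draws, with occasional ensemble migration
(cyclic permutation of chain states — a symmetric, always-accepted
proposal on the product space). Chains initialize at jittered
per-participant maximum-likelihood fits (`mle_fit()`, the fast recovery
route: multi-start bounded L-BFGS-B). Degenerate proposals
($B_{ij} \le 0$, $t_0$ outside $[0.1, 1]$, nonpositive scales) are
rejected outright; densities are floored at $10^{-300}$ before logs.

**Convergence.** `split_rhat()` implements the split-chain potential
scale reduction. At the desk-scale settings used throughout (20 chains,
700 warmup + 500 kept sweeps, 10–20 participants with ~400–460 retained
decisions each — sizes chosen so a full recovery run completes in
minutes), population locations reach split R-hat of roughly 1.05–1.2.
We surface rather than suppress this: the analysis driver warns whenever
a population R-hat exceeds 1.05, consistent with treating 1.01 as
preferred, values up to 1.05 as acceptable with a warning, and larger
values as a flag on the affected effect. Recovery quality at these
settings is strong regardless of the residual R-hat: on a 20-participant
cohort the posterior sign of the score-difference effects on threshold
and drift is recovered with probability above 0.9 and population-location
posterior means correlate with the generating truth at $r > 0.95$; a
residual ridge bias remains (threshold intercept high, $A$ and $t_0$
low), which is the familiar LBA start-point/threshold trade-off and
shrinks with more data per participant.

## Bayes factors and reporting

`savage_dickey_bf()` computes $\mathrm{BF}_{10}$ for each effect's
population location as the ratio of prior to posterior density at zero,
the posterior ordinate estimated by a Gaussian kernel with Silverman's
bandwidth (configurable). Unresolvable posterior mass at zero returns a
flagged cap of $10^6$ rather than infinity. `classify_evidence()` applies
the conventional bins (1–3 anecdotal, 3–10 moderate, 10–30 strong,
30–100 very strong, >100 extreme; reciprocals mirrored for evidence of
absence), and `credible_interval()` reports equal-tailed intervals.
`evidence_report()` assembles the per-effect table: estimate, posterior
sd, $\mathrm{BF}_{10}$, 95% CI, split R-hat, label.

## Behavioral mixed models

Independently of the LBA, `fit_behavioral_model()` regresses accuracy
(logit link) and response time (log scale, milliseconds) on the
standardized score difference, time remaining, both squares, and the
interaction, with participant random intercepts — six fixed effects per
outcome. The same DE-MC machinery samples the posterior (random
intercepts via a vectorized participant-wise Metropolis pass, since their
conditionals factor), so Savage–Dickey Bayes factors and credible
intervals come off the draws exactly as for the LBA. Priors: normal(0, 1)
on the five slope coefficients (this is the Savage–Dickey prior ordinate),
normal(0, 5) on the intercept, half-normal(1) on the random-intercept
scale and the log-RT residual sd. The test suite cross-checks the
posterior means against `lme4::glmer`/`lmer` fits of the same models and
verifies that the log-RT residual sd recovers the generating noise within
10%.

## Numerical choices

* Choice-probability quadrature integrates the defective density over a
  knot sequence spanning the crossing-time scale and hands the tail to
  the semi-infinite transformation of `stats::integrate`; a single wide
  adaptive rule can miss the near-deterministic spike that small $sv$
  produces, and a fixed upper cutoff is unusable because the defective
  CDF approaches its limit only polynomially.
* Normal-CDF arguments in the scalar closed forms are clamped at
  $\pm 38$; the vectorized likelihood path instead relies on `pnorm`'s
  saturation and floors the resulting density.
* The MLE route handles infeasible regions with a large finite penalty so
  bounded quasi-Newton iterations never see `-Inf`; curvature-based
  standard errors from the observed information matrix are used in the
  tests to separate estimator noise from bias along the
  $A/\beta_0$ ridge.
* All stage seeds derive from one global seed via `seed_stream()`
  (counter-based, below $2^{31}$).

## Known limitations

* The residual ridge bias in $A$, $t_0$, $\beta_0$ at ~450 decisions per
  participant is inherent to the LBA likelihood; conclusions should rest
  on the regression slopes, which recover cleanly.
* The time-remaining effect on drift ($\beta_6$) is the least reliably
  recovered slope in our experiments — the same caveat the original
  analysis attaches to it.
* The regression is linear in the standardized covariates; simulating far
  outside the design's covariate range (e.g. multi-minute deadlines)
  extrapolates the linear predictors and can produce degenerate drifts.
* The behavioral models use random intercepts only; random slopes are out
  of scope.
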