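---
title: "Modelling Pavlovian bias under low outcome controllability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian bias under low outcome controllability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavbias)
```

## The paradigm

The orthogonalized Go/NoGo task decouples what a card *predicts* (a possible
+10-point win versus a possible −10-point loss) from what it *requires* (an
active Go response versus withholding one). Two of the four card types are
Pavlovian-congruent (Go-to-Win, NoGo-to-Avoid) — the motivationally natural
response is also the instrumentally correct one — and two put the systems in
conflict (NoGo-to-Win, Go-to-Avoid). Correct responses produce the good
outcome with 70% probability; any outcome following a Go response is reduced
by a 1-point Go-cost (9 / −1 / −11 after action). Each block introduces four
new cards, so learning restarts at the block boundary.

Outcome controllability is manipulated by *yoking*: a LowControl subject's
block-1 base outcomes are a re-randomized replay, card by card, of the
outcomes a matched HighControl subject earned, with the Go-cost first
removed and then re-applied according to the LowControl subject's own
responses. Reward and loss frequencies are thereby matched within each pair
while the response–outcome contingency is severed (except for the Go-cost
itself).

`make_block_schedule()`, `resolve_outcome()`, `apply_go_cost()`,
`build_yoked_streams()` and `run_session()` implement exactly this, and
`generate_cohort()` assembles full four-group cohorts with yoked pairs.

## The choice model

Choices are modelled by a Rescorla–Wagner / Q-learning hybrid. Stimulus
values $V(s)$ and action values $Q(a|s)$ both start at zero with each
block's new cards and are updated by the delta rule with a shared learning
rate $\alpha$; $V$ updates on every trial, $Q$ only for the chosen action.
The response weights are

$$W(\mathrm{Go}|s) = Q(\mathrm{Go}|s) + b_{go} + \pi V(s), \qquad
  W(\mathrm{NoGo}|s) = Q(\mathrm{NoGo}|s),$$

passed through a two-option softmax in which the weights are divided by the
temperature $\beta$ — larger $\beta$ means more random choice. The Pavlovian
bias $\pi$ couples learned stimulus value to action initiation: positive
$\pi$ promotes Go for reward-predictive cards and NoGo for loss-predictive
ones, independent of the instrumental contingency. $b_{go}$ is a
valence-independent action tendency.

### Parameters, links and ranges

| parameter | natural range | link | role |
|---|---|---|---|
| $\alpha$ | (0, 1) | logit | delta-rule step size |
| $\beta$ | (0, ∞) | log | choice randomness (temperature) |
| $\pi$ | ℝ | identity | Pavlovian bias |
| $b_{go}$ | ℝ | identity | Go-bias |

### Reward scale

The feedback entering the value updates is the *delivered* (Go-cost
inclusive) points multiplied by `reward_scale`, default 0.1, so wins enter
as +1.0/+0.9 and losses as −1.0/−1.1. The ±1 scale is the convention in
this model family, and under it a temperature near 2.7 produces the modestly
value-driven behavior (Pavlovian performance index a little above 0.5,
accuracies in the 0.55–0.70 band) characteristic of this task. The scale is
a configuration field, not a constant, because the temperature estimate only
has meaning jointly with it.

## Hierarchical inference

`fit_hierarchical()` estimates, for each of the four parameters, eight
group-level coefficients — intercept, block, controllability, stimulation
and all interactions, dummy-coded with HighControl-Sham block 1 as the
reference cell — plus a subject random intercept shared across blocks (block
enters only through the design row). Priors are Normal(0, 1) on coefficients
on the linked scale and Half-Normal(1) on subject SDs: weakly informative
against the ±3-ish linked scales in play. Dummy coding is itself a design
choice (sum-to-zero coding would redefine every printed coefficient), which
is why the coding is centralized in `build_design()`.

### The sampler

The posterior is sampled by adaptive Metropolis-within-Gibbs on the
non-centered parameterization, with the trial-replay likelihood in compiled
code. Four ingredients matter for mixing and are worth documenting:

1. **Intercept initialization** by deterministic coordinate descent over a
   coarse grid of population-level values. The likelihood has a shallow
   ridge along which higher learning rates trade off against higher
   temperatures; chains started blindly at zero can spend the whole warmup
   walking it.
2. **Component-wise random walks** with Robbins–Monro scale adaptation
   (target acceptance 0.44) for coefficients, subject SDs and subject
   effects; subject effects are updated in one vectorized sweep per
   parameter, valid because the likelihood factorizes over subjects.
3. **Interweaving moves**: a translation move (shift the intercept, absorb
   the shift into the subject effects) and a rescaling move (scale the
   subject SD, counter-scale the effects). Both leave every linear
   predictor — hence the likelihood — unchanged and are accepted on the
   priors alone, so they are essentially free; they break the strong
   posterior correlation between the group mean and the subject effects
   that slows component-wise walks.
4. A **joint multivariate proposal** per parameter over its eight
   coefficients, using the warmup-estimated covariance (Haario-style),
   which cuts across contrast ridges such as intercept versus arm effects.

Each recorded iteration performs two full Gibbs scans. The
replication-scale configuration is 6 chains × 1000 warmup / 1000 draws;
`desk_mcmc_config()` (2 × 300/300) is the bench configuration used
throughout the tests and the acceptance script, where a 20-subject fit takes
well under a minute. Convergence is screened automatically: every monitored
group-level quantity gets the Gelman–Rubin statistic, and any value above
1.05 raises a warning naming the quantity rather than failing silently.
Degenerate data (every subject producing a single response category) raise
an identifiability warning but still fit, as the priors keep the posterior
proper.

### Posterior reporting

`summary()` on a fit reports, per coefficient, the posterior mean, the 95%
highest-density interval (narrowest contiguous window of sorted draws — a
zero-width interval is flagged degenerate), $P(b > 0)$, and the evidence
ratio in the favored direction, reported as `Inf` when every draw lies on
one side.

## Model-free statistics

Reward-based invigoration is the fraction of *all* Go responses emitted on
Win-valence trials, punishment-based suppression the mirror image for NoGo
on Avoid; the PPI is their mean. The denominators are block-wise response
totals, not within-valence totals, and a block with no Go (or no NoGo)
response leaves the sub-measure — and hence the PPI — missing rather than
clamped; missingness propagates into the group analyses, which require
complete cases.

The mixed between-within ANOVA is the classical univariate decomposition
via `stats::aov()` with `Error()` strata; with exclusively two-level within
factors sphericity holds exactly ($\varepsilon = 1$), so no correction is
applied. Partial $\eta^2$ is $SS_{effect}/(SS_{effect}+SS_{error})$ within
the effect's own stratum; a stratum with (numerically) zero residual
variance flags its rows as degenerate instead of reporting an infinite F as
a result. Effect sizes for estimation plots are unpaired Cohen's $d$ with
the pooled SD, and their confidence intervals come from bias-corrected and
accelerated bootstrap over stratified resamples (via the `boot` package),
deterministic given a seed. Both comparison flavors used with this paradigm
are provided: arms against a shared control group, and block-2 minus
block-1 difference scores between stimulation arms.

## The synthetic cohort generator

`cohort_config()` fixes everything about a cohort: group sizes (default
26/26/24/27 across HighControl-Sham/-Stim and LowControl-Sham/-Stim, 103
subjects), the 4 × 8 matrix of generating coefficients, per-parameter
subject SDs, schedule geometry and a master seed from which every schedule,
session and yoking shuffle derives. `generating_coefficients()` offers
three presets: `"none"` (intercepts only: learning rate 0.20, temperature
2.71, Pavlovian bias 0.59, Go-bias 0.30 — values in the range reported for
healthy adults on this task), `"demo"` (adds a small negative block effect
on the Pavlovian bias, emulating its gradual suppression), and `"full"`
(adds controllability, stimulation and interaction effects with the signs
and magnitudes this paradigm produces, e.g. a strongly reduced Go-bias
under low controllability, concentrated in block 1). Subject SDs default to
0.5 on each linked scale — moderate, realistic inter-individual variation.

The generator emulates the *structure* of real data: group sizes, yoked
pairing with source recycling when arms are unequal, exact per-card
contingencies, the Go-cost, and block-boundary learning resets. It does not
emulate several features of real behavior: no lapses or attention drifts,
no session-order or fatigue effects, no reaction times (the paradigm's
fixed response window provides none), and subject parameters drawn from
clean normal distributions on the linked scales. Tests passing on synthetic
cohorts therefore certify the pipeline's internal consistency, not the
adequacy of the model for any particular empirical dataset.

### Recovery studies and the choice of regime

`recovery_cohort_config()` defines the 20-subject configuration used by the
recovery checks: all HighControl (every trial carries response–outcome
contingency, hence instrumental learning signal) and generating values in
an informative regime — temperature 0.5 on the ±1 reward scale, learning
rate 0.35, Pavlovian bias 0.6, Go-bias 0.3, subject SD 0.5. The point of a
recovery study is to ask whether the estimation machinery finds known
parameters *when the data contain information about them*; in that regime
the hierarchical fit recovers all four group-level intercepts within two
posterior SDs and subject-wise ML estimates correlate with truth above 0.5,
as the acceptance script verifies end to end.

The low-signal demonstration regime (temperature 2.71 with ±1 rewards)
behaves differently, and this is a known limitation worth stating plainly:
with 320 trials per subject and near-chance choice behavior, the likelihood
is nearly flat in the learning rate, so its subject-level estimates are
unstable under ML (degenerate zero-temperature corners) and its group-level
intercept is dominated by the prior and the upper-mass of the flat region
in small cohorts. This mirrors why hierarchical estimation — and large
samples — are used with this task in practice. Recovery claims made by this
package are therefore explicitly claims about the informative regime.

## Numerical choices

- The softmax is evaluated as a logistic of the scaled weight difference in
  log-space (`log1p`-based), which is algebraically identical and
  overflow-safe; linked-scale temperatures are clamped to ±20 before
  exponentiation inside the sampler.
- Ties ($P(\mathrm{Go}) = 0.5$) are resolved by the Bernoulli draw itself.
- The 70/30 contingency is realized as exactly `round(0.7 · n_reps)`
  favorable trials per card (a `"bernoulli"` per-trial mode is available);
  fixed proportions make the schedule property exact rather than
  asymptotic.
- Card order is a uniform shuffle of the whole block, with no run-length
  constraints.
- Yoked streams are fully re-randomized within card rather than preserving
  the source's trial positions.
- Every stochastic operation takes an explicit seed; sessions derive
  per-block sub-seeds, cohorts derive per-subject sub-seeds, and the RNG
  state of the caller is always restored.
- Empty record sets have likelihood 0 by convention; an exhausted yoked
  stream is an internal-consistency error, not silent recycling.

## Problem sizes

The test suite and acceptance script run at bench scale by choice: recovery
on 20 subjects × 320 trials with the 2 × 300/300 sampler configuration,
likelihood–oracle comparison on 100 agents × 320 trials, model-free
statistics on one full 103-subject synthetic cohort, and 5000 bootstrap
resamples for every BCa interval. The replication-scale sampler
configuration (6 × 1000/1000) is exposed through `mcmc_config()` for use on
full datasets.
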