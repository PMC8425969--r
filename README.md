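# pavbias

Simulation and analysis of the **orthogonalized Go/NoGo task** with a yoked
low-controllability manipulation — the paradigm used to study how outcome
controllability and medial-prefrontal stimulation shape **Pavlovian bias**
during reinforcement learning.

The package is aimed at decision-neuroscience researchers who want to
simulate this task, fit its standard computational model, and run the
model-free statistics that typically accompany it, all from reproducible,
seeded code.

## What it implements

**Task engine.** Two blocks of 160 trials (4 card types × 40 repetitions)
crossing valence (Win: +10/0 points; Avoid: 0/−10) with required action (Go /
NoGo), a 70/30 response–feedback contingency realized exactly per card, and a
1-point *Go-cost*, so Go-preceded outcomes become 9 / −1 / −11. The
low-controllability manipulation is a *yoked replay*: each LowControl
subject receives, card by card and in fresh random order, the block-1 base
outcomes (Go-cost removed) earned by a matched HighControl subject, so their
own responses influence only the Go-cost.

**Choice model.** A Rescorla–Wagner / Q-learning hybrid. On each trial the
probability of responding is a two-option softmax

```
P(Go | s) = exp(W(Go|s)/β) / [exp(W(Go|s)/β) + exp(W(NoGo|s)/β)]
W(Go|s)   = Q(Go|s) + b_go + π · V(s)
W(NoGo|s) = Q(NoGo|s)
```

with stimulus values and action values updated by the delta rule

```
V(s)   ← V(s)   + α (r − V(s))        (every trial)
Q(a|s) ← Q(a|s) + α (r − Q(a|s))      (chosen action only)
```

Four parameters per subject and block: learning rate α, temperature β
(weights are *divided* by β, so larger β = more random choice), Pavlovian
bias π (couples learned stimulus value to action initiation), and Go-bias
b_go. The same equations serve as generative agent and as likelihood.

**Hierarchical Bayesian inference.** Each parameter gets a group-level
regression over block, controllability, stimulation and all interactions
(dummy coding, HighControl-Sham block 1 reference), plus subject random
intercepts; links are logit (α), log (β), identity (π, b_go). Sampling is an
adaptive Metropolis-within-Gibbs scheme with interweaving moves and a
compiled likelihood; every monitored quantity is screened with the
Gelman–Rubin diagnostic (threshold 1.05). Posteriors are summarized as mean,
95% highest-density interval, P(b > 0) and the evidence ratio
ER₊ = P(b>0)/(1−P(b>0)) (or its inverse).

**Model-free statistics.** The Pavlovian performance index
(PPI = mean of reward-based invigoration and punishment-based suppression),
accuracy and percent-Go tables per card type, mixed between-within ANOVA
with partial η², Bonferroni-adjusted comparisons, and Cohen's *d* with BCa
bootstrap confidence intervals for estimation plots against a shared
control.

**Synthetic cohorts.** `generate_cohort()` builds complete study-structured
cohorts (default 103 subjects in four groups, with yoked pairs) from known
group-level coefficients, so parameter- and effect-recovery can be scored
against ground truth with `recovery_report()`.

## Worked example

```r
library(pavbias)

# one agent on the standard two-block session
agent  <- agent_params(alpha = 0.2, beta = 2.71, pi = 0.59, b_go = 0.3)
trials <- simulate_agent(agent, seed = 1)
ppi(trials[trials$block == 1, ])
#> [1] 0.4245757

# a small four-group cohort with controllability/stimulation effects wired in
cfg <- cohort_config(
  n_per_group = c(high_sham = 5, high_stim = 5, low_sham = 5, low_stim = 5),
  coefficients = generating_coefficients("full"), seed = 2026)
cohort <- generate_cohort(cfg)

bs <- behavioral_summary(cohort$trials)
bs$group <- group_label(bs$control, bs$tdcs)
mixed_anova(bs, dv = "ppi", subject = "subject_id",
            between = "group", within = "block")
#>        effect     F df_num df_den      p partial_eta_sq degenerate
#> 1       group 3.399      3     16 0.0436         0.3892      FALSE
#> 2       block 0.855      1     16 0.3688         0.0507      FALSE
#> 3 group:block 0.492      3     16 0.6926         0.0845      FALSE
```

The PPI of 0.42 says that fewer than half of this noisy agent's Go responses
landed on Win cards (0.5 is the neutral baseline on a balanced block). In
the cohort ANOVA, the `group` row tests the four between-subject arms
(controllability × stimulation) on PPI; with only 5 subjects per arm the
interaction terms are, as expected, far from significant.

A hierarchical fit of a cohort and its recovery score:

```r
fit <- fit_hierarchical(cohort$trials, desk_mcmc_config(seed = 7))
summary(fit)                        # mean, 95% HDI, P(b>0), ER per coefficient
recovery_report(fit, cohort$truth)  # posterior vs generating coefficients
```

A command-line wrapper with `simulate`, `fit`, `summarize`, `metrics` and
`recover` subcommands is installed at `inst/cli/pavbias`; see
`?gng_cli`.

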