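---
title: "Competing critics: model, tasks, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing critics: model, tasks, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(competingcritics)
```

## The model

The package simulates a tabular temporal-difference learner that keeps two
state-action value functions over the same stream of experience. After taking
action $A$ in state $S$, receiving reward $R$ and arriving in $S'$, each
critic computes its own prediction error

$$\delta^{\pm} = R + \gamma \max_a Q^{\pm}(S', a) - Q^{\pm}(S, A),$$

and applies an asymmetrically weighted update with a shared learning rate
$\alpha$:

$$Q^{+} \leftarrow Q^{+} + \alpha\left[(1 + k^{+})\,\mathbf{1}_{\delta^{+} > 0}
  + (1 - k^{+})\,\mathbf{1}_{\delta^{+} < 0}\right]\delta^{+},$$
$$Q^{-} \leftarrow Q^{-} + \alpha\left[(1 - k^{-})\,\mathbf{1}_{\delta^{-} > 0}
  + (1 + k^{-})\,\mathbf{1}_{\delta^{-} < 0}\right]\delta^{-}.$$

With $k^{+}, k^{-} \in [0, 1]$, the optimist $Q^{+}$ amplifies good news and
discounts bad news; the pessimist $Q^{-}$ does the reverse. At
$k^{+} = k^{-} = 0$ both reduce to classic Q-learning, which the engine also
tracks as a reference table $Q$.

Choice integrates the two critics through time-free "go/no-go" semantics: for
every available action a utility is drawn uniformly from the interval between
its two values, $U(a) \sim \mathrm{Unif}[Q^{-}(S,a),\, Q^{+}(S,a)]$, and the
learner acts greedily on the draws with probability $1 - \varepsilon$,
otherwise picking uniformly among the non-greedy actions. Wide intervals make
actions with similar midpoints look like live competitors; narrow intervals
make choice decisive.

Behaviour is best described in a 45-degree rotation of the $(k^{+}, k^{-})$
axes: the risk-sensitivity axis $s_r = k^{+} - k^{-}$ moves the midpoint
$\tfrac12(Q^{+} + Q^{-})$ relative to expected reward (risk-averse to
risk-seeking), and the uncertainty-sensitivity axis $s_u = k^{+} + k^{-}$
widens the interval (decisive to deliberative). `sensitivity_coords()` and
`coords_to_weights()` convert between the two frames.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha` | learning rate shared by all tables | 0.5 | unitless, (0, 1] |
| `epsilon` | exploration probability | 0.3 | unitless, [0, 1] |
| `gamma` | discount factor | 0 (0.9 for the two-stage task) | unitless, [0, 1) |
| `k_plus` | optimism weight | 0.9 | unitless, [0, 1] |
| `k_minus` | pessimism weight | 0.9 | unitless, [0, 1] |

The default tuple `(0.5, 0.3, 0, 0.9, 0.9)` is the reference setting used by
every simulation unless a sweep varies `k_plus`/`k_minus`. All value tables
start at zero.

Three conventions make the update rule total. The indicator pair leaves
$\delta = 0$ unweighted; any weight there yields a zero update, so the weight
is defined as 0 and only affects logging. The proof that
$Q^{-} \le Q \le Q^{+}$ within a run requires $k^{\pm}$ to be neither too
small nor too large, so the package does not assume $Q^{-} \le Q^{+}$
everywhere: utility draws order the two endpoints before sampling, keeping
the "interval of consideration" semantics in every parameter regime. Terminal
transitions (used by the episodic market task) set the
$\max_a Q(S', a)$ continuation term to zero. Ties in the utility arg-max are
broken uniformly at random; they occur with probability zero unless an
interval is degenerate. The utility draw is made (and logged) on every trial,
including exploration trials, so latency readouts exist everywhere;
$\varepsilon$ only changes which action is returned.

## The reward generator

The single-arm learning experiments draw rewards from distributions specified
by their first four moments (mean, SD, skewness, raw kurtosis), with
kurtosis fixed at 2.5 and the other moments varied. `sample_rewards()`
selects a generating family from the Pearson system by the
$(\text{skew}^2, \text{kurt})$ criterion:

* below the Type III line $\text{kurt} = 3 + 1.5\,\text{skew}^2$ — a
  four-parameter (possibly mirrored) beta, with shapes from the classical
  method-of-moments closed form;
* on the line — a standardized gamma;
* symmetric with kurtosis 3 — Gaussian; symmetric and heavier-tailed — a
  rescaled Student $t$;
* elsewhere — a cubic polynomial transform of a Gaussian solved to match all
  four moments (Fleishman power method with a Newton polish).

The downstream learning dynamics depend on the reward law only through its
moments, so the generator is validated by moment recovery (each target within
three Monte-Carlo standard errors at large $n$) rather than by family
identity. Kurtosis 2.5 is read as *raw* (Pearson) kurtosis — platykurtic,
excess $-0.5$ — which lands every learning-experiment configuration in the
beta region and therefore on bounded support; no truncation is applied.
A specification with $\text{kurt} \le \text{skew}^2 + 1$ violates the moment
feasibility bound and is rejected with the violated inequality.

```{r moments}
set.seed(1)
round(sample_moments(sample_rewards(moment_spec(0.5, 0.2, 0, 2.5), 1e5)), 3)
```

## Task environments

All four tasks implement one vectorized Markov-decision-process contract
(`reset`/`step` over replicate vectors), so the engine code is identical
across tasks.

**Single-arm learning** (`stationary_env`): one state, one action, i.i.d.
four-moment rewards. Used for the value-geometry results.

**Iowa Gambling Task** (`igt_env`): one state, four decks. Published net
payoff distributions for decks A, B, D vary across task versions, so the
default scheme follows the classic structure scaled to a Deck C that pays
uniformly from $\{+50, 0\}$: A pays $+100$ with a $-250$ loss half the time,
B pays $+100$ with a $-1250$ loss a tenth of the time, D pays $+50$ with a
$-250$ loss a tenth of the time. That gives expected values
$(-25, -25, +25, +25)$, preserves "bad decks lose on average", and makes
Deck B's single worst outcome far larger than Deck A's. The scheme is a
plain config object (`deck_scheme()`), so alternative published parameter
sets drop in directly.

**Two-stage Markov task** (`two_stage_env`): stage-1 state 1 with two
actions leading to stage-2 states 2 or 3 through common (0.7) / rare (0.3)
transitions; stage-1 rewards are zero; the return to stage 1 is treated as an
ordinary state transition, and information flows between stages through a
discount of $\gamma = 0.9$ rather than an eligibility trace. Stage-2 rewards
are Bernoulli with probabilities following independent reflecting Gaussian
random walks on $[0.25, 0.75]$ with step SD 0.025 — the design of the
original task — redrawn once per completed trial. Trials index *decisions*
(80 decisions = 40 first-stage choices), and stay probabilities condition on
the previous first-stage trial's transition type and its stage-2 reward.

**Market betting task** (`market_env`): 6 markets of 20 decisions, bets
$\{25\%, 75\%\}$, reward centered on the counterfactual neutral 50% bet,
$R = \frac{p' - p}{p}(A - 50)$, so a $+10\%$ move pays $+2.5$ at the high bet
and $-2.5$ at the low bet. The human experiment used historical price
series; the simulated stand-in is a multiplicative Gaussian walk
($p' = p(1+\eta)$, $\eta \sim N(0, 0.05^2)$ truncated above $-0.9$, restart
at 100 per market) — volatile enough that both error signs occur at both bet
levels, which is all the transient readout consumes. Each decision is
episodic for learning; the price path persists within a market. The
task-level reward prediction error z-scores the current fractional gain
against its past values *within the market* (sample SD, $n-1$ denominator);
with fewer than two past values or zero spread it is defined as 0, and such
trials are excluded from sign-conditioned readouts.

## The engine and its seeding

`run_replicates()` advances all replicates in lock-step: one utility draw per
action, epsilon-greedy selection, a vectorized environment step, then both
prediction errors computed from the pre-update tables before either is
written. All randomness flows from a single `set.seed()` per run, with
replicates occupying interleaved positions of one Mersenne-Twister stream.
This makes the run reproducible as a whole — identical configuration and
seed give bitwise-identical results, which the suite asserts — at the cost
that an individual replicate cannot be regenerated in isolation; replicate
independence is preserved because every random variate is consumed by
exactly one replicate. Sweeps give each grid point its own seed offset.

The reference scale is 30,000 replicates of 100 trials. The packaged tests
and the acceptance script run at desk scale — 2,000 replicates for the
numeric summaries (with tolerances computed as three Monte-Carlo standard
errors from the replicate spread), 20,000 for the small stay-probability
contrast, 400–1,000 per point for grid sweeps — sizes chosen so the full
suite completes in well under a minute while every directional claim remains
several standard errors from its boundary.

"Asymptote" is not defined by a curve alone; the package uses the mean over
the final 20 of 100 trials, per replicate, since at $\alpha = 0.5$ every
value trajectory is visibly flat well before trial 80 (the slowest mode, the
pessimist's gain side, contracts by $1 - \alpha(1 - k^{-}) = 0.95$ per
trial). The same window length is the default for gap, midpoint, and IQR
summaries.

## Readouts

*Reaction-time proxy.* A strictly decreasing map $F(x) = e^{-bx}$ puts
utilities on a time scale: the latency is $\min_a F(U(a))$ and the implied
action $\arg\min_a F(U(a))$ equals the greedy action exactly, so choice
probabilities are untouched. $b$ has no empirical anchor here; only
orderings and variability are interpreted, and $b = 1$ fixes the units.
Latency tables (`reaction_times()`) default to greedy trials, where the
reading applies; the pooled mean/SD maps (`max_utility_stats()`) default to
all trials, since the draw itself is made regardless of exploration. Both
filters are arguments.

*Update transients.* `transient_table()` groups the applied updates
$\Delta Q^{+}$ (dopamine-like) and $-\Delta Q^{-}$ (serotonin-like) by the
sign of the task-level RPE and the bet, optionally refined by the next
trial's bet. The grouping variable is the environment's z-scored percent
gain, not $\delta^{\pm}$, mirroring how the corresponding experiment split
trials. Empty cells are reported with a zero count, never interpolated.

```{r transients}
sim <- run_replicates(market_env(), n_trials = 120, n_reps = 300, seed = 2,
                      log_q = FALSE, log_u = FALSE)
transient_table(sim)
```

## What the generators do and do not emulate

The synthetic tasks reproduce the *structure* of the corresponding
experiments — payoff asymmetries, transition kernels, counterfactual
centering — under idealized stationarity: no session effects, no
within-subject parameter drift, no real price histories, and no fitted
subject-level parameters (fitting is out of scope). Tests passing on these
generators therefore demonstrate properties of the model under its stated
conditions, not goodness-of-fit to human data. Quantities whose exact
experimental values are unavailable (deck distributions beyond Deck C, the
stage-2 reward walks, market volatility) are defaults on config objects, so
recovered values can be substituted without code changes.

## Known limitations

* Tables are dense over (state, action); the tasks here need at most
  3 x 4 entries, and no function approximation is provided.
* Soft-max selection, eligibility traces, per-critic learning rates, and
  sequential-sampling (drift-diffusion) reaction-time models are deliberately
  out of scope.
* The within-run ordering $Q^{-} \le Q \le Q^{+}$ is a theorem only for
  intermediate $k^{\pm}$ and equal $\alpha$; the suite asserts it at the
  reference setting $k^{\pm} = 0.9$, not globally.
* The Fleishman branch of the reward generator covers the leptokurtic
  region only up to the power method's own feasibility boundary; outside it
  the solver reports failure rather than sampling from a mismatched law.
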