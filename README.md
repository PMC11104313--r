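# competingcritics

Simulation toolkit for a dual-critic model of human reward learning and
choice, aimed at computational psychiatry and decision-neuroscience work on
risk- and uncertainty-sensitivity.

## The model

Standard temporal-difference (TD) learners track a single state-action value
`Q` and treat good and bad surprises symmetrically. Human choice often does
neither: positive and negative prediction errors appear to be processed by
different systems (dopamine- and serotonin-linked), and behaviour ranges
from risk-averse to risk-seeking and from decisive to deliberative. This
package simulates a learner with **two competing critics** trained on the
same experience:

- an **optimistic critic** `Q+`, updated by
  `alpha * [(1 + k+) 1{d > 0} + (1 - k+) 1{d < 0}] * d` with its own TD error
  `d = R + gamma * max_a Q+(S', a) - Q+(S, A)`, so gains are amplified;
- a **pessimistic critic** `Q-`, with the mirrored weighting
  `(1 - k-)` on gains and `(1 + k-)` on losses.

Choice integrates the pair: each candidate action draws a utility
`U(a) ~ Unif[Q-(S, a), Q+(S, a)]`, and the learner is epsilon-greedy on the
draws. Behaviour decomposes along two rotated axes: **risk sensitivity**
`s_r = k+ - k-` (shifts the midpoint of the two values relative to expected
reward) and **uncertainty sensitivity** `s_u = k+ + k-` (widens the interval,
making similar-valued actions compete). At `k+ = k- = 0` everything collapses
to classic Q-learning, which is carried along as a reference curve.

The package provides the learner and four task environments behind one
contract — single-arm reward learning with moment-specified (Pearson-system)
rewards, the Iowa Gambling Task, the two-stage Markov task, and a
stock-market betting task with counterfactual-centered rewards — plus a
seeded replicate engine, `(k+, k-)` grid sweeps, and readouts: value-function
geometry, deck preferences, stay probabilities, reaction-time proxies, and
dopamine/serotonin-like update transients.

## Worked example

Value-function geometry in the single-arm task (rewards with mean 0.5,
SD 0.2, zero skew, kurtosis 2.5), at the reference parameters
`(alpha, epsilon, gamma, k+, k-) = (0.5, 0.3, 0, 0.9, 0.9)`:

```r
library(competingcritics)

sim <- run_replicates(stationary_env(moment_spec(0.5, 0.2, 0, 2.5)),
                      critic_params(), n_trials = 100, n_reps = 2000, seed = 1)
s <- summarize_q(sim)
round(s$asymptote, 3)
#>    q_plus   q_minus q_neutral
#>     0.743     0.255     0.499
```

The optimist settles well above the true mean, the pessimist well below, and
the risk-neutral reference at the mean (0.5); the gap `q_plus - q_minus`
(here 0.488) scales with the reward SD, and the midpoint (0.499) tracks the
mean because `k+ = k-`.

Deck preference in the Iowa Gambling Task flips from a "good" to a "bad"
deck when pessimism is lowered:

```r
balanced <- run_replicates(igt_env(), critic_params(k_plus = 0.9, k_minus = 0.9),
                           n_reps = 2000, seed = 2, log_q = FALSE)
seeking  <- run_replicates(igt_env(), critic_params(k_plus = 0.9, k_minus = 0.1),
                           n_reps = 2000, seed = 3, log_q = FALSE)
round(deck_frequencies(balanced), 3)
#>     A     B     C     D
#> 0.220 0.204 0.376 0.200
round(deck_frequencies(seeking), 3)
#>     A     B     C     D
#> 0.225 0.328 0.208 0.239
```

With balanced critics the modal deck is C (steady small gains); dropping
`k-` to 0.1 underweights Deck B's rare large loss and the learner develops a
penchant for gambling — the modal deck becomes B despite its negative
expected value.

Other entry points: `run_sweep()` (parameter maps), `stay_probabilities()`
(two-stage task), `transient_table()` (market task),
`reaction_times()` / `max_utility_stats()` (latency proxies), and
`load_config()` / `run_from_config()` / `write_outputs()` for config-driven
runs. `inst/cli/cc` wraps these as `cc run`, `cc sweep`, `cc report`, and
`cc reproduce` subcommands. The vignette
(`vignettes/competing-critics.Rmd`) documents the model, the task
parameterizations, and every numerical convention.

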