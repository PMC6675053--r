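---
title: "Sequence learning and recall with BCPNN attractor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence learning and recall with BCPNN attractor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpnnseq)
```

## The model

`bcpnnseq` simulates a modular attractor memory: `N = H * U` rate units are
organised into `H` hypercolumns of `U` units each, and a hard winner-take-all
(WTA) rule — a stand-in for lateral inhibition — keeps exactly one unit
active per hypercolumn. A *pattern* (cell assembly) activates one unit in
every hypercolumn. Each unit `j` carries a support current `s_j`, a binary
activation `o_j`, and an intrinsic adaptation variable `a_j`:

$$\tau_s \dot s_j = \beta_j + \tfrac{1}{H}\sum_i w_{ij} o_i - g_a a_j - s_j
  + \sigma\,\xi_j + I_j, \qquad
  \tau_a \dot a_j = o_j - a_j,$$

with `o_j = 1` for the per-hypercolumn maximum of `s`. Self-excitatory
weights (`w_self`) make patterns meta-stable; adaptation (`g_a a`) erodes the
active pattern until the feed-forward drive to its successor (`w_next`) wins
the WTA competition, producing sequential recall. Recall is started by a cue
that activates the first pattern: the activation is clamped to the cued
pattern for the cue duration (default 50 ms) while a cue current (default
amplitude 1) raises its support, and the competition is free afterwards. The
clamp is used because with learned, slightly heterogeneous biases a free WTA
on the initial currents can ignite an arbitrary attractor whose learned
self-excitation no moderate cue current can displace.

### Recall tempo

For orthogonal patterns and a homogeneous protocol the dwell (persistence)
time of a pattern has the closed form

$$T_{per} = \tau_a \log\frac{1}{1 - B} + \tau_a \log\frac{1}{1 - \tau_s/\tau_a},
  \qquad B = \frac{\Delta w_{next} + \Delta\beta_{next}}{g_a},$$

implemented in `theoretical_persistence_time()` and defined exactly on
`0 < B < 1`; its `B -> 0` limit, `persistence_time_floor()`, is bounded below
by `tau_s`. `gain_for_target()` inverts the formula algebraically
(`B = 1 - e^{-T/\tau_a}/(1 - \tau_s/\tau_a)`, then `g_a = (\Delta w +
\Delta\beta)/B`), so the dwell time of every pattern can be programmed
individually through per-unit adaptation gains; the round trip holds to
machine precision and zero-noise simulations match the formula to within two
integration steps across `B` from 0.1 to 0.9. The formula is exact for
orthogonal patterns; for overlapping patterns `summarize_transitions()`
reports it as an approximation based on pattern-averaged effective weights
(unit weights aggregated consistently with the `1/H` normalisation above).

### Learning

Training never runs the recurrent dynamics: a timed clamping protocol
(`build_input_series()`) presents each pattern for the pulse time `T_p`,
separated by the inter-pulse interval `IPI`, for a number of epochs;
distinct sequences are separated by 1 s of silence. Each unit carries two
exponential traces of its activation — a slow presynaptic `z` (default
`tau_z_pre` = 25 ms, NMDA-like) and a fast postsynaptic `z` (default
`tau_z_post` = 5 ms, AMPA-like) — and probability traces `p` accumulate the
z-traces and their outer product as exponentially weighted moving averages
with `tau_p` = 5 s. Weights and biases are log-odds estimates

$$w_{ij} = \log\frac{p_{ij}}{p_i\,p_j}, \qquad \beta_j = \log p_j,$$

with every probability floored at `epsilon` = 1e-7 inside the logarithms
(the floor never enters the trace dynamics). Because the presynaptic trace
outlives the pulse while the postsynaptic one does not, temporally adjacent
patterns acquire asymmetric weights — the substrate of sequential recall.
Independent units get zero weight, so the rule weighs associations by their
statistical significance rather than raw frequency: an association seen once
from a rarely active source outranks an equally rare association from a
highly active source, which plain co-occurrence counting
(`naive_hebbian_weights()`) cannot do.

Two estimator details matter. First, weights are computed once after
training (`train_offline()`); recall runs with frozen connectivity. Second,
the probabilities entering the logarithms are the time-average of the
p-traces over the final protocol period, not the end-of-series snapshot: at
the periodic steady state the EWMA oscillates with the presentation phase,
and a snapshot systematically inflates whatever was presented last (for a
two-sequence protocol the second sequence's biases come out ~0.4 log-units
high, which poisons overlap experiments and violates the homogeneous-protocol
symmetry `Δβ = 0`). The period average is the phase-free estimate of the same
quantity. Both raw and averaged traces are returned for inspection.

## Noise model and statistics

Additive Gaussian noise enters the support-current equation. The user-facing
level `sigma_out` is the *stationary standard deviation of `s`*: since `s`
behaves as an Ornstein-Uhlenbeck process away from transitions
(`tau_s << tau_a`), the per-step increment is `sigma_in * sqrt(dt)` with
`sigma_in = sigma_out * sqrt(2 / tau_s)`, which makes the long-run sd of `s`
equal `sigma_out` (verified against the closed-form OU variance in the test
suite). Noise makes transitions fire early, so the stochastic dwell time
`T_per,sigma` shortens with `sigma` while the success-rate-versus-noise
profile is insensitive to the programmed dwell time.

Recall success is judged conservatively: events are maximal intervals during
which all `H` units of a pattern are co-active for longer than `tau_s`
(shorter blips are discarded; same-pattern events separated by at most
`tau_s`, and consecutive duplicate events, are merged — a dwell split by a
transient single-hypercolumn dropout that the recurrent drive corrects is a
detection artifact, not an intrusion). A sequence is recalled iff the event
order reproduces the full target with no skips and no intruding patterns.

`estimate_success_rate()` wraps seeded Monte-Carlo trials with Wald 95%
intervals `p ± 1.96 sqrt(p(1-p)/n)`; `find_sigma50()` locates the noise
level of 50% success by naive bisection on the estimates, stopping when 0.5
falls inside the Wald interval at the midpoint — both accept injected trial
generators, and both are calibrated in the test suite against exact binomial
enumeration and a closed-form threshold. Trial seeds are spawned from one
master seed by a counter scheme (`child_seed()`), so enlarging a trial count
never reshuffles earlier trials.

## Overlapping sequences and disambiguation

`overlapping_pair()` constructs two equal-length sequences whose aligned
patterns share the active unit in a fixed leading set of hypercolumns
(*representational overlap*, a fraction of `H`) over a centered window of
positions (*sequential overlap*, a count); the window never touches the
sequence endpoints, and `representational_overlap()` /
`sequential_overlap()` measure the construction back exactly. With
representational overlap 1 the window patterns are identical and the task
becomes sequence disambiguation: after the shared window the network must
pick the branch consistent with the cued context.
`max_disambiguation_window()` trains such pairs at increasing window sizes
and reports the largest window for which both cues are recalled correctly.

Two mechanisms carry the context across the window. Context patterns
project (floored, hence weakly informative) inhibition to the two fork
candidates, but the joint probability of units `k` pulses apart scales as
`~0.01 * exp(-(k-1) T_p / tau_z_pre)`, which crosses the `epsilon` = 1e-7
floor at `k = 4` for the default protocol — beyond that the fork drives are
equal *by construction*. Past the reach of the weights, only the support
currents remember the context, decaying as `exp(-w T_per / tau_s)` across a
window of `w` dwells. With the defaults this bounds the solvable window at
2; lowering the floor extends it (4 at 1e-12, 5 at 1e-25) until the memory
falls below double-precision resolution of the O(1) currents. Longer dwell
times shrink the window further — recovering tempo control and
disambiguation power are in direct tension.

## Numerical choices

* Integration is explicit Euler (Euler-Maruyama under noise) at `dt` =
  0.5 ms for recall; the stability guard requires `dt <= tau_s / 5`. The
  dominant discretisation bias on measured dwell times is the first-order
  error of the adaptation decay, about `T_per * dt / (2 tau_a)` (0.6 ms at
  `T_per` = 600 ms), plus event quantisation of one step.
* Trace integration uses `dt` = 1 ms by default (at most one fifth of the
  fastest z time constant); traces start at exactly zero.
* WTA ties break to the lowest unit index — deterministic and testable; ties
  have measure zero under noise. At zero noise this makes floored-weight
  regimes look spuriously ordered (the tie-break walks unit indices in
  order), which is why the sequential/unordered regime classification is run
  at a small noise level (`sigma_out` = 0.05) with majority success over
  seeded trials.
* Degenerate inputs: `B` outside `(0, 1)`, dwell targets below the floor,
  invalid bisection brackets and non-finite states raise classed conditions
  (`bcpnnseq_domain_error`, `bcpnnseq_bracket_error`,
  `bcpnnseq_convergence_error`).

## What the generators emulate — and what they do not

All inputs are synthetic by design: the package studies the model, not a
data set. The generators produce idealised minicolumn codes (uniform `U`,
one active unit per hypercolumn, orthogonal or precisely-overlapping
patterns) and noise-free, perfectly timed clamping protocols. Real cortical
data would bring graded activity, heterogeneous column sizes, distance-
dependent connectivity and conduction delays, temporally inhomogeneous
protocols, and correlated noise — none of which are modelled. Passing tests
therefore certify the internal consistency of the dynamics, learning rule
and statistics under the stated idealisations, not biological adequacy.

## Problem sizes

The shipped experiments are desk-scale by choice: 200 Monte-Carlo trials
per success-rate point (Wald half-width ≈ 0.07 at `p = 0.5`), 5-to-12
pattern sequences over 1-10 hypercolumns, 30-100 training epochs, and
bisection at 200 trials per step. All are parameters, not limits; every
experiment scales by changing its configuration.

## A worked run

```{r example}
ps <- orthogonal_patterns(H = 1, U = 5, n_patterns = 5)
fit <- bcpnn(ps, sequences = list(1:5),
             protocol = training_protocol(T_p = 100, IPI = 0, epochs = 50),
             config = learning_config(tau_z_pre = 25, tau_z_post = 5))
summary(fit)

rec <- simulate(fit, T_per = 150, seed = 1)
rec$events
```

The learned matrix is forward-asymmetric (`w_self > w_next > w_prev`), the
homogeneous protocol gives `Δβ ≈ 0`, and the recalled dwell times track the
150 ms target set through the gain inversion.
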