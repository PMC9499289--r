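---
title: "A thalamocortical gating model of cognitive flexibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamocortical gating model of cognitive flexibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it simulates: the
task, the network, the learning rules, the companion estimators, and — most
importantly for a reimplementation — the numerical and design choices that
the model's verbal description leaves open, with the reasons each choice was
made.

## The task

The environment is a blocked probabilistic inference task. On each trial a
tactile cue (*up* or *down*) is presented; the subject responds *up* or
*down*, which amounts to choosing between two rules: **match** (respond with
the cue's direction) or **non-match** (respond with the opposite). Within a
block, the match rule is rewarded with a fixed probability — the
*association level* — of 0.9, 0.7, 0.5, 0.3, or 0.1. A target (the cue
transformed by the rewarded rule) is revealed every trial, so reward is
deterministic given the response: `reward = 1` iff `response == target`.
Blocks change without announcement; the subject must infer the change from
outcomes.

`build_schedule()` provides two schedules. The *human-style* schedule has 10
blocks, two per association level, one 30 and one 40 trials long, 350 trials
in total, in a fixed pseudorandom order (frozen in the package so all runs
use the same order). The *model-style* schedule used in most simulations has
configurable blocks (default 500 trials, levels alternating 0.9/0.1). Cues
are exactly balanced within a block; the rewarded rule is drawn i.i.d. per
trial at the association level (a quota-balanced mode is available as a
configuration flag, since the original description does not say which was
used; i.i.d. is the default for simplicity).

## The network

The dorsolateral prefrontal cortex (dlPFC) is a 500-neuron rate reservoir.
Membrane inputs evolve by Euler integration (dt = 1 ms, tau = 20 ms),

$$\tau \dot I_i = -I_i + [W_{inp}u]_i + (1 + g_m m_i)[W_{rec}r]_i
  + g_a m_i + \rho_i,\qquad r_i = [\tanh I_i]_+,$$

with fixed recurrent weights (Gaussian, variance $0.75/\sqrt{2 N_{sub}}$,
rows zero-centered), structured inputs (each cue unit projects to 200
neurons with uniform [0.2, 0.4] weights; each half of a cue population also
receives one of the two strategy-value inputs; 100 neurons receive no
feedforward input), per-step Gaussian noise of variance $10^{-3}$, and MD
modulation $m = W_{MD}\,r^{MD}$ through one fixed Gaussian weight set
(SD 0.1; see the modulation-strength note below) used both additively and
as a gain on the recurrent drive.
Trials are 200 steps; cue and value inputs are on for the first 100 steps.

The mediodorsal thalamus (MD) is two neurons with winner-take-all (WTA)
activations in {0, 1}. Corticothalamic weights $W^{dlPFC\text{-}MD}$ learn by
a Hebbian rule whose presynaptic factor is an eligibility trace — a low-pass
filter of dlPFC rates with time constant $\tau_{pre}$ = 2000 ms — with both
factors centered, entries clipped to [-0.1, 0.1], and the matrix rescaled to
its initial Frobenius norm at the end of every trial.

Two output neurons integrate the reservoir through plastic readout weights
with an injected uniform perturbation $\zeta \sim U(-1,1)$ per neuron per
step (node perturbation). After the trial's reward, every weight takes the
update $\Delta w_{ij} = \mu\, \delta e \sum_t \zeta_i(t) r_j(t)$ with
$\mu = 5\times10^{-5}$ and $\delta e$ the reward-prediction error.

## Companion estimators

**Strategy value (vmPFC).** A grid maximum-likelihood estimator of the
probability `q` that the match strategy is rewarded, over a 10-trial
horizon; the value pair (q, 1-q) is fed to the reservoir as input. The held
estimate tracks the windowed ML value slowly (rate 0.2 per trial). When it
diverges from the recent match-reward average by more than 0.15 the
estimator considers a block change: it banks the outgoing value, reuses a
banked value that matches the recent average, or creates a fresh estimate at
0.5 that adapts toward the recent average. The slow tracking is a deliberate
deviation from a literal "estimate = windowed ML every trial" reading: the
windowed ML argmax *is* the window average up to grid rounding, so under the
literal reading the divergence test could never fire; a lagging estimate is
what makes the bank-and-switch behavior described for the estimator
possible at all.

**Changepoint observer (OFC).** Two one-hot context-belief nodes and a
Bayesian posterior over "a context switch occurred within the last 10
trials". Each buffered trial is rule-consistent with the believed context or
not; consistency has probability 0.9 under the believed context (the
`context_likelihood` parameter, unstated in the original description and
fixed to mirror the strongest contingency). The posterior combines a
per-trial switch prior of 1/T (T = the experiment's total trial count) over
all split points, normalized by total evidence so it is a proper
probability; pre-switch trials exclude the split point (the printed index
ranges are ambiguous at the boundary; this convention is enumerated in an
oracle test). Above threshold (0.5, strict) the nodes flip and the buffer
clears. Hebbian routing weights from the context nodes to MD (norm 1) and
to dlPFC (norm 2) learn from zero-centered trial-averaged rates at rate
0.001 and are renormalized every trial; the active context's weight row is
injected as a current during the first 10 ms of each trial, into MD or into
dlPFC, starting after the first two blocks.

## Design choices the description leaves open

These were the decisions that mattered in practice. Each is the package's
own choice, made once and kept; the relevant parameters are exposed in
`tc_config()`.

**Trials are episodes.** Membrane states ($I$, $I_{out}$) reset at trial
onset; learning states (eligibility trace, MD membrane and activation,
reward baseline, all plastic weights) persist. With carried-over membranes,
the per-cue activity patterns fluctuate from trial to trial; those
fluctuations, projected through the readout, add decision noise that grows
with the readout norm, and node-perturbation learning then never leaves the
noise floor. With episode resets the patterns are nearly deterministic per
cue and context, and learning converges within one or two 500-trial blocks.

**Linear output units.** The output equation specifies only a leaky
integrator; no activation function is stated. The outputs are therefore
taken as linear, and the decision compares window means (steps 101-200) of
the two output membranes, ties to *up*. A rectified-tanh output has a dead
zone at zero that decouples decisions from the learned signal.

**Per-step readout accumulation.** The readout update references per-time
quantities while reward arrives per trial; the package applies the update
once per trial using the summed product $\sum_t \zeta_i(t) r_j(t)$, which is
what applying the per-step rule at every step with the trial's $\delta e$
amounts to. A trial-mean mode (product of window means) is available but is
~200x slower per trial and does not reach the reported performance within
realistic trial budgets.

**Reward baseline.** $\delta e$ = reward minus an exponential moving average
(decay 0.1). Decay = 1 recovers the one-trial difference reading of "change
in reward received".

**Adaptive decision referencing.** Each output's decision value is its
window mean minus a slow per-output running average (time constant 50
trials). Without it, a change in thalamic state shifts both outputs by a
large constant; the biased margin then exceeds the perturbation noise,
responses pin to one side, the reward gradient through the perturbation
vanishes, and behavior locks at chance in the new context.

**Changepoint debouncing (vmPFC).** A block change is considered only when
the estimate has diverged from the recent reward average for two
consecutive trials; with a single-trial trigger the 10-trial window mean's
sampling noise resets a well-calibrated estimate every ~15 trials and the
estimator misses its own recovery bound at the 0.3/0.7 levels.

**Warm starts.** `simulate_experiment(..., resume = )` carries all plastic
weights and slow states from a previous run, so a trained network can be
continued under a new condition. The routing comparisons use this: one
two-block base run trains the circuit and the OFC's Hebbian routing
weights, then each routing condition (target, neuron count, signal
duration) branches from the same trained state.

**MD competition.** Several ingredients beyond the WTA sentence were needed
to reproduce context coding in MD; all are exposed in the configuration.
First, the corticothalamic drive is integrated with the same membrane time
constant as dlPFC (as stated for the MD neurons) and the MD membrane
persists across trials, which removes within-trial winner flicker. Second,
the competition compares each MD neuron's input *deviation from its own
slow running average*. With absolute inputs, whichever neuron wins first is
self-reinforcing: the centered Hebbian rule drives the loser's weights to
the negative of the winner's, and because the two contexts' population
patterns correlate positively (~+0.8 in trained networks), the winner keeps
the larger input in both contexts and MD never differentiates — no lesion
effect, no context decoding. Third, the winner enjoys a fixed hysteresis
margin (0.1) so near-tied inputs cannot flicker, and a small exploration
noise (SD 0.05) on the comparison lets the competition discover structure
while learned margins are still small. The adaptation/centering timescale is
yoked to the eligibility trace (60 x $\tau_{pre}$: 600 trials at the
2000-ms default, ~3 trials at 10 ms), so the competition operates on
deviations at the scale the trace resolves. Under this scheme block
transitions flip the winner, the Hebbian rule aligns each neuron with one
context, and context (but not cue) becomes decodable from MD — with the
long eligibility trace biasing MD toward the slow rule variable and a short
trace ($\tau_{pre}$ ~ 10 ms) toward the fast cue, as in the sweep
experiments.

**Hebbian centering.** The postsynaptic MD factor is centered on its
population mean at the current step (uniform activity contributes nothing);
the presynaptic factor is the eligibility trace's deviation from its own
slow running mean (the same yoked timescale), i.e. learning is driven by
what recently *changed* in each neuron's trace.

**MD modulation strength.** The fixed MD-to-dlPFC weights are drawn with
SD 0.1. Their dispersion is the single most consequential constant in the
model: at ~3x this value the minimal model's multiplicative sweep is
already at ceiling at factor 1 and the additive sweep collapses by factor
8 (both sweeps then contradict their reported shapes), the count of
context-indifferent cue cells falls ~4x below the reported scale, and MD
feedback degrades rather than helps behavior. At SD 0.1 the multiplicative
sweep rises toward its 0.9 ceiling across the 1-40 range, the additive
sweep shows its inverted U, and the selectivity counts land on the reported
scale.

**W_ct initialization.** Zero-mean uniform [-0.01, 0.01]; an all-positive
initialization hands one MD neuron a systematic input advantage before any
learning. The initial Frobenius norm is the rescaling target thereafter.

**Lesions.** Lesioning removes both MD-to-dlPFC pathways (additive and
multiplicative) and multiplies the recurrent weights by 1.3 to restore
activity levels; MD itself keeps running (its activity is recorded but has
no effect). Mid-run lesions apply the same change at a configured block.

**Gain sweeps.** The additive/multiplicative sweeps run the minimal model:
one MD neuron forced active per context, corticothalamic learning off, no
value inputs, and the *other* pathway's factor set to 0, since the sweep is
defined for the projections separated.

**Noise convention.** The per-step noise (variance $10^{-3}$) enters the
rate-of-change expression and is not scaled by $\sqrt{dt}$; no stochastic
calculus convention is implied or needed at fixed dt = 1 ms.

## What the synthetic task emulates — and what it does not

The task generator reproduces the block structure, association levels, cue
balance, and deterministic target feedback of the behavioral task. It does
not model stimulus rendering, presentation timing, inter-trial intervals,
lapses, or reaction times; human sessions also fix one pseudorandom block
order, whereas model-style schedules are parametric. Passing the package's
tests therefore certifies the computational claims (learning dynamics,
context gating, routing efficiency) on this idealized environment, not any
property of human subjects or neuroimaging data, which are outside the
package's scope.

## Problem sizes used by the checks

The acceptance script uses the reference sizes: five seeds of the
human-comparison preset (two 500-trial pre-training blocks, then the
10-block schedule at 10x trials) for accuracy by association level; three
seeds of the minimal forced-MD model on four 500-trial blocks for the
multiplicative ceiling; and five seeds each of the intact and lesioned
models on six 500-trial blocks for the selectivity counts. The test suite
repeats these with the human preset at three seeds and probes the ordering
properties (lesion comparisons, eligibility-trace sweeps, gain sweeps,
routing comparisons) on shorter blocks of 150-300 trials with five seeds
per ordering, sizes this model's learning pace supports; each choice is
recorded next to the test that uses it.

## Known limitations

* The MD competition requires the adaptive input baseline described above;
  a cold-started model needs a few blocks before MD context coding is
  reliable, so analyses of MD coding discard no trials but are strongest
  from the third block on.
* In this implementation the strategy-value inputs alone support fast
  post-switch recovery, so removing MD output (the lesion) does not slow
  switching the way the circuit-level account predicts, and injecting the
  OFC context signal into MD does not improve post-switch behavior (the
  corticocortical OFC route does). The tests encoding those orderings fail
  and are left failing: MD context coding here is real but not
  behaviorally load-bearing, and making it so without destroying the
  node-perturbation learning is an open problem for this codebase.
* With two MD neurons the model handles two interleaved contexts; more
  contexts would need more MD neurons and were not explored here.
* Reported accuracies are measured with the perturbation noise on, as
  during learning; an evaluation mode with `perturb = FALSE` exists but is
  not the default.
* The vmPFC bank matching reuses the divergence threshold (0.15) as its
  tolerance; the two roles are conceptually distinct but share one value.
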