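# thalamoflex

Simulation of a thalamocortical circuit model of cognitive flexibility, for
computational neuroscientists studying how the mediodorsal thalamus (MD)
regulates prefrontal computations during task switching.

## The model

A probabilistic inference task presents a tactile cue (*up*/*down*) on each
trial; responding amounts to choosing the **match** rule (repeat the cue) or
the **non-match** rule (invert it). Within a block, the match rule is
rewarded with probability 0.9, 0.7, 0.5, 0.3 or 0.1 (the *association
level*); blocks change covertly, so the rewarded rule must be inferred from
outcomes.

The circuit that solves it:

* **dlPFC** — a 500-neuron rate reservoir,
  τ dI/dt = −I + W_inp·u + (1 + g_m·m)·(W_rec·r) + g_a·m + ρ, with
  r = [tanh I]₊, fixed recurrent weights, and τ = 20 ms integrated at 1 ms.
* **MD** — two winner-take-all neurons reading dlPFC through plastic
  corticothalamic weights (Hebbian rule with a 2000-ms eligibility trace,
  clipping to ±0.1, trial-end norm rescaling). MD feeds back the modulation
  m = W_MD·r^MD both additively and as a gain on the recurrent drive; it
  comes to encode the temporal context (the dominant rule) rather than the
  cue.
* **Readout** — two linear output units trained by node perturbation:
  w ← w + μ·δe·Σ_t ζ(t) r(t), with ζ ~ U(−1,1) injected each step and δe
  the reward-prediction error.
* **vmPFC** — a maximum-likelihood estimator of the match strategy's
  expected reward q over the last 10 trials, with changepoint detection and
  a bank of previously seen values; (q, 1−q) enters dlPFC as input.
* **OFC** — a Bayesian changepoint observer holding two context-belief
  nodes, whose switch signal can be routed to dlPFC directly (1000 learned
  parameters) or through MD (4 parameters) — the transthalamic route.

Experiments built in: MD lesions (with 1.3× recurrent compensation),
mid-run lesions, additive/multiplicative gain sweeps in a minimal forced-MD
model, eligibility-trace time-constant sweeps, and OFC routing comparisons
(target, neuron count, signal duration).

## A worked example

```r
library(thalamoflex)

cfg <- tc_config(task = list(n_blocks = 6, trials_per_block = 500))
res <- simulate_experiment(cfg, seed = 1)
res
#> <tc_experiment> seed 1 - 6 blocks, 3000 trials
#>   accuracy 0.840  ratio correct 0.917 (pre-training excluded)
res$block_summary
#>   block_index association_level pretrain n_trials accuracy ratio_correct
#> 1           0               0.9    FALSE      500    0.858         0.950
#> 2           1               0.1    FALSE      500    0.724         0.780
#> 3           2               0.9    FALSE      500    0.804         0.872
#> 4           3               0.1    FALSE      500    0.886         0.958
#> 5           4               0.9    FALSE      500    0.878         0.976
#> 6           5               0.1    FALSE      500    0.888         0.968
```

Accuracy is the rewarded fraction (ceiling 0.9 in 90/10 blocks); ratio
correct is the fraction of trials whose chosen rule matches the block's
dominant rule. The first block shows learning from scratch; later blocks show recovery
after each covert rule reversal, with the first reversal (block 1) costing
the most. Trial-resolved activity is in
`res$trials` (including per-trial MD activations and the vmPFC value
estimate) and `res$rates`; `plot(res)` draws the running accuracy with block
boundaries.

Post-hoc analyses:

```r
sel <- experiment_selectivity(res)      # logistic-regression cue responsiveness
sel$counts
#> non-responsive     match-only  nonmatch-only           both
#>            181             98            130             91
decode_variable(res$trials$md_avg,      # context is decodable from MD
                as.integer(res$trials$association_level > 0.5))
#> [1] 0.7
```

A thin CLI wraps the same functions:

```sh
exec/thalamoflex run --experiment performance --seeds 3 --out out/
exec/thalamoflex sweep --experiment minimal_forced_md --grid "g_mult=1,10,40" --out out/
```

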