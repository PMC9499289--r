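# Example experiment configuration for the command-line tool.
# Any key omitted falls back to the package defaults (tc_config()).
task:
  mode: model_style
  n_blocks: 6
  trials_per_block: 500
  levels: [0.9, 0.1]
md:
  tau_pre_ms: 2000
  g_add: 1
  g_mult: 1
readout:
  mu: 5.0e-5
  baseline_decay: 0.1
vmpfc:
  enabled: true
  horizon: 10
  divergence_threshold: 0.15
ofc:
  route_target: "off"
record_rates: true
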