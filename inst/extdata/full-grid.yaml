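# The full 36-scenario design: 3 cohort sizes x 2 treatment prevalences
# x 2 outcome prevalences x 3 true odds ratios, both matching algorithms,
# both caliper widths, 1000 repetitions each.
reps: 1000
master_seed: 1
algorithms: [caliper_random, nn_caliper]
caliper_multipliers: [0.2, 0.01]
n_cal: 1000000
grid:
  n: [500, 2500, 10000]
  p_treat: [0.2, 0.5]
  p_outcome: [0.1, 0.5]
  true_or: [0.75, 1.0, 1.5]
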