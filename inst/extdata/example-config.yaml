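# Minimal run configuration: two explicit scenarios, default covariates.
reps: 200
master_seed: 42
algorithms: [caliper_random, nn_caliper]
caliper_multipliers: [0.2]
n_cal: 1000000
scenarios:
  - {n: 2500, p_treat: 0.2, p_outcome: 0.5, true_or: 0.75}
  - {n: 2500, p_treat: 0.5, p_outcome: 0.1, true_or: 1.5}
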