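# Example study grid for `raschgof study` / read_study_config().
# Desk-scale replication counts; raise `reps` for stable rates.
alphas: [0.05, 0.01]
tests: [LR, T10, T11, M2]
conditions:
  - {family: rasch,       N: 200, n: 10, reps: 50, seed: 101, B: 300}
  - {family: multidim,    N: 200, n: 10, reps: 50, seed: 102, r: 0.3, B: 300}
  - {family: twopl,       N: 200, n: 10, reps: 50, seed: 103, log_var: 0.25, B: 300}
  - {family: mixed_rasch, N: 200, n: 10, reps: 50, seed: 104, dif_frac: 0.4, B: 300}
  - {family: guessing,    N: 200, n: 10, reps: 50, seed: 105, gamma: 0.25, B: 300}
  - {family: surface_ld,  N: 200, n: 10, reps: 50, seed: 106, overwrite_prob: 0.9, B: 300}
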