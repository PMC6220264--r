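# Demo run: simulate a four-occasion achievement cohort under the default
# simplex regime, prepare the phenotypes, and fit the simplex and common
# pathway models.
output_dir: demo_out
seed: 42
restarts: 3
simulate:
  model: simplex
  n_mz: 600
  n_dz: 600
  params: achievement
preprocess: true
measures: [ach_t1, ach_t2, ach_t3, ach_t4]
models: [simplex, cpm]
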