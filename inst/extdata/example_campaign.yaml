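# Example campaign configuration for the CLI.
# All keys are optional; omitted ones take the package defaults
# (full-size campaign: n_init 13, batch 5, NSGA-II 100x100).
n_init: 13
seed: 1
restarts: 10
space:
  sorbitol: [0, 550]
  arginine: [0, 250]
  ph: [4.5, 7.5]
  histidine: 10
  osmolality: [100, 600]
acquisition:
  p_exploit: 0.75
  batch_size: 5
  explore_starts: 20
  distance_weight: 0.5
  pop: 100
  gens: 100
lab:
  tm_noise_C: 0.2
  kd_noise: 1.5
  rm_noise_pct: 2
  dls_noise_rel: 0.005
  replicates: 3
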