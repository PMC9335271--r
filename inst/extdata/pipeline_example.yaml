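out_dir: chemspacer_run
seed: 1
generate:
  years: [1800, 1824]
  base_count: 6
  growth: 1.06
  seed: 1
backbone_threshold: 60
ubiquity_sizes: [20, 50, 80]
ubiquity_reps: 25
taus: [0.05, 0.10, 0.20]
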