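# Example study grid for run_study(): a desk-scale false-positive study on
# the short scale plus one non-invariance cell.
n_reps: 50
seed: 20260
engines: [ccfa_scale, ccfa_item, irt, lor]
parameters: [loadings, thresholds]
criteria:
  alpha: 0.05
  delta_rmsea_cut: 0.01
  delta_cfi_cut: -0.01
  delta_r2_cut: 0.02
conditions:
  - n_items: 5
    n_categories: 3
    n_per_group: 250
  - n_items: 5
    n_categories: 3
    n_per_group: 250
    pct_threshold: 40
    alignment: misaligned
    magnitude: large
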