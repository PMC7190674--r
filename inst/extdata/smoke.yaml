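scenario: smoke
seed: 1
events:
  n_events: 200
  n_true: 20
  dpsi: 0.3
  psi_a: 0.4
  depth: 200
  n_replicates: 3
thresholds:
  dpsi: 0.1
  fdr: 0.1
cohort:
  n_patients: 40
  p_amp: 0.1
  p_del: 0.1
  p_mut: 0.02
  delta: 2
  hazard_coef: 1.0986
  baseline_rate: 0.1
  censoring: 0.3
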