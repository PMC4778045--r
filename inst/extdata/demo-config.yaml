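# Demo screen configuration: 8000-member NNK triad library with a single
# high-affinity member, Poisson-loaded at lambda = 0.1 into one million
# drops and sorted at normalized fluorescence 1.3.
design:
  scaffold: TSFAEYWNLLSP
  variable_positions: [3, 7, 10]
  codons: NNK
screen:
  lam: 0.1
  n_drops: 1000000
  threshold: 1.3
  binders: [FWL]
  leakage_rate: 0.2
  drop_volume_pl: 7.2
  seed: 20160304
fluorescence:
  baseline: 1.0
  increment: 1.0
  cooperativity: 1.35
  noise_sd: 0.10
  noise_limit: 3
  width_gate_outlier_rate: 0.01
amplification:
  transcripts_per_template: 300
  efficiency_sd: 1.0
  cycles: 35
reads:
  read_length: 56
  upstream_context: 10
  max_mismatches_per_anchor: 1
  n_reads: 20000
  error_rate: 0.005
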