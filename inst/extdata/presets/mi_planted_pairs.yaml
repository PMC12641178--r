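# Network-recovery preset: one homogeneous population with every gene an
# independent Bernoulli(0.5) baseline and exactly five strongly co-varying
# pairs planted, so thresholded-network recovery and false-edge counts have
# unambiguous truth labels.
name: mi_planted_pairs
version: 1
group: CPR
classes:
  Uniform: 505
retention:
  rbf_core: []
  rbf_core_p: 0.5
  rbf_background_p: 0.5
  rp_p: 0.5
  gene_overrides: {}
  class_knockouts: {}
  knockout_p: 0.5
planted_pairs:
  - {driver: groEL, partner: groES, strength: 0.95}
  - {driver: dnaK, partner: dnaJ, strength: 0.95}
  - {driver: rimM, partner: rimP, strength: 0.95}
  - {driver: rsmE, partner: rsmI, strength: 0.95}
  - {driver: rnt, partner: rph, strength: 0.95}
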