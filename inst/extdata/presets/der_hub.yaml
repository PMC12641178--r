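# Hub-recovery preset: der planted to co-vary with six partners (its uL1,
# ribonuclease and modification-enzyme neighbours in the dependency network)
# over an otherwise independent Bernoulli(0.5) baseline.
name: der_hub
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
  - {driver: der, partner: rplA, strength: 0.90}
  - {driver: der, partner: yqgF, strength: 0.90}
  - {driver: der, partner: rlmD, strength: 0.90}
  - {driver: der, partner: rlmH, strength: 0.90}
  - {driver: der, partner: rluB, strength: 0.90}
  - {driver: der, partner: rsmA, strength: 0.90}
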