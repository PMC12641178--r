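# Helix-shortening preset: a small cohort per class with class-specific
# shortening planted in H12, H58 and H78, for seed-comparison and H78
# classification checks. H78 carries the full set of variant states (full,
# mid-stem, short-stem, absent).
name: helix_fig4b
version: 1
group: CPR
classes:
  Paceibacteria: 12
  Microgenomatia: 12
  ABY1: 12
  Saccharimonadia: 12
  Dojkabacteria: 12
  Gracilibacteria: 12
  WWE3: 12
  Berkelbacteria: 12
retention:
  rbf_core: []
  rbf_core_p: 0.5
  rbf_background_p: 0.5
  rp_p: 0.5
  gene_overrides: {}
  class_knockouts: {}
  knockout_p: 0.5
planted_pairs: []
alignment:
  ref_length: 240
  helix_plan:
    - {class: ABY1, helix_id: H78, keep_stem: 0}
    - {class: WWE3, helix_id: H78, keep_stem: 0}
    - {class: Microgenomatia, helix_id: H78, keep_stem: 0}
    - {class: Dojkabacteria, helix_id: H78, keep_stem: 7}
    - {class: Saccharimonadia, helix_id: H78, keep_stem: 6}
    - {class: Gracilibacteria, helix_id: H78, keep_stem: 3}
    - {class: Paceibacteria, helix_id: H12, keep_stem: 6}
    - {class: Dojkabacteria, helix_id: H12, keep_stem: 6}
    - {class: Saccharimonadia, helix_id: H58, keep_stem: 7}
    - {class: Gracilibacteria, helix_id: H58, keep_stem: 7}
  inserts: []
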