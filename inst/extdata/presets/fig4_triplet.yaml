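# Triplet co-evolution preset: the paper_like class structure restricted to
# what the der/rplA/H78 analysis consumes. Gene content is generated as in
# paper_like_cpr; helix 78 states come from a planted structure alignment:
# absent in ABY1/WWE3/Microgenomatia, mid-stem (6-8 bp) and short-stem
# (2-3 bp) variants in other classes, full-length elsewhere. A small insert
# (unaligned lowercase residues inside the 5' strand) is planted in
# Dojkabacteria to exercise insert handling.
name: fig4_triplet
version: 1
group: CPR
classes:
  Paceibacteria: 125
  Microgenomatia: 105
  ABY1: 85
  Saccharimonadia: 55
  Dojkabacteria: 45
  Gracilibacteria: 40
  WWE3: 32
  Berkelbacteria: 18
retention:
  rbf_core: [lepA, ychF, bipA, rnj, rnc, pnp, rsmH, rluD, groEL, groES,
             dnaK, dnaJ, grpE, rbgA, engB, rimO, rel, yhbH, yheS, hflX]
  rbf_core_p: 0.97
  rbf_background_p: 0.05
  rp_p: 0.93
  gene_overrides:
    der: 0.95
    obgE: 0.72
    era: 0.90
    rbfA: 0.90
    rplA: 0.95
    rplI: 0.95
  class_knockouts:
    der: [Paceibacteria, Dojkabacteria, WWE3, Microgenomatia]
    obgE: [ABY1]
    era: [Paceibacteria, Dojkabacteria, WWE3, Saccharimonadia]
    rbfA: [ABY1, Dojkabacteria, WWE3, Saccharimonadia]
    rplA: [Paceibacteria]
    rplI: [Gracilibacteria]
  knockout_p: 0.02
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
  inserts:
    - {class: Dojkabacteria, helix_id: H78, len: 2}
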