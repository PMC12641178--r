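# Synthetic genome-collection preset emulating the statistical structure of
# a CPR (Patescibacteria) genome survey: 505 genomes over the eight most
# represented classes, a conserved RBF core with sparse background retention
# calibrated so the median per-genome RBF count is 25, class-specific
# knockouts of the focal biogenesis genes (der/obgE/era/rbfA) and the two
# lineage-variable ribosomal proteins (rplA/rplI), chaperone-operon style
# co-occurrence pairs, and class-level loss of 23S helix 78.
name: paper_like_cpr
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
    groEL: 0.87
    groES: 0.87
  class_knockouts:
    der: [Paceibacteria, Dojkabacteria, WWE3, Microgenomatia]
    obgE: [ABY1]
    era: [Paceibacteria, Dojkabacteria, WWE3, Saccharimonadia]
    rbfA: [ABY1, Dojkabacteria, WWE3, Saccharimonadia]
    rplA: [Paceibacteria]
    rplI: [Gracilibacteria]
  knockout_p: 0.02
planted_pairs:
  - {driver: groEL, partner: groES, strength: 0.95}
  - {driver: dnaK, partner: dnaJ, strength: 0.90}
  - {driver: rimM, partner: rimP, strength: 0.90}
  - {driver: rsmE, partner: rsmI, strength: 0.85}
  - {driver: rnt, partner: rph, strength: 0.85}
h78:
  retention_p: 0.97
  knockout_classes: [ABY1, WWE3, Microgenomatia]
  knockout_p: 0.02
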