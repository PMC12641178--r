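Package: rbfcoevo
Title: Co-Evolution of Ribosome Biogenesis Factors, Ribosomal Proteins and
    rRNA Structure Across Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of ribosome biogenesis factor (RBF) and
    ribosomal protein (RP) gene content across bacterial genomes, with a
    focus on reduced-genome lineages such as the Candidate Phyla Radiation
    (CPR/Patescibacteria). Builds binary gene presence/absence matrices from
    functional annotations, profiles per-group gene conservation ratios,
    computes mutual-information dependency networks between gene occurrence
    profiles, reconstructs gene gain/loss histories on a phylogeny by Fitch
    parsimony, encodes der/rplA/H78 triplet states and their co-evolution
    trajectories, and measures rRNA helix lengths from structure-annotated
    alignments. A deterministic synthetic-data generator emulates the
    statistical structure of such genome collections so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
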