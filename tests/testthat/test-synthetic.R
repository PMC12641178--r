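test_that("generators are byte-deterministic under a fixed seed", {
  g1 <- gen_preset("helix_fig4b", seed = 42)
  g2 <- gen_preset("helix_fig4b", seed = 42)
  expect_identical(g1$pa$mat, g2$pa$mat)
  expect_identical(ape::write.tree(g1$tree), ape::write.tree(g2$tree))
  expect_identical(g1$alignment$aln$seqs, g2$alignment$aln$seqs)
  g3 <- gen_preset("helix_fig4b", seed = 43)
  expect_false(identical(g1$pa$mat, g3$pa$mat))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotations_tsv(g1$pa, f1); write_annotations_tsv(g2$pa, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated marginals converge to the configured retention", {
  cfg <- list(name = "conv", group = "CPR", classes = c(Uniform = 1000L),
              retention = list(rbf_core = list(), rbf_core_p = 0.5,
                               rbf_background_p = 0.30, rp_p = 0.80,
                               gene_overrides = list(der = 0.38),
                               class_knockouts = list(), knockout_p = 0.02),
              planted_pairs = list())
  gm <- gen_matrix(cfg, seed = 99)
  n <- 1000
  freq <- colMeans(gm$pa$mat)
  check <- function(gene, p)
    expect_lt(abs(freq[[gene]] - p), 3 * sqrt(p * (1 - p) / n))
  check("der", 0.38)
  check("rplA", 0.80)
  check("obgE", 0.30)
})

test_that("planted co-variation strength is monotone in recovered MI", {
  mis <- vapply(c(0.2, 0.5, 0.8, 0.95), function(s) {
    cfg <- list(name = "mono", group = "CPR", classes = c(Uniform = 800L),
                retention = list(rbf_core = list(), rbf_core_p = 0.5,
                                 rbf_background_p = 0.5, rp_p = 0.5,
                                 gene_overrides = list(),
                                 class_knockouts = list(), knockout_p = 0.5),
                planted_pairs = list(list(driver = "groEL",
                                          partner = "groES", strength = s)))
    gm <- gen_matrix(cfg, seed = 7)
    mutual_information(gm$pa$mat[, "groEL"], gm$pa$mat[, "groES"])
  }, 0)
  expect_true(all(diff(mis) > 0))
})

test_that("degenerate planted configurations behave exactly", {
  cfg <- list(name = "deg", group = "CPR", classes = c(Uniform = 50L),
              retention = list(rbf_core = list(), rbf_core_p = 0.5,
                               rbf_background_p = 0.5, rp_p = 0.5,
                               gene_overrides = list(rimM = 0),
                               class_knockouts = list(), knockout_p = 0.5),
              planted_pairs = list(list(driver = "groEL", partner = "groES",
                                        strength = 1.0)))
  gm <- gen_matrix(cfg, seed = 5)
  expect_identical(gm$pa$mat[, "groEL"], gm$pa$mat[, "groES"])
  expect_true(all(gm$pa$mat[, "rimM"] == 0L))
  bad <- cfg
  bad$planted_pairs <- list(list(driver = "groEL", partner = "groES",
                                 strength = 1.5))
  expect_error(gen_matrix(bad, seed = 1), "strength")
  bad2 <- cfg
  bad2$retention$gene_overrides <- list(der = 1.4)
  expect_error(gen_matrix(bad2, seed = 1), "\\[0, 1\\]")
})

test_that("random trees are rooted, binary and class-monophyletic", {
  expect_equal(length(gen_tree(2, seed = 1)$tree$tip.label), 2L)
  t1 <- gen_tree(c(A = 5, B = 7, C = 3), seed = 10)
  expect_identical(ape::write.tree(t1$tree),
                   ape::write.tree(gen_tree(c(A = 5, B = 7, C = 3),
                                            seed = 10)$tree))
  expect_true(ape::is.rooted(t1$tree))
  expect_true(ape::is.binary(t1$tree))
  for (cl in c("A", "B", "C")) {
    tips <- names(t1$class_map)[t1$class_map == cl]
    expect_true(ape::is.monophyletic(t1$tree, tips))
  }
  big <- gen_tree(c(A = 60, B = 45, C = 30, D = 20), seed = 3)
  for (cl in c("A", "B", "C", "D"))
    expect_true(ape::is.monophyletic(
      big$tree, names(big$class_map)[big$class_map == cl]))
  expect_error(gen_tree(1, seed = 1), "at least 2 leaves")
})

test_that("simulated histories respect their rates and bound the parsimony score", {
  tr <- gen_tree(64, seed = 2)$tree
  none <- simulate_history(tr, gain = 0, loss = 0, root_state = 1, seed = 4)
  expect_true(all(none$tip_states == 1L))
  expect_equal(none$n_events, 0L)

  lossy <- simulate_history(tr, gain = 0, loss = 0.3, root_state = 1,
                            seed = 4)
  expect_true(all(lossy$events$event == "loss"))
  fit <- fitch_reconstruct(tr, lossy$tip_states)
  expect_lte(fit$score, lossy$n_events)       # parsimony is a lower bound

  # low-rate regime: parsimony usually recovers the exact event count
  hits <- 0L; total <- 60L
  for (i in seq_len(total)) {
    h <- simulate_history(tr, gain = 0.02, loss = 0.02, root_state = 1,
                          seed = 100 + i)
    f <- fitch_reconstruct(tr, h$tip_states)
    hits <- hits + (f$score == h$n_events)
  }
  expect_gte(hits / total, 0.9)
})

test_that("alignment generator plants deletions and inserts exactly", {
  genomes <- data.frame(genome_id = c("x1", "x2", "y1"),
                        taxon_class = c("X", "X", "Y"))
  ga <- gen_alignment(genomes, helix_plan = NULL, seed = 6)
  map <- map_reference_coordinates(ga$aln, synthetic_helix_table())
  lens <- helix_lengths(ga$aln, map)
  expect_true(all(lens$length[lens$seq_id != "reference"] ==
                    ga$seed_lengths[lens$helix_id[lens$seq_id != "reference"]]))

  plan <- data.frame(class = "X", helix_id = "H78", keep_stem = 8L)
  ga2 <- gen_alignment(genomes, helix_plan = plan, seed = 6)
  lens2 <- helix_lengths(ga2$aln,
                         map_reference_coordinates(ga2$aln,
                                                   synthetic_helix_table()))
  h78 <- lens2[lens2$helix_id == "H78", ]
  expect_equal(h78$length[h78$seq_id == "x1"],
               ga2$seed_lengths[["H78"]] - 4L)  # 2 bases cut per strand
  expect_equal(h78$length[h78$seq_id == "y1"], ga2$seed_lengths[["H78"]])
  expect_equal(h78$stem[h78$seq_id == "x1"], 8L)

  expect_error(gen_alignment(genomes,
                             helix_plan = data.frame(class = "X",
                                                     helix_id = "H78",
                                                     keep_stem = 99L),
                             seed = 1), "outside helix")
})

test_that("preset truth labels agree with measured helix profiles", {
  gp <- gen_preset("helix_fig4b", seed = 11, tree = FALSE)
  al <- gp$alignment
  map <- map_reference_coordinates(al$aln, synthetic_helix_table())
  lens <- helix_lengths(al$aln, map, rows = setdiff(names(al$aln$seqs),
                                                    "reference"))
  merged <- merge(lens, al$truth, by = c("seq_id", "helix_id"))
  expect_true(all(merged$length.x == merged$length.y))
  expect_true(all(merged$stem.x == merged$stem.y))

  cmp <- compare_to_seed(lens, al$seed_lengths,
                         setNames(gp$pa$metadata$taxon_class,
                                  gp$pa$metadata$genome_id))
  planted <- c("H78.ABY1", "H78.WWE3", "H78.Microgenomatia",
               "H78.Dojkabacteria", "H78.Saccharimonadia",
               "H78.Gracilibacteria", "H12.Paceibacteria",
               "H12.Dojkabacteria", "H58.Saccharimonadia",
               "H58.Gracilibacteria")
  got <- paste(cmp$helix_id, cmp$taxon_class, sep = ".")[cmp$shortened]
  expect_setequal(got, planted)
})
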