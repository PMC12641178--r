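# A tiny hand-built alignment: reference of 30 bases with one helix
# ("HX": 5' positions 3-8, 3' positions 15-20).
tiny_table <- function() {
  validate_helix_table(data.frame(
    helix_id = "HX", molecule = "23S", fp_start = 3L, fp_end = 8L,
    tp_start = 15L, tp_end = 20L))
}
tiny_ref <- strrep("ACGUA", 6)

test_that("stockholm round trip preserves rows and consensus structure", {
  aln <- structure_alignment(
    c(reference = "ACGU-ACGU", seq1 = "AC--GACGU"), ref = "reference",
    ss_cons = "<<<....>>")
  f <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(aln, f)
  back <- read_stockholm(f)
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$ss_cons, aln$ss_cons)
  expect_identical(back$ref, "reference")
})

test_that("interleaved stockholm blocks are concatenated", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "", "seqA ACGU", "seqB AC-U",
               "#=GC SS_cons <..>", "", "seqA ACGU", "seqB A--U",
               "#=GC SS_cons <..>", "//"), f)
  aln <- read_stockholm(f)
  expect_equal(unname(aln$seqs["seqA"]), "ACGUACGU")
  expect_equal(unname(aln$seqs["seqB"]), "AC-UA--U")
  expect_equal(aln$ss_cons, "<..><..>")
  expect_error(read_stockholm(withr::local_tempfile(lines = "plain text")),
               "not a Stockholm")
})

test_that("alignment containers validate shape and reference", {
  expect_error(structure_alignment(c(a = "ACGU", b = "ACG"), ref = "a"),
               "differ in length")
  expect_error(structure_alignment(c(a = "ACGU"), ref = "zz"),
               "reference row not found")
  expect_error(structure_alignment(c(a = "ACGU"), ref = "a", ss_cons = "<"),
               "SS_cons length")
})

test_that("helix tables validate coordinates and completeness", {
  expect_s3_class(tiny_table(), "helix_table")
  expect_error(validate_helix_table(data.frame(
    helix_id = "H1", molecule = "23S", fp_start = 5L, fp_end = 3L,
    tp_start = 10L, tp_end = 12L)), "start > end")
  expect_error(validate_helix_table(data.frame(
    helix_id = "H1", molecule = "23S", fp_start = 3L, fp_end = 12L,
    tp_start = 10L, tp_end = 14L)), "precede")
  expect_error(validate_helix_table(data.frame(
    helix_id = "H1", molecule = "18S", fp_start = 1L, fp_end = 2L,
    tp_start = 5L, tp_end = 6L)), "unknown molecule")
  expect_error(read_helix_table(system.file(
    "extdata", "synthetic_helix_table.tsv", package = "rbfcoevo"),
    complete = TRUE), "incomplete helix table")
})

test_that("reference coordinate mapping handles gaps and round-trips", {
  tab <- tiny_table()
  # ungapped reference: columns equal coordinates
  aln <- structure_alignment(c(reference = tiny_ref), ref = "reference")
  map <- map_reference_coordinates(aln, tab)
  expect_equal(map$HX$fp_span, 3:8)
  expect_equal(map$HX$tp_match, 15:20)

  # one leading gap column shifts everything by one
  aln2 <- structure_alignment(c(reference = paste0("-", tiny_ref),
                                other = paste0("A", tiny_ref)),
                              ref = "reference")
  map2 <- map_reference_coordinates(aln2, tab)
  expect_equal(map2$HX$fp_span, 4:9)

  # random gapping: mapping composed with gap stripping recovers coordinates
  set.seed(21)
  for (i in 1:10) {
    chars <- strsplit(tiny_ref, "")[[1]]
    gapped <- character(0)
    for (ch in chars)
      gapped <- c(gapped, sample(c(".", "-"), rpois(1, 0.5), replace = TRUE),
                  ch)
    g <- paste(gapped, collapse = "")
    m <- map_reference_coordinates(
      structure_alignment(c(reference = g), ref = "reference"), tab)
    cols <- strsplit(g, "")[[1]]
    recovered <- cumsum(!rbfcoevo:::is_gap(cols))[m$HX$fp_match]
    expect_equal(recovered, 3:8)
  }

  bad <- validate_helix_table(data.frame(
    helix_id = "HY", molecule = "23S", fp_start = 3L, fp_end = 8L,
    tp_start = 25L, tp_end = 40L))
  expect_error(map_reference_coordinates(aln, bad), "HY.*beyond reference")
})

test_that("helix lengths count bases, not gaps, and respect inserts", {
  tab <- tiny_table()
  ref <- tiny_ref
  row_del <- paste0(substr(ref, 1, 4), "----", substr(ref, 9, 30)) # 4 bases cut
  row_gap <- paste0(substr(ref, 1, 2), strrep("-", 6),
                    substr(ref, 9, 30))                            # 5' all gone
  aln <- structure_alignment(c(reference = ref, full = ref, del = row_del,
                               nofp = row_gap), ref = "reference")
  map <- map_reference_coordinates(aln, tab)
  lens <- helix_lengths(aln, map)
  get <- function(id, col) lens[lens$seq_id == id, col]
  expect_equal(get("full", "length"), 12L)      # identical to reference
  expect_equal(get("full", "stem"), 6L)
  expect_equal(get("del", "length"), 8L)        # 12 - 4
  expect_equal(get("nofp", "fp_bases"), 0L)
  expect_equal(get("nofp", "stem"), 0L)

  # all-gap columns added anywhere leave lengths invariant
  pad <- function(s) paste0(substr(s, 1, 10), "..", substr(s, 11, 30))
  aln_pad <- structure_alignment(vapply(aln$seqs, pad, ""), ref = "reference")
  lens_pad <- helix_lengths(aln_pad, map_reference_coordinates(aln_pad, tab))
  expect_equal(lens_pad$length, lens$length)

  # lowercase insert inside the 5' segment: counts for length, not stem
  ins <- function(s) paste0(substr(s, 1, 5), "aa", substr(s, 6, 30))
  aln_ins <- structure_alignment(
    c(reference = paste0(substr(ref, 1, 5), "..", substr(ref, 6, 30)),
      withins = ins(ref)), ref = "reference")
  lens_ins <- helix_lengths(aln_ins, map_reference_coordinates(aln_ins, tab))
  wi <- lens_ins[lens_ins$seq_id == "withins", ]
  expect_equal(wi$length, 14L)
  expect_equal(wi$stem, 6L)

  # total helix bases never exceed the ungapped row length
  for (r in names(aln$seqs)) {
    ungapped <- sum(!rbfcoevo:::is_gap(strsplit(aln$seqs[[r]], "")[[1]]))
    expect_lte(sum(lens$length[lens$seq_id == r]), ungapped)
  }
})

test_that("planted deletions shift class medians past the seed bound", {
  lens <- data.frame(seq_id = rep(c("s1", "s2", "s3", "s4"), each = 1),
                     helix_id = "HX",
                     length = c(12, 12, 7, 7))
  seed_len <- c(HX = 12)
  classes <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  cmp <- compare_to_seed(lens, seed_len, classes)
  expect_equal(cmp$shortened[cmp$taxon_class == "A"], FALSE)
  expect_equal(cmp$shortened[cmp$taxon_class == "B"], TRUE)
  # equality at seed - min_reduction counts as shortened
  cmp2 <- compare_to_seed(lens, seed_len, classes, min_reduction = 5L)
  expect_equal(cmp2$shortened[cmp2$taxon_class == "B"], TRUE)
  cmp3 <- compare_to_seed(lens, seed_len, classes, min_reduction = 6L)
  expect_equal(cmp3$shortened[cmp3$taxon_class == "B"], FALSE)
})

test_that("H78 classification is total and flags between-class stems", {
  lens <- data.frame(seq_id = sprintf("s%d", 1:8), helix_id = "H78",
                     stem = c(10, 9, 7, 3, 2, 0, 4, 5),
                     length = NA, fp_bases = NA, tp_bases = NA)
  cl <- classify_h78(lens, seed_stem = 10)
  expect_equal(cl$h78_class,
               c("full", "full", "mid_stem", "short_stem", "short_stem",
                 "absent", "short_stem", "mid_stem"))
  expect_equal(cl$ambiguous, c(rep(FALSE, 6), TRUE, TRUE))
  expect_false(anyNA(cl$h78_class))
  expect_error(classify_h78(lens[lens$helix_id == "H99", ], 10), "not mapped")

  calls <- h78_presence_calls(cl)
  expect_equal(unname(calls), c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L))
})
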