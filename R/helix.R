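# rRNA helix length metrics from structure-annotated multiple alignments.
#
# Conventions: helix coordinates are 1-based inclusive in reference
# (E. coli-style) nucleotide numbering, with a 5' and a 3' strand segment per
# helix (CRW style). Alignment columns are 1-based. Gap symbols are '.', '-'
# and '~'; lowercase residues mark insert states relative to the consensus:
# they count toward helix length but are excluded from stem-pairing
# estimates, since insert columns are not aligned to the consensus structure
# (and intervening intron-like sequence inside a helix therefore does not
# inflate the stem).

#' Structure-annotated multiple alignment
#'
#' Lightweight container for an aligned set of sequences with a designated
#' reference row and optional consensus secondary-structure line.
#' `read_stockholm()` parses (possibly interleaved) Stockholm 1.0, honouring
#' `#=GC SS_cons` and `#=GC RF`; `read_alignment()` also accepts aligned
#' FASTA (via Biostrings) with a named reference row.
#'
#' @param seqs Named character vector of equal-length aligned rows.
#' @param ref Name of the reference row.
#' @param ss_cons Optional consensus structure annotation string.
#' @return Object of class `structure_alignment`.
#' @export
structure_alignment <- function(seqs, ref, ss_cons = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  if (!ref %in% names(seqs))
    stop("reference row not found: ", ref, call. = FALSE)
  if (!is.null(ss_cons) && nchar(ss_cons) != nchar(seqs[[1]]))
    stop("SS_cons length does not match the alignment", call. = FALSE)
  structure(list(seqs = seqs, ref = ref, ss_cons = ss_cons),
            class = "structure_alignment")
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat(sprintf("structure alignment: %d rows x %d columns (reference: %s%s)\n",
              length(x$seqs), nchar(x$seqs[[1]]), x$ref,
              if (is.null(x$ss_cons)) "" else ", SS_cons present"))
  invisible(x)
}

#' @rdname structure_alignment
#' @param path Input file.
#' @export
read_stockholm <- function(path, ref = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file: ", path, call. = FALSE)
  seqs <- character(0); gc <- character(0)
  for (ln in lines[-1]) {
    if (ln == "//" ) break
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#=GC ")) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      cur <- if (f[2] %in% names(gc)) gc[[f[2]]] else ""
      gc[f[2]] <- paste0(cur, f[3])
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) != 2L) stop("malformed sequence line: ", ln, call. = FALSE)
      cur <- if (f[1] %in% names(seqs)) seqs[[f[1]]] else ""
      seqs[f[1]] <- paste0(cur, f[2])
    }
  }
  if (!length(seqs)) stop("no sequences in ", path, call. = FALSE)
  structure_alignment(seqs, ref = ref %||% names(seqs)[1],
                      ss_cons = if ("SS_cons" %in% names(gc)) gc[["SS_cons"]])
}

#' @rdname structure_alignment
#' @param aln A `structure_alignment`.
#' @export
write_stockholm <- function(aln, path) {
  w <- max(nchar(names(aln$seqs)), nchar("#=GC SS_cons"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s %s", w, names(aln$seqs), aln$seqs), con)
  if (!is.null(aln$ss_cons))
    writeLines(sprintf("%-*s %s", w, "#=GC SS_cons", aln$ss_cons), con)
  writeLines("//", con)
  invisible(path)
}

#' @rdname structure_alignment
#' @param format `"stockholm"` or `"fasta"`.
#' @export
read_alignment <- function(path, format = c("stockholm", "fasta"),
                           ref = NULL) {
  format <- match.arg(format)
  if (format == "stockholm") return(read_stockholm(path, ref = ref))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA alignments", call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (is.null(ref)) stop("a reference row name is required for FASTA input",
                         call. = FALSE)
  structure_alignment(stats::setNames(as.character(ss), names(ss)), ref = ref)
}

#' Read a CRW-style helix coordinate table
#'
#' TSV with columns `helix_id`, `molecule` (5S/16S/23S), `fp_start`, `fp_end`,
#' `tp_start`, `tp_end`: the 5' and 3' strand segments of each helix in
#' 1-based inclusive reference numbering. When `complete = TRUE` the table is
#' additionally required to carry the full helix complement per molecule
#' (50 for 16S, 5 for 5S, 100 for 23S).
#'
#' @param path TSV file.
#' @param complete Enforce full per-molecule helix counts.
#' @return Data.frame of class `helix_table`.
#' @export
read_helix_table <- function(path, complete = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("helix_id", "molecule", "fp_start", "fp_end",
                             "tp_start", "tp_end"), "helix table")
  validate_helix_table(df, complete = complete)
}

#' @rdname read_helix_table
#' @param table Helix table data.frame.
#' @export
validate_helix_table <- function(table, complete = FALSE) {
  bad <- setdiff(unique(table$molecule), c("5S", "16S", "23S"))
  if (length(bad)) stop("unknown molecule: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  with(table, {
    if (any(fp_start > fp_end) || any(tp_start > tp_end))
      stop("helix segment start > end", call. = FALSE)
    if (any(fp_end >= tp_start))
      stop("5' segment must precede 3' segment", call. = FALSE)
  })
  if (anyDuplicated(table$helix_id))
    stop("duplicate helix_id", call. = FALSE)
  if (complete) {
    want <- c(`16S` = 50L, `5S` = 5L, `23S` = 100L)
    got <- table(factor(table$molecule, names(want)))
    if (!all(got == want))
      stop("incomplete helix table: expected 50/5/100 helices for 16S/5S/23S",
           call. = FALSE)
  }
  class(table) <- c("helix_table", "data.frame")
  table
}

#' Map reference helix coordinates onto alignment columns
#'
#' Walks the reference row, assigning each ungapped reference position its
#' alignment column, and returns for each helix segment both the full column
#' span (which may include insert columns, i.e. columns gapped in the
#' reference) and the reference-aligned match columns within it.
#'
#' @param aln A `structure_alignment`.
#' @param table A `helix_table`.
#' @return Named list per helix: `fp_span`, `tp_span` (integer column
#'   vectors), `fp_match`, `tp_match` (match columns only). Attribute
#'   `ref_length` is the ungapped reference length.
#' @export
map_reference_coordinates <- function(aln, table) {
  refchars <- strsplit(aln$seqs[[aln$ref]], "")[[1]]
  resid <- !is_gap(refchars)
  col_of <- which(resid)            # col_of[k] = column of reference pos k
  ref_len <- length(col_of)
  seg <- function(from, to, hx) {
    if (to > ref_len)
      stop(sprintf("helix %s: coordinate %d beyond reference length %d",
                   hx, to, ref_len), call. = FALSE)
    list(span = seq(col_of[from], col_of[to]),
         match = col_of[from:to])
  }
  out <- lapply(seq_len(nrow(table)), function(i) {
    fp <- seg(table$fp_start[i], table$fp_end[i], table$helix_id[i])
    tp <- seg(table$tp_start[i], table$tp_end[i], table$helix_id[i])
    list(fp_span = fp$span, tp_span = tp$span,
         fp_match = fp$match, tp_match = tp$match)
  })
  names(out) <- table$helix_id
  attr(out, "ref_length") <- ref_len
  out
}

#' Per-sequence helix lengths and stem estimates
#'
#' For every (sequence, helix) pair: the ungapped base count across both
#' strand segments (insert-state residues included) and the stem-length
#' estimate `min(5' match residues, 3' match residues)` — a deterministic
#' sequence-level approximation to the paired stem length of a
#' covariance-model alignment.
#'
#' @param aln A `structure_alignment`.
#' @param map Result of [map_reference_coordinates()].
#' @param rows Row names to measure (default: all).
#' @return Data.frame (seq_id, helix_id, fp_bases, tp_bases, length, stem).
#' @export
helix_lengths <- function(aln, map, rows = names(aln$seqs)) {
  chars <- lapply(aln$seqs[rows], function(s) strsplit(s, "")[[1]])
  out <- do.call(rbind, lapply(rows, function(r) {
    cc <- chars[[r]]
    res <- !is_gap(cc)
    do.call(rbind, lapply(names(map), function(h) {
      m <- map[[h]]
      fp <- sum(res[m$fp_span]); tp <- sum(res[m$tp_span])
      data.frame(seq_id = r, helix_id = h, fp_bases = fp, tp_bases = tp,
                 length = fp + tp,
                 stem = min(sum(res[m$fp_match]), sum(res[m$tp_match])),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Flag class-level helix shortening relative to seed lengths
#'
#' A helix is flagged shortened for a class when the class median length is
#' at most `seed length - min_reduction`.
#'
#' @param lengths Data.frame from [helix_lengths()] (non-reference rows).
#' @param seed_lengths Named numeric: reference/seed length per helix
#'   (e.g. `helix_lengths()` of the seed row).
#' @param classes Named character: taxon class per seq_id; sequences without
#'   a class are dropped.
#' @param min_reduction Minimum length reduction to call shortening.
#' @return Data.frame (taxon_class, helix_id, median_length, seed_length,
#'   shortened, n).
#' @export
compare_to_seed <- function(lengths, seed_lengths, classes,
                            min_reduction = 1L) {
  d <- lengths[lengths$seq_id %in% names(classes), , drop = FALSE]
  d$taxon_class <- classes[d$seq_id]
  out <- do.call(rbind, lapply(split(d, list(d$taxon_class, d$helix_id),
                                     drop = TRUE), function(g) {
    data.frame(taxon_class = g$taxon_class[1], helix_id = g$helix_id[1],
               median_length = stats::median(g$length),
               seed_length = unname(seed_lengths[g$helix_id[1]]),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  out$shortened <- out$median_length <= out$seed_length - min_reduction
  out <- out[order(out$helix_id, out$taxon_class), ]
  rownames(out) <- NULL
  out
}

#' Classify helix 78 stem states
#'
#' Classifies each sequence's H78 into `absent` (stem below `presence_min`),
#' `short_stem` (2-3 paired bases), `mid_stem` (6-8) or `full` (at least the
#' seed stem length minus one). Stems falling in the gaps between classes
#' (4-5, or between 8 and the full bound) are labelled with the nearest class
#' and flagged ambiguous. Classification is total: every profile gets exactly
#' one label.
#'
#' @param lengths Data.frame from [helix_lengths()] containing H78 rows.
#' @param seed_stem Stem length of the seed/reference H78.
#' @param presence_min Minimum stem to call the helix present (default 2).
#' @param helix_id Helix identifier (default `"H78"`).
#' @return Data.frame (seq_id, stem, h78_class, ambiguous).
#' @export
classify_h78 <- function(lengths, seed_stem, presence_min = 2L,
                         helix_id = "H78") {
  d <- lengths[lengths$helix_id == helix_id, , drop = FALSE]
  if (nrow(d) == 0L) stop("helix ", helix_id, " not mapped", call. = FALSE)
  full_min <- seed_stem - 1L
  lab <- character(nrow(d)); amb <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    s <- d$stem[i]
    if (s < presence_min) { lab[i] <- "absent"
    } else if (s >= 2 && s <= 3) { lab[i] <- "short_stem"
    } else if (s >= 6 && s <= 8) { lab[i] <- "mid_stem"
    } else if (s >= full_min) { lab[i] <- "full"
    } else {
      # gap between declared classes: nearest class, flagged
      anchors <- c(short_stem = 3, mid_stem = if (s < 6) 6 else 8,
                   full = full_min)
      lab[i] <- names(anchors)[which.min(abs(anchors - s))]
      amb[i] <- TRUE
    }
  }
  data.frame(seq_id = d$seq_id, stem = d$stem, h78_class = lab,
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' Binary H78 presence calls
#'
#' Maps H78 classes to presence bits: `absent` is 0, any detectable stem
#' (short, mid or full) is 1. The result feeds [encode_triplets()].
#'
#' @param h78_classes Data.frame from [classify_h78()].
#' @return Named 0/1 integer vector per seq_id.
#' @export
h78_presence_calls <- function(h78_classes) {
  stats::setNames(as.integer(h78_classes$h78_class != "absent"),
                  h78_classes$seq_id)
}

#' @rdname helix_lengths
#' @param path Output TSV.
#' @export
write_helix_lengths_tsv <- function(lengths, path) {
  utils::write.table(lengths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
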